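# Readers and writers for the package's on-disk formats. Everything is
# plain text (CSV, YAML) or TIFF; grid metadata and a provenance stamp
# (tool version + config hash) travel in '#' comment headers (CSV), the
# description tag (TIFF) or provenance.yaml.

provenance_line <- function(provenance = NULL) {
  ver <- as.character(utils::packageVersion("waveseg"))
  if (is.null(provenance)) {
    sprintf("waveseg %s", ver)
  } else {
    sprintf("waveseg %s config=%s", ver, provenance)
  }
}

#' Write / read a vector-field sequence as CSV
#'
#' Long format with one row per (time step, node): columns `t`, node
#' indices (`y`, `x`\[, `z`\], 1-based), components (`vy`, `vx`\[, `vz`\])
#' and `valid`. Grid metadata lives in `#` header lines.
#'
#' @param fields a `vector_field_sequence`.
#' @param path output file.
#' @param provenance optional config-hash string for the file header.
#' @return `path`, invisibly (writer); a `vector_field_sequence` (reader).
#' @export
write_field_csv <- function(fields, path, provenance = NULL) {
  stopifnot(inherits(fields, "vector_field_sequence"))
  nd <- field_ndim(fields)
  gs <- grid_shape(fields)
  tt <- n_steps(fields)
  ax <- if (nd == 2) c("y", "x") else c("z", "y", "x")
  nodes <- as.matrix(expand.grid(lapply(gs, seq_len)))
  rows <- cbind(rep(seq_len(tt), each = nrow(nodes)),
                nodes[rep(seq_len(nrow(nodes)), times = tt), , drop = FALSE])
  colnames(rows) <- c("t", ax)
  comp <- matrix(0, nrow(rows), nd)
  for (c_ in seq_len(nd)) {
    comp[, c_] <- fields$vectors[cbind(rows, c_)]
  }
  val <- fields$validity[rows]
  df <- data.frame(rows, comp, valid = as.integer(val))
  names(df) <- c("t", ax, paste0("v", ax), "valid")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# ", provenance_line(provenance)),
    paste0("# axis order: (t, ", paste(ax, collapse = ", "),
           "), 1-based indices; components in the same order"),
    paste0("# grid_step: ", paste(fields$grid_step, collapse = " ")),
    paste0("# grid_origin: ", paste(fields$grid_origin, collapse = " ")),
    paste0("# grid_shape: ", paste(gs, collapse = " "))
  ), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_header_values <- function(path, key) {
  lines <- readLines(path, n = 20)
  ln <- grep(paste0("^# ", key, ":"), lines, value = TRUE)
  if (!length(ln)) return(NULL)
  as.numeric(strsplit(sub(paste0("^# ", key, ": *"), "", ln[1]), " ")[[1]])
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  gs <- read_header_values(path, "grid_shape")
  step <- read_header_values(path, "grid_step")
  origin <- read_header_values(path, "grid_origin")
  if (is.null(gs)) stop("missing grid_shape header in ", path)
  df <- utils::read.csv(path, comment.char = "#")
  nd <- length(gs)
  ax <- if (nd == 2) c("y", "x") else c("z", "y", "x")
  tt <- max(df$t)
  vec <- array(0, c(tt, gs, nd))
  val <- array(0, c(tt, gs))
  idx <- as.matrix(df[, c("t", ax)])
  val[idx] <- df$valid
  for (c_ in seq_len(nd)) {
    vec[cbind(idx, c_)] <- df[[paste0("v", ax[c_])]]
  }
  vector_field_sequence(vec, val, grid_step = step, grid_origin = origin)
}

#' Write / read a label volume as multi-page TIFF
#'
#' One 8-bit page per frame; label values 0 (none), 1 (V), 2 (D) are
#' stored as grey levels `value / 255`. TIFF files carry no comment header;
#' run provenance for TIFF artifacts is recorded in the run's
#' `provenance.yaml`.
#'
#' @param labels integer array `(t, y, x)` or a `wave_segmentation`.
#' @param path output file.
#' @param provenance unused for TIFF (accepted for interface symmetry).
#' @return `path`, invisibly (writer); an integer label array (reader).
#' @export
write_labels_tiff <- function(labels, path, provenance = NULL) {
  arr <- label_array_of(labels)
  if (length(dim(arr)) != 3) stop("TIFF export supports (t, y, x) label maps")
  tt <- dim(arr)[1]
  pages <- lapply(seq_len(tt), function(t) {
    m <- arr[t, , ]
    m / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' @rdname write_labels_tiff
#' @export
read_labels_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0L, c(length(pages), dim(pages[[1]])))
  for (t in seq_along(pages)) {
    arr[t, , ] <- as.integer(round(pages[[t]] * 255))
  }
  arr
}

#' Read / write binary masks as TIFF
#'
#' Masks are stored as single-page (2D) or multi-page (3D, one page per
#' z-plane) black-and-white TIFF.
#'
#' @param mask binary array (2D or 3D).
#' @param path file path.
#' @return `path`, invisibly (writer); an integer 0/1 array (reader).
#' @export
write_mask_tiff <- function(mask, path) {
  m <- (mask != 0) * 1
  if (length(dim(m)) == 2) {
    tiff::writeTIFF(m, path, bits.per.sample = 8)
  } else if (length(dim(m)) == 3) {
    pages <- lapply(seq_len(dim(m)[1]), function(z) m[z, , ])
    tiff::writeTIFF(pages, path, bits.per.sample = 8)
  } else {
    stop("mask must be 2D or 3D")
  }
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 1) {
    return(array(as.integer(pages[[1]] > 0.5), dim(pages[[1]])))
  }
  arr <- array(0L, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- as.integer(pages[[z]] > 0.5)
  arr
}

#' Read a multi-page TIFF image sequence
#'
#' Pages are interpreted as time frames, yielding a `(t, y, x)` array of
#' intensities in `[0, 1]`.
#'
#' @param path TIFF file.
#' @return numeric array `(t, y, x)`.
#' @export
read_image_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p[, , 1] else p  # drop extra channels
  })
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (t in seq_along(pages)) arr[t, , ] <- pages[[t]]
  arr
}

#' Write an image sequence as multi-page TIFF
#'
#' @param images numeric array `(t, y, x)`; values are clipped to `[0, 1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(images, path) {
  stopifnot(length(dim(images)) == 3)
  mx <- max(images)
  if (mx > 1) images <- images / mx
  pages <- lapply(seq_len(dim(images)[1]), function(t) {
    pmin(pmax(images[t, , ], 0), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

#' Write / read a distortion grid as CSV
#'
#' Columns `tile_row`, `tile_col`, `longitudinal_factor`,
#' `latitudinal_factor`; the tile size travels in a `#` header line.
#'
#' @param grid a [distortion_grid()].
#' @param path file path.
#' @return `path`, invisibly (writer); a `distortion_grid` (reader).
#' @export
write_distortion_csv <- function(grid, path) {
  stopifnot(inherits(grid, "distortion_grid"))
  nt <- dim(grid$longitudinal)
  df <- data.frame(
    tile_row = rep(seq_len(nt[1]), times = nt[2]),
    tile_col = rep(seq_len(nt[2]), each = nt[1]),
    longitudinal_factor = as.numeric(grid$longitudinal),
    latitudinal_factor = as.numeric(grid$latitudinal)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", provenance_line()),
               paste0("# tile_size: ", grid$tile_size)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distortion_csv
#' @export
read_distortion_csv <- function(path) {
  ts <- read_header_values(path, "tile_size")
  df <- utils::read.csv(path, comment.char = "#")
  nr <- max(df$tile_row)
  nc <- max(df$tile_col)
  lon <- matrix(NA_real_, nr, nc)
  lat <- matrix(NA_real_, nr, nc)
  lon[cbind(df$tile_row, df$tile_col)] <- df$longitudinal_factor
  lat[cbind(df$tile_row, df$tile_col)] <- df$latitudinal_factor
  distortion_grid(lon, lat, ts %||% 10)
}

#' Write a kymograph as CSV
#'
#' Long format via [tidy_kymograph()], with a provenance header.
#'
#' @param k a [kymograph()].
#' @param path output file.
#' @param provenance optional config-hash string.
#' @return `path`, invisibly.
#' @export
write_kymograph_csv <- function(k, path, provenance = NULL) {
  df <- tidy_kymograph(k)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", provenance_line(provenance)),
               paste0("# axis: ", k$axis, "  reduce: ", k$reduce)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write the per-wave table as CSV
#'
#' @param segmentation a `wave_segmentation`.
#' @param path output file.
#' @param provenance optional config-hash string.
#' @return `path`, invisibly.
#' @export
write_waves_csv <- function(segmentation, path, provenance = NULL) {
  stopifnot(inherits(segmentation, "wave_segmentation"))
  w <- segmentation$waves
  w$v_avg <- NULL
  w$d_avg <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# ", provenance_line(provenance)),
               "# 1-based frame and node indices"), con)
  utils::write.csv(as.data.frame(w), con, row.names = FALSE)
  invisible(path)
}
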