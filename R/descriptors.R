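#' Expanding-template kernel
#'
#' A square vector kernel of odd size whose cells hold unit vectors pointing
#' away from the centre cell (the centre itself is zero). Correlating a
#' vector field with this template yields a divergence score at the
#' template's spatial scale: positive where the flow locally expands,
#' negative where it constricts.
#'
#' @param size odd kernel edge length in grid cells (>= 3).
#' @return numeric array `(size, size, 2)`, components in `(y, x)` order.
#' @export
expanding_template <- function(size) {
  if (size %% 2 != 1) stop("kernel size must be odd")
  if (size < 3) stop("kernel size must be >= 3")
  h <- (size - 1) / 2
  k <- array(0, c(size, size, 2))
  for (i in seq_len(size)) {
    for (j in seq_len(size)) {
      off <- c(i - h - 1, j - h - 1)
      n <- sqrt(sum(off^2))
      if (n > 0) k[i, j, ] <- off / n
    }
  }
  k
}

#' Divergence map by expanding-template correlation
#'
#' For every node `p` and time step `t`,
#' `D(p, t) = sum_q k(q) . v(p + q, t)` where `k` is the expanding
#' template: the sum over kernel offsets of dot products between the
#' template vectors and the field. Near the grid border the kernel is
#' clipped to the available nodes (partial sums), so border divergences are
#' attenuated rather than inflated. Positive values mark expansion,
#' negative values constriction. Invalid field nodes carry zero vectors and
#' hence contribute nothing.
#'
#' @param fields a 2D `vector_field_sequence`.
#' @param kernel_size odd template edge length in grid cells (default 17).
#' @return An object of class `divergence_map`: numeric array
#'   `(t, ny, nx)` with attribute `kernel_size`.
#' @export
divergence_map <- function(fields, kernel_size = 17) {
  stopifnot(inherits(fields, "vector_field_sequence"))
  if (field_ndim(fields) != 2) stop("divergence maps are defined for 2D fields")
  gs <- grid_shape(fields)
  if (any(kernel_size > gs)) stop("kernel larger than the grid")
  k <- expanding_template(kernel_size)
  h <- (kernel_size - 1) / 2
  tt <- n_steps(fields)
  nsp <- prod(gs)
  vy <- array(fields$vectors[seq_len(tt * nsp)], c(tt, gs))
  vx <- array(fields$vectors[seq_len(tt * nsp) + tt * nsp], c(tt, gs))
  out <- array(0, c(tt, gs))
  for (oi in seq_len(kernel_size)) {
    for (oj in seq_len(kernel_size)) {
      ky <- k[oi, oj, 1]
      kx <- k[oi, oj, 2]
      if (ky == 0 && kx == 0) next
      dy <- oi - h - 1
      dx <- oj - h - 1
      # target rows p such that p + (dy,dx) lies on the grid
      py <- seq.int(max(1, 1 - dy), min(gs[1], gs[1] - dy))
      px <- seq.int(max(1, 1 - dx), min(gs[2], gs[2] - dx))
      out[, py, px] <- out[, py, px, drop = FALSE] +
        ky * vy[, py + dy, px + dx, drop = FALSE] +
        kx * vx[, py + dy, px + dx, drop = FALSE]
    }
  }
  attr(out, "kernel_size") <- kernel_size
  class(out) <- c("divergence_map", class(out))
  out
}

#' Per-frame divergence extrema
#'
#' Reports, for each time step, the `k` strongest local minima and maxima
#' of the divergence map after non-maximum suppression within one kernel
#' radius (Euclidean). A cell is a local extremum when it is strictly
#' larger (or smaller) than all its 8-neighbours, so constant regions
#' yield no extrema.
#'
#' @param maps a [divergence_map()].
#' @param k number of minima and maxima to report per frame.
#' @param radius suppression radius in grid cells; defaults to half the
#'   kernel size used to build the map.
#' @return A tibble with columns `frame`, `type` (`"min"`/`"max"`), `y`,
#'   `x`, `value`.
#' @export
divergence_extrema <- function(maps, k = 1, radius = NULL) {
  if (k < 1) stop("k must be >= 1")
  ks <- attr(maps, "kernel_size") %||% 3
  if (is.null(radius)) radius <- (ks - 1) / 2
  dims <- dim(maps)
  tt <- dims[1]
  gs <- dims[-1]
  res <- list()
  neigh <- struct_offsets(1, 2, "box")
  neigh <- neigh[rowSums(abs(neigh)) > 0, , drop = FALSE]
  for (t in seq_len(tt)) {
    m <- array(maps[slice_index(tt, t, prod(gs))], gs)
    for (type in c("max", "min")) {
      z <- if (type == "max") m else -m
      is_ext <- array(TRUE, gs)
      for (i in seq_len(nrow(neigh))) {
        nb <- shift_array_num(z, neigh[i, ], fill = Inf)
        is_ext <- is_ext & (z > nb | is.infinite(nb))
      }
      # border cells compared only against existing neighbours; strictness
      # against at least one real neighbour is still required
      is_ext <- is_ext & is.finite(z)
      cand <- which(is_ext)
      if (!length(cand)) next
      ord <- cand[order(z[cand], decreasing = TRUE)]
      kept <- matrix(numeric(0), ncol = 2)
      for (ci in ord) {
        pos <- arrayInd(ci, gs)[1, ]
        if (nrow(kept) &&
            any(rowSums((kept - matrix(pos, nrow(kept), 2,
                                       byrow = TRUE))^2) <= radius^2)) next
        kept <- rbind(kept, pos)
        res[[length(res) + 1]] <- tibble::tibble(
          frame = t, type = type, y = pos[1], x = pos[2],
          value = m[pos[1], pos[2]]
        )
        if (nrow(kept) >= k) break
      }
    }
  }
  if (!length(res)) {
    return(tibble::tibble(frame = integer(0), type = character(0),
                          y = integer(0), x = integer(0), value = numeric(0)))
  }
  do.call(rbind, res)
}

# numeric shift with custom fill (logical version lives in morphology.R)
shift_array_num <- function(a, offset, fill = 0) {
  dims <- dim(a)
  nd <- length(dims)
  out <- array(fill, dims)
  src <- vector("list", nd)
  dst <- vector("list", nd)
  for (kk in seq_len(nd)) {
    o <- offset[kk]
    if (o >= 0) {
      if (o >= dims[kk]) return(out)
      dst[[kk]] <- seq.int(1 + o, dims[kk])
      src[[kk]] <- seq.int(1, dims[kk] - o)
    } else {
      if (-o >= dims[kk]) return(out)
      dst[[kk]] <- seq.int(1, dims[kk] + o)
      src[[kk]] <- seq.int(1 - o, dims[kk])
    }
  }
  piece <- do.call(`[`, c(list(a), src, list(drop = FALSE)))
  do.call(`[<-`, c(list(out), dst, list(piece)))
}

#' Kymograph by summed projection
#'
#' Collapses a 2D+t dataset onto (retained axis x time) by summing over one
#' spatial axis, the standard visualization of wave recurrence. For label
#' volumes the V and D phases are projected separately (each as a binary
#' mask), yielding one kymograph per phase.
#'
#' @param data integer label array `(t, y, x)` (values 0/1/2, or a
#'   `wave_segmentation`) or a numeric image array `(t, y, x)`.
#' @param axis spatial axis to project over: `"x"` (columns) or `"y"`
#'   (rows).
#' @param reduce `"sum"` (default) or `"mean"` (label-density view).
#' @return An object of class `kymograph`: list with `values` (a matrix
#'   `retained x time`, or a named list of such matrices for labels),
#'   `axis`, `reduce`.
#' @export
kymograph <- function(data, axis = c("x", "y"), reduce = c("sum", "mean")) {
  axis <- match.arg(axis)
  reduce <- match.arg(reduce)
  is_labels <- inherits(data, "wave_segmentation")
  arr <- if (is_labels) data$labels else data
  if (length(dim(arr)) != 3) stop("kymographs are defined for (t, y, x) data")
  if (!is_labels && all(arr %in% c(0L, 1L, 2L)) && is.integer(arr)) {
    is_labels <- TRUE
  }
  proj_margin <- if (axis == "x") c(1, 2) else c(1, 3)
  red <- function(a) {
    p <- apply(a, proj_margin, if (reduce == "sum") sum else mean)
    t(p)  # -> (retained axis, time)
  }
  values <- if (is_labels) {
    list(V = red(arr == 1L), D = red(arr == 2L))
  } else {
    red(arr)
  }
  structure(list(values = values, axis = axis, reduce = reduce),
            class = "kymograph")
}

#' Tidy a kymograph into a long tibble
#'
#' @param k a [kymograph()].
#' @return A tibble with columns `position`, `frame`, `value` and (for
#'   label kymographs) `phase`.
#' @export
tidy_kymograph <- function(k) {
  stopifnot(inherits(k, "kymograph"))
  one <- function(m, phase = NA_character_) {
    tibble::tibble(
      position = rep(seq_len(nrow(m)), times = ncol(m)),
      frame = rep(seq_len(ncol(m)), each = nrow(m)),
      value = as.numeric(m),
      phase = phase
    )
  }
  if (is.list(k$values)) {
    out <- rbind(one(k$values$V, "V"), one(k$values$D, "D"))
  } else {
    out <- one(k$values)
    out$phase <- NULL
  }
  out
}
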