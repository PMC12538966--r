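# End-to-end orchestration: YAML run configuration, the piv -> segment ->
# postprocess -> descriptors pipeline, and the summary report.

known_cfg_keys <- list(
  top = c("representation", "input", "piv", "params", "reference",
          "postprocess", "rupture_frame", "polar_crop_rows", "output"),
  input = c("images", "fields", "mask", "distortion"),
  piv = c("interrogation_size", "search_margin", "grid_step",
          "min_mask_fraction", "subpixel"),
  params = c("preset", "theta_r", "theta_V", "theta_D", "theta_VD", "M_min",
             "M_avg", "M_total", "window_N", "max_gap",
             "enforce_dorsal_halfplane"),
  reference = c("preset", "r", "dorsal_axis", "split_col"),
  postprocess = c("radius", "min_size", "region", "shape")
)

check_keys <- function(x, section) {
  extra <- setdiff(names(x), known_cfg_keys[[section]])
  if (length(extra)) {
    stop("unknown key(s) in config section '", section, "': ",
         paste(extra, collapse = ", "))
  }
}

#' Load and validate a run configuration
#'
#' Reads a YAML run configuration describing one analysis: the data
#' representation (`lateral`, `volume` or `cylinder`), input paths, PIV
#' settings, wave parameters (a preset name or explicit values; presets
#' reproduce the standard parameter sets for each representation, e.g.
#' `theta_r` 40 degrees and `M_total` 10 px for lateral projections),
#' the reference direction, post-processing settings, and the optional
#' rupture frame. Unknown or missing required keys raise descriptive
#' errors.
#'
#' @param path YAML file, or a list with the same structure.
#' @return A validated run-config list of class `run_config`.
#' @export
load_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  check_keys(cfg, "top")
  if (is.null(cfg$representation)) {
    stop("config is missing required key: representation")
  }
  if (!cfg$representation %in% c("lateral", "volume", "cylinder")) {
    stop("representation must be lateral, volume or cylinder")
  }
  if (is.null(cfg$input) ||
      (is.null(cfg$input$images) && is.null(cfg$input$fields))) {
    stop("config is missing required key: input.images or input.fields")
  }
  check_keys(cfg$input, "input")
  if (!is.null(cfg$piv)) check_keys(cfg$piv, "piv")

  # wave parameters: preset and/or explicit keys
  pcfg <- cfg$params
  if (is.null(pcfg)) stop("config is missing required key: params")
  if (is.character(pcfg)) pcfg <- list(preset = pcfg)
  check_keys(pcfg, "params")
  if (is.null(pcfg$preset)) {
    required <- c("theta_r", "theta_V", "theta_D", "theta_VD", "M_min",
                  "M_avg", "M_total")
    miss <- setdiff(required, names(pcfg))
    if (length(miss)) {
      stop("config params is missing required key(s): ",
           paste(miss, collapse = ", "))
    }
  }
  cfg$params_obj <- do.call(wave_params, pcfg)

  # reference direction
  rcfg <- cfg$reference
  if (is.null(rcfg)) {
    rcfg <- switch(cfg$representation,
                   lateral = list(preset = "lateral"),
                   volume = list(preset = "volume"),
                   cylinder = NULL)
    if (is.null(rcfg)) {
      stop("config is missing required key: reference (cylinder runs need ",
           "reference.split_col)")
    }
  }
  if (is.character(rcfg)) rcfg <- list(preset = rcfg)
  check_keys(rcfg, "reference")
  cfg$reference <- rcfg

  cfg$piv <- cfg$piv %||% list()
  cfg$postprocess <- cfg$postprocess %||% list()
  if (length(cfg$postprocess)) check_keys(cfg$postprocess, "postprocess")
  cfg$polar_crop_rows <- cfg$polar_crop_rows %||% 0L
  class(cfg) <- "run_config"
  cfg
}

resolve_reference <- function(cfg, grid_dims) {
  rcfg <- cfg$reference
  if (!is.null(rcfg$preset)) {
    return(reference_field(rcfg$preset))
  }
  if (!is.null(rcfg$split_col)) {
    return(cylinder_reference_field(grid_dims, rcfg$split_col))
  }
  if (!is.null(rcfg$r)) {
    return(reference_field(unit_vec(as.numeric(rcfg$r)),
                           dorsal_axis = if (!is.null(rcfg$dorsal_axis)) {
                             unit_vec(as.numeric(rcfg$dorsal_axis))
                           }))
  }
  stop("reference config needs a preset, components r, or split_col")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full wave-analysis pipeline
#'
#' Orchestrates PIV (or loading of precomputed fields), optional polar
#' cropping and distortion correction (cylinder maps), temporal wave
#' segmentation, spatial post-processing, descriptors (phase kymographs,
#' divergence map for 2D runs) and a summary report. When `outdir` is
#' given, all artifacts are written there (fields CSV, raw and cleaned
#' label TIFFs, per-wave CSV, kymograph CSV, average-velocity CSV,
#' provenance.yaml); every file carries the tool version and a hash of the
#' configuration, and reruns on identical inputs are byte-identical.
#'
#' @param cfg a [load_config()] result, a path to a YAML config, or a list.
#' @param outdir output directory, or `NULL` to skip writing.
#' @return A list with `fields`, `segmentation` (raw), `clean`
#'   (post-processed `wave_segmentation`), `kymograph`, `divergence`
#'   (2D only), `velocity` and `report` (see [wave_report()]).
#' @export
run_pipeline <- function(cfg, outdir = NULL) {
  if (!inherits(cfg, "run_config")) cfg <- load_config(cfg)
  # hash the configuration; in-memory data objects are summarized by shape
  hashable <- rapply(cfg[setdiff(names(cfg), "params_obj")], function(x) {
    if (length(x) > 64) paste0("<object ", paste(dim(x) %||% length(x),
                                                 collapse = "x"), ">")
    else x
  }, how = "replace")
  cfg_hash <- fnv1a_hash(yaml::as.yaml(hashable))

  fields <- stage("piv", {
    if (!is.null(cfg$input$fields)) {
      f <- if (inherits(cfg$input$fields, "vector_field_sequence")) {
        cfg$input$fields
      } else {
        read_field_csv(cfg$input$fields)
      }
      f
    } else {
      imgs <- if (is.character(cfg$input$images)) {
        read_image_tiff(cfg$input$images)
      } else {
        cfg$input$images
      }
      mask <- if (is.character(cfg$input$mask)) {
        read_mask_tiff(cfg$input$mask)
      } else {
        cfg$input$mask
      }
      compute_piv_sequence(imgs, mask = mask,
                           cfg = do.call(piv_config, cfg$piv))
    }
  })

  if (cfg$polar_crop_rows > 0) {
    fields <- stage("polar_crop", crop_field_rows(fields, cfg$polar_crop_rows))
  }
  if (!is.null(cfg$input$distortion)) {
    fields <- stage("distortion", {
      g <- if (inherits(cfg$input$distortion, "distortion_grid")) {
        cfg$input$distortion
      } else {
        read_distortion_csv(cfg$input$distortion)
      }
      correct_distortion(fields, g)
    })
  }

  refs <- stage("reference", resolve_reference(cfg, grid_shape(fields)))
  seg <- stage("segment", segment_field(fields, refs, cfg$params_obj))

  pp <- cfg$postprocess
  region <- if (!is.null(pp$region)) {
    if (is.character(pp$region)) read_mask_tiff(pp$region) else pp$region
  }
  clean <- stage("postprocess", postprocess_labels(
    seg, radius = pp$radius %||% 1, min_size = pp$min_size %||% 50,
    region = region, shape = pp$shape %||% "box"
  ))

  two_d <- field_ndim(fields) == 2
  kymo <- if (two_d) stage("kymograph", kymograph(clean, axis = "x"))
  div <- if (two_d) {
    ks <- min(17, grid_shape(fields) - (1 - grid_shape(fields) %% 2))
    ks <- max(3, ks - (1 - ks %% 2))
    stage("divergence", divergence_map(fields, ks))
  }
  vel <- stage("velocity", average_velocity(fields))

  split_col <- cfg$reference$split_col
  report <- stage("report", wave_report(clean, cfg$rupture_frame, split_col))

  if (!is.null(outdir)) {
    stage("write", {
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      write_field_csv(fields, file.path(outdir, "fields.csv"), cfg_hash)
      write_labels_tiff(seg, file.path(outdir, "labels_raw.tif"), cfg_hash)
      write_labels_tiff(clean, file.path(outdir, "labels_clean.tif"), cfg_hash)
      write_waves_csv(clean, file.path(outdir, "waves.csv"), cfg_hash)
      if (!is.null(kymo)) {
        write_kymograph_csv(kymo, file.path(outdir, "kymograph.csv"), cfg_hash)
      }
      con <- file(file.path(outdir, "velocity.csv"), "w")
      writeLines(paste0("# ", provenance_line(cfg_hash)), con)
      utils::write.csv(as.data.frame(vel), con, row.names = FALSE)
      close(con)
      yaml::write_yaml(
        list(tool = provenance_line(), config_hash = cfg_hash,
             report = report_as_list(report)),
        file.path(outdir, "provenance.yaml")
      )
    })
  }

  list(fields = fields, segmentation = seg, clean = clean, kymograph = kymo,
       divergence = div, velocity = vel, report = report,
       config_hash = cfg_hash)
}

# drop n polar rows from the top and bottom of a 2D field's node grid
crop_field_rows <- function(fields, n) {
  gs <- grid_shape(fields)
  keep <- (n + 1):(gs[1] - n)
  if (length(keep) < 1) stop("polar crop removes the whole grid")
  vec <- fields$vectors[, keep, , , drop = FALSE]
  val <- fields$validity[, keep, , drop = FALSE]
  vector_field_sequence(vec, val, grid_step = fields$grid_step,
                        grid_origin = fields$grid_origin +
                          c(n * fields$grid_step[1], 0))
}

#' Count wave events and summarize a segmentation
#'
#' A wave event is a maximal run of consecutive frames in which any node
#' carries a V label. The report gives the number of events before and
#' after the rupture frame (events are assigned by their first frame), the
#' V and D durations of each per-node wave record, and the labelled area
#' (node count) per frame — split by map side when `split_col` is given
#' (cylinder maps).
#'
#' @param segmentation a `wave_segmentation` (typically post-processed).
#' @param rupture_frame frame separating the pre- and post-rupture epochs,
#'   or `NULL` for a single undivided count.
#' @param split_col optional first column of the right map side.
#' @return A list of class `wave_report`: `n_waves`, `n_pre`, `n_post`,
#'   `events` (tibble: `start`, `end`, `epoch`), `durations` (tibble per
#'   wave record), `area` (tibble: `frame`, `phase`, `side`, `n_nodes`).
#' @export
wave_report <- function(segmentation, rupture_frame = NULL, split_col = NULL) {
  stopifnot(inherits(segmentation, "wave_segmentation"))
  labels <- segmentation$labels
  dims <- dim(labels)
  tt <- dims[1]
  flat <- labels
  dim(flat) <- c(tt, prod(dims[-1]))
  has_v <- rowSums(flat == 1L) > 0
  r <- rle(has_v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ev <- which(r$values)
  events <- tibble::tibble(start = starts[ev], end = ends[ev])
  if (!is.null(rupture_frame)) {
    events$epoch <- ifelse(events$start <= rupture_frame, "pre", "post")
  } else {
    events$epoch <- "all"
  }
  w <- segmentation$waves
  durations <- tibble::tibble(
    v_duration = w$v_end - w$v_start + 1L,
    d_duration = w$d_end - w$d_start + 1L
  )
  side_of <- function(x_idx) {
    if (is.null(split_col)) "all" else ifelse(x_idx < split_col, "left", "right")
  }
  nd <- length(dims) - 1
  area <- list()
  for (ph in 1:2) {
    cells <- which(labels == ph)
    if (!length(cells)) next
    co <- arrayInd(cells, dims)
    side <- side_of(co[, nd + 1])
    key <- paste(co[, 1], side)
    tabk <- table(key)
    parts <- strsplit(names(tabk), " ")
    area[[length(area) + 1]] <- tibble::tibble(
      frame = as.integer(vapply(parts, `[`, character(1), 1)),
      phase = c("V", "D")[ph],
      side = vapply(parts, `[`, character(1), 2),
      n_nodes = as.integer(tabk)
    )
  }
  area <- if (length(area)) do.call(rbind, area) else {
    tibble::tibble(frame = integer(0), phase = character(0),
                   side = character(0), n_nodes = integer(0))
  }
  structure(
    list(
      n_waves = nrow(events),
      n_pre = sum(events$epoch == "pre"),
      n_post = sum(events$epoch == "post"),
      events = events, durations = durations, area = area
    ),
    class = "wave_report"
  )
}

#' @export
print.wave_report <- function(x, ...) {
  cat(sprintf("<wave_report> %d wave events (%d pre-rupture, %d post)\n",
              x$n_waves, x$n_pre, x$n_post))
  if (nrow(x$durations)) {
    cat(sprintf("  median V duration %g frames, median D duration %g frames\n",
                stats::median(x$durations$v_duration),
                stats::median(x$durations$d_duration)))
  }
  invisible(x)
}

report_as_list <- function(report) {
  list(
    n_waves = report$n_waves, n_pre = report$n_pre, n_post = report$n_post,
    events = lapply(seq_len(nrow(report$events)), function(i) {
      as.list(report$events[i, ])
    }),
    median_v_duration = if (nrow(report$durations)) {
      stats::median(report$durations$v_duration)
    },
    median_d_duration = if (nrow(report$durations)) {
      stats::median(report$durations$d_duration)
    }
  )
}
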