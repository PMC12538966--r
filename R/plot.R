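# ggplot2 views of the main result types. These are convenience displays;
# all underlying numbers come from the exported accessors.

utils::globalVariables(c("frame", "position", "value", "phase", "mean_speed",
                         "x", "y", "t_max"))

#' Plot a kymograph
#'
#' Heat-map of the summed projection against time; label kymographs show
#' the V and D phases as facets.
#'
#' @param k a [kymograph()].
#' @return A ggplot object.
#' @export
plot_kymograph <- function(k) {
  df <- tidy_kymograph(k)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = frame, y = position,
                                        fill = value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "frame", y = paste0("position (", k$axis, " projected)"),
                  fill = k$reduce)
  if ("phase" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~phase, ncol = 1)
  }
  p
}

#' Plot the average-velocity trace
#'
#' @param vel the tibble returned by [average_velocity()].
#' @param rupture_frame optional frame to mark with a vertical line.
#' @return A ggplot object.
#' @export
plot_average_velocity <- function(vel, rupture_frame = NULL) {
  p <- ggplot2::ggplot(vel, ggplot2::aes(x = frame, y = mean_speed)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frame", y = "mean speed (px/frame)")
  if (!is.null(rupture_frame)) {
    p <- p + ggplot2::geom_vline(xintercept = rupture_frame, linetype = 2)
  }
  p
}

#' Plot one frame of a label map
#'
#' @param segmentation a `wave_segmentation` or integer label array.
#' @param frame frame index.
#' @return A ggplot object.
#' @export
plot_label_frame <- function(segmentation, frame) {
  arr <- label_array_of(segmentation)
  m <- arr[frame, , ]
  df <- tibble::tibble(
    y = rep(seq_len(nrow(m)), times = ncol(m)),
    x = rep(seq_len(ncol(m)), each = nrow(m)),
    phase = factor(c("none", "V", "D")[as.integer(m) + 1],
                   levels = c("none", "V", "D"))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = x, y = y, fill = phase)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(none = "grey90", V = "#d62728",
                                          D = "#1f77b4")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste("frame", frame))
}
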