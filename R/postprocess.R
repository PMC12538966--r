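# Spatial post-processing of rasterized wave labels. The temporal
# segmentation is applied independently per position, so spurious isolated
# detections are cleaned up per frame: morphological opening against thin
# segmentations, size filtering of connected components, and removal of
# components whose centroid falls in an exclusion region (e.g. the head of
# the embryo, which twitches after rupture). All three operations only ever
# delete labels; they never create them.

label_array_of <- function(labels) {
  if (inherits(labels, "wave_segmentation")) labels$labels else labels
}

with_label_array <- function(labels, new) {
  if (inherits(labels, "wave_segmentation")) {
    labels$labels <- new
    labels
  } else {
    new
  }
}

# apply f(binary frame mask) -> binary frame mask to each frame and phase,
# then recompose the label volume
map_label_frames <- function(labels, f) {
  arr <- label_array_of(labels)
  dims <- dim(arr)
  tt <- dims[1]
  sp <- dims[-1]
  out <- array(0L, dims)
  for (t in seq_len(tt)) {
    fr <- do.call(`[`, c(list(arr), c(list(t), lapply(sp, seq_len)),
                         list(drop = FALSE)))
    dim(fr) <- sp
    v <- f(fr == 1L)
    d <- f(fr == 2L)
    new_fr <- array(0L, sp)
    new_fr[v] <- 1L
    new_fr[d] <- 2L
    out[slice_index(tt, t, prod(sp))] <- new_fr
  }
  with_label_array(labels, out)
}

#' Morphological opening of wave labels
#'
#' Opens the V and D label masks of each frame separately with a
#' structuring element of the given radius, removing thin or spindly
#' segmentations. Radius 0 is the identity.
#'
#' @param labels integer label array `(t, <grid dims>)` with values 0/1/2,
#'   or a `wave_segmentation`.
#' @param radius structuring-element radius in grid cells.
#' @param shape structuring-element shape, see [struct_offsets()].
#' @return Same type as `labels`.
#' @export
morphological_open_labels <- function(labels, radius = 1, shape = "box") {
  if (radius < 0) stop("radius must be >= 0")
  if (radius == 0) return(labels)
  nd <- length(dim(label_array_of(labels))) - 1L
  se <- struct_offsets(radius, nd, shape)
  map_label_frames(labels, function(m) binary_open(m, se))
}

#' Size filtering of wave labels
#'
#' Removes, per frame and phase, connected components (face adjacency)
#' smaller than `min_size` grid cells. Components of exactly `min_size`
#' cells are kept.
#'
#' @inheritParams morphological_open_labels
#' @param min_size minimum component size in grid cells (>= 1).
#' @return Same type as `labels`.
#' @export
size_filter <- function(labels, min_size = 50) {
  if (min_size < 1) stop("min_size must be >= 1")
  if (min_size == 1) return(labels)
  map_label_frames(labels, function(m) {
    lab <- label_components(m)
    sizes <- attr(lab, "sizes")
    keep <- which(sizes >= min_size)
    lab_ok <- array(lab %in% keep & lab > 0L, dim(m))
    lab_ok
  })
}

#' Exclusion-region filtering of wave labels
#'
#' Removes, per frame and phase, connected components whose centroid (mean
#' of member cell coordinates, rounded to the nearest cell) falls inside
#' the exclusion region. Components merely overlapping the region edge but
#' centred outside survive.
#'
#' @inheritParams morphological_open_labels
#' @param region binary array matching the label map's spatial shape.
#' @return Same type as `labels`.
#' @export
region_filter <- function(labels, region) {
  arr <- label_array_of(labels)
  sp <- dim(arr)[-1]
  if (!identical(dim(region), sp)) stop("region shape must match the label grid")
  region <- region != 0
  if (!any(region)) return(labels)
  map_label_frames(labels, function(m) {
    if (!any(m)) return(m)
    lab <- label_components(m)
    drop <- integer(0)
    for (cid in seq_along(attr(lab, "sizes"))) {
      cells <- arrayInd(which(lab == cid), dim(m))
      cen <- pmin(pmax(round(colMeans(cells)), 1), dim(m))
      if (region[matrix(cen, 1)]) drop <- c(drop, cid)
    }
    if (length(drop)) m[lab %in% drop] <- FALSE
    m
  })
}

#' Standard label clean-up
#'
#' Convenience wrapper running opening, size filtering and (optionally)
#' exclusion-region filtering in the standard order.
#'
#' @inheritParams morphological_open_labels
#' @param min_size minimum component size; see [size_filter()].
#' @param region optional exclusion region; see [region_filter()].
#' @return Same type as `labels`.
#' @export
postprocess_labels <- function(labels, radius = 1, min_size = 50,
                               region = NULL, shape = "box") {
  out <- morphological_open_labels(labels, radius, shape)
  out <- size_filter(out, min_size)
  if (!is.null(region)) out <- region_filter(out, region)
  out
}
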