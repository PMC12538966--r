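#' Gridded displacement vector-field sequence
#'
#' The central container of the package: displacement vectors between
#' consecutive frames, sampled on a regular spatial grid. `vectors` is an
#' array of dimension `(T, <grid dims>, D)` where `T` is the number of
#' inter-frame steps, the grid dims follow array axis order (`(y, x)` in 2D,
#' `(z, y, x)` in 3D) and `D` equals the number of grid dims. Vector
#' components are stored in the same axis order as the grid, so component 1
#' is displacement along rows. Units are px/frame (2D) or vx/frame (3D).
#'
#' Invalid nodes (e.g. rejected by the PIV mask) carry zero vectors and
#' `validity == 0`; every operation downstream treats them as zero motion.
#'
#' @param vectors numeric array `(T, <grid dims>, D)`.
#' @param validity numeric/logical array `(T, <grid dims>)` of 0/1 flags, or
#'   `NULL` for all-valid.
#' @param grid_step pixels between neighbouring grid nodes, per spatial axis
#'   (recycled).
#' @param grid_origin pixel coordinate (1-based) of the first grid node
#'   centre, per spatial axis (recycled).
#' @return An object of class `vector_field_sequence`.
#' @export
vector_field_sequence <- function(vectors, validity = NULL, grid_step = 1,
                                  grid_origin = 1) {
  dv <- dim(vectors)
  if (is.null(dv) || length(dv) < 3) {
    stop("`vectors` must be an array (T, <grid dims>, D)")
  }
  nd <- length(dv) - 2L
  if (!nd %in% c(2L, 3L)) stop("only 2D and 3D vector fields are supported")
  if (dv[length(dv)] != nd) {
    stop("last dimension of `vectors` must equal the number of grid dims")
  }
  if (is.null(validity)) {
    validity <- array(1, dv[-length(dv)])
  }
  if (!identical(dim(validity), dv[-length(dv)])) {
    stop("`validity` shape must match (T, <grid dims>)")
  }
  validity <- array(as.numeric(validity != 0), dim(validity))
  # contract: invalid nodes carry zero vectors
  if (any(validity == 0)) {
    inval <- which(validity == 0)
    nspace <- prod(dv[-length(dv)])
    for (c_ in seq_len(nd)) vectors[inval + (c_ - 1) * nspace] <- 0
  }
  structure(
    list(
      vectors = vectors,
      validity = validity,
      grid_step = rep_len(grid_step, nd),
      grid_origin = rep_len(grid_origin, nd)
    ),
    class = "vector_field_sequence"
  )
}

#' @export
print.vector_field_sequence <- function(x, ...) {
  gs <- grid_shape(x)
  cat(sprintf(
    "<vector_field_sequence> %d time steps, %s grid (%dD), %.1f%% valid nodes\n",
    n_steps(x), paste(gs, collapse = " x "), field_ndim(x),
    100 * mean(x$validity)
  ))
  invisible(x)
}

#' Number of inter-frame time steps of a field sequence
#' @param x a `vector_field_sequence`.
#' @export
n_steps <- function(x) dim(x$vectors)[1]

#' Spatial grid shape of a field sequence
#' @param x a `vector_field_sequence`.
#' @export
grid_shape <- function(x) {
  dv <- dim(x$vectors)
  dv[-c(1, length(dv))]
}

#' Spatial dimensionality (2 or 3) of a field sequence
#' @param x a `vector_field_sequence`.
#' @export
field_ndim <- function(x) length(dim(x$vectors)) - 2L

#' Extract the vector time series at one grid node
#'
#' Returns the `T x D` matrix of displacement vectors across all time steps
#' at a fixed grid position, the substrate of the temporal wave segmentation.
#' Frames where the node is invalid are returned as zero vectors.
#'
#' @param x a `vector_field_sequence`.
#' @param pos integer vector of node indices, one per grid axis (1-based).
#' @return numeric matrix `T x D`.
#' @export
vector_series <- function(x, pos) {
  gs <- grid_shape(x)
  if (length(pos) != length(gs)) stop("`pos` must have one index per grid axis")
  if (any(pos < 1 | pos > gs)) stop("`pos` out of grid range")
  nd <- field_ndim(x)
  idx <- c(list(seq_len(n_steps(x))), as.list(pos), list(seq_len(nd)))
  out <- do.call(`[`, c(list(x$vectors), idx, list(drop = FALSE)))
  dim(out) <- c(n_steps(x), nd)
  out
}

# per-node-and-frame speed, array (T, <grid dims>)
field_magnitudes <- function(x) {
  dv <- dim(x$vectors)
  nd <- field_ndim(x)
  m2 <- array(0, dv[-length(dv)])
  nspace <- prod(dv[-length(dv)])
  for (c_ in seq_len(nd)) {
    m2 <- m2 + array(x$vectors[seq_len(nspace) + (c_ - 1) * nspace],
                     dv[-length(dv)])^2
  }
  sqrt(m2)
}

#' Average tissue speed per time step
#'
#' Mean vector magnitude over all valid grid nodes, per time step: the trace
#' whose peaks accompany contraction waves. Time steps with no valid node
#' yield `NA`.
#'
#' @param fields a `vector_field_sequence`.
#' @return A tibble with columns `frame`, `mean_speed`, `n_valid`.
#' @export
average_velocity <- function(fields) {
  stopifnot(inherits(fields, "vector_field_sequence"))
  mags <- field_magnitudes(fields)
  tt <- n_steps(fields)
  dim(mags) <- c(tt, length(mags) / tt)
  val <- fields$validity
  dim(val) <- dim(mags)
  nv <- rowSums(val)
  ms <- rowSums(mags * val) / nv
  ms[nv == 0] <- NA_real_
  tibble::tibble(frame = seq_len(tt), mean_speed = ms, n_valid = as.integer(nv))
}
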