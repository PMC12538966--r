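#' PIV configuration
#'
#' Settings for masked PIV by normalized squared differences. Defaults follow
#' common practice for nuclei-labelled light-sheet recordings at ~0.6 um/px:
#' 32 px interrogation windows in 2D (24 vx in 3D), a 10 px search margin and
#' 50% window overlap.
#'
#' @param interrogation_size pixels per axis of the interrogation window
#'   (recycled across axes); must be >= 4.
#' @param search_margin maximum displacement searched, in pixels per axis;
#'   must be >= 1.
#' @param grid_step spacing between grid nodes in pixels; defaults to half
#'   the interrogation size.
#' @param min_mask_fraction minimum fraction of an interrogation window that
#'   must be covered by the mask for the node to be valid, in \[0, 1\].
#' @param subpixel logical; refine integer displacements by a 3-point
#'   parabolic fit per axis on the score surface.
#' @return An object of class `piv_config`.
#' @export
piv_config <- function(interrogation_size = 32, search_margin = 10,
                       grid_step = NULL, min_mask_fraction = 0.5,
                       subpixel = TRUE) {
  if (any(interrogation_size < 4)) stop("interrogation_size must be >= 4 per axis")
  if (any(search_margin < 1)) stop("search_margin must be >= 1")
  if (min_mask_fraction < 0 || min_mask_fraction > 1) {
    stop("min_mask_fraction must be in [0, 1]")
  }
  if (is.null(grid_step)) grid_step <- floor(interrogation_size / 2)
  structure(
    list(
      interrogation_size = interrogation_size,
      search_margin = search_margin,
      grid_step = grid_step,
      min_mask_fraction = min_mask_fraction,
      subpixel = isTRUE(subpixel)
    ),
    class = "piv_config"
  )
}

# n-d subarray extraction by per-axis ranges (list of index vectors)
subarr <- function(a, ranges) {
  out <- do.call(`[`, c(list(a), ranges, list(drop = FALSE)))
  out
}

#' PIV between one pair of frames
#'
#' Estimates the displacement field from `frame_a` to `frame_b` on a regular
#' grid of interrogation windows. At each node the displacement is the argmin
#' over the search range of the normalized squared-difference score
#' \deqn{NSQ(d) = \sum_x (a(x) - b(x+d))^2 \big/
#'   \sqrt{\sum_x a(x)^2 \cdot \sum_x b(x+d)^2},}
#' evaluated over the interrogation window (windows reaching past the image
#' border are clipped to the overlap, never wrapped), optionally followed by
#' a 3-point parabolic sub-pixel fit per axis. Nodes whose window overlaps
#' the mask by less than `min_mask_fraction`, or whose window is all zero,
#' are flagged invalid and carry zero vectors.
#'
#' @param frame_a,frame_b numeric arrays of identical shape (2D or 3D).
#' @param mask optional binary array of the same spatial shape.
#' @param cfg a [piv_config()].
#' @return A `vector_field_sequence` with a single time step.
#' @export
compute_piv_pair <- function(frame_a, frame_b, mask = NULL, cfg = piv_config()) {
  if (is.null(dim(frame_a))) stop("frames must be 2D or 3D arrays")
  dims <- dim(frame_a)
  nd <- length(dims)
  if (!nd %in% c(2L, 3L)) stop("frames must be 2D or 3D arrays")
  if (!identical(dim(frame_b), dims)) stop("frame shapes differ")
  if (!is.null(mask) && !identical(dim(mask), dims)) {
    stop("mask shape must match the frames")
  }
  W <- rep_len(cfg$interrogation_size, nd)
  m <- rep_len(cfg$search_margin, nd)
  step <- rep_len(cfg$grid_step, nd)
  if (any(dims < W)) stop("interrogation window larger than the image")

  n_nodes <- floor((dims - W) / step) + 1
  disp_ax <- lapply(m, function(mm) seq.int(-mm, mm))
  n_disp <- 2 * m + 1

  vec <- array(0, c(1, n_nodes, nd))
  val <- array(0, c(1, n_nodes))

  node_grid <- as.matrix(expand.grid(lapply(n_nodes, seq_len)))
  score <- array(Inf, n_disp)
  disp_grid <- as.matrix(expand.grid(disp_ax))

  for (ni in seq_len(nrow(node_grid))) {
    node <- node_grid[ni, ]
    s <- (node - 1) * step + 1
    a_rng <- lapply(seq_len(nd), function(k) seq.int(s[k], s[k] + W[k] - 1))
    if (!is.null(mask)) {
      mfrac <- mean(subarr(mask, a_rng) != 0)
      if (mfrac < cfg$min_mask_fraction) next
    }
    a_win <- subarr(frame_a, a_rng)
    if (all(a_win == 0)) next

    score[] <- Inf
    for (di in seq_len(nrow(disp_grid))) {
      d <- disp_grid[di, ]
      bs <- s + d
      be <- bs + W - 1
      lo <- pmax(bs, 1)
      hi <- pmin(be, dims)
      if (any(lo > hi)) next
      b_rng <- lapply(seq_len(nd), function(k) seq.int(lo[k], hi[k]))
      # matching portion of the (clipped) interrogation window
      aw_rng <- lapply(seq_len(nd), function(k) {
        seq.int(lo[k] - bs[k] + 1, hi[k] - bs[k] + 1)
      })
      aa <- subarr(a_win, aw_rng)
      bb <- subarr(frame_b, b_rng)
      den <- sqrt(sum(aa^2) * sum(bb^2))
      if (den == 0) next
      score[di] <- sum((aa - bb)^2) / den
    }
    if (all(is.infinite(score))) next

    best <- arrayInd(which.min(score), n_disp)[1, ]
    d_best <- vapply(seq_len(nd), function(k) disp_ax[[k]][best[k]], numeric(1))
    delta <- numeric(nd)
    # a score of exactly 0 is a perfect match; refinement could only add noise
    if (cfg$subpixel && score[matrix(best, 1)] > 0) {
      for (k in seq_len(nd)) {
        if (best[k] <= 1 || best[k] >= n_disp[k]) next  # peak touches border
        i_m <- best; i_m[k] <- best[k] - 1
        i_p <- best; i_p[k] <- best[k] + 1
        s_m <- score[matrix(i_m, 1)]
        s_0 <- score[matrix(best, 1)]
        s_p <- score[matrix(i_p, 1)]
        if (!is.finite(s_m) || !is.finite(s_p)) next
        den <- s_m - 2 * s_0 + s_p
        if (den <= 0) next
        delta[k] <- max(-0.5, min(0.5, 0.5 * (s_m - s_p) / den))
      }
    }
    v_idx <- cbind(1, matrix(node, nrow = nd, ncol = nd, byrow = TRUE),
                   seq_len(nd))
    vec[v_idx] <- d_best + delta
    val[cbind(1, matrix(node, 1))] <- 1
  }

  vector_field_sequence(
    vec, val,
    grid_step = step,
    grid_origin = (W + 1) / 2
  )
}

#' PIV over an image sequence
#'
#' Computes PIV between each pair of consecutive frames, on one shared grid
#' and with one static mask, so all time steps share the same set of node
#' coordinates.
#'
#' @param images numeric array `(T, <spatial dims>)` with `T >= 2` frames.
#' @param mask optional binary array matching one frame's spatial shape.
#' @param cfg a [piv_config()].
#' @return A `vector_field_sequence` with `T - 1` time steps.
#' @export
compute_piv_sequence <- function(images, mask = NULL, cfg = piv_config()) {
  dims <- dim(images)
  if (is.null(dims) || length(dims) < 3) {
    stop("`images` must be an array (T, <spatial dims>)")
  }
  tt <- dims[1]
  if (tt < 2) stop("at least 2 frames are required")
  nd <- length(dims) - 1L
  slices <- vector("list", tt - 1)
  for (t in seq_len(tt - 1)) {
    fa <- subarr(images, c(list(t), lapply(dims[-1], seq_len)))
    dim(fa) <- dims[-1]
    fb <- subarr(images, c(list(t + 1), lapply(dims[-1], seq_len)))
    dim(fb) <- dims[-1]
    slices[[t]] <- compute_piv_pair(fa, fb, mask = mask, cfg = cfg)
  }
  vecs <- array(0, c(tt - 1, grid_shape(slices[[1]]), nd))
  vals <- array(0, c(tt - 1, grid_shape(slices[[1]])))
  nspace <- prod(grid_shape(slices[[1]])) * nd
  nval <- prod(grid_shape(slices[[1]]))
  for (t in seq_len(tt - 1)) {
    vecs[slice_index(tt - 1, t, nspace)] <- slices[[t]]$vectors
    vals[slice_index(tt - 1, t, nval)] <- slices[[t]]$validity
  }
  vector_field_sequence(vecs, vals,
                        grid_step = slices[[1]]$grid_step,
                        grid_origin = slices[[1]]$grid_origin)
}

# linear indices of time-slice t in an array whose first dim has length tn
# and whose remaining dims hold n elements
slice_index <- function(tn, t, n) {
  t + tn * (seq_len(n) - 1)
}
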