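#' Wave segmentation parameters
#'
#' Thresholds controlling which two-phase motion patterns count as a
#' contraction wave. All angles are in degrees; speed thresholds are in
#' px/frame (2D) or vx/frame (3D); `M_total` is in px (or vx). Presets
#' bundle the parameter sets used for the three standard data
#' representations: 2D lateral maximum-intensity projections (`"lateral"`),
#' 3D fused volumes (`"volume"`) and 2D cylinder projections (`"cylinder"`).
#'
#' The angle thresholds enter the algorithm through their cosines: a vector
#' is "aligned within `theta`" when the normalized dot product exceeds
#' `cos(theta)`, and the V/D separation requires the dot product of the two
#' phase representatives to be *below* `cos(theta_VD)`. Angle comparisons
#' are strict (`>` / `<`); magnitude comparisons are inclusive (`>=`).
#'
#' @param preset optional preset name (`"lateral"`, `"volume"`,
#'   `"cylinder"`); explicit arguments override preset values.
#' @param theta_r allowable angular deviation of the V-phase representative
#'   vector around the reference direction, degrees.
#' @param theta_V,theta_D intra-phase coherence angle for the V and D phase
#'   expansions, degrees.
#' @param theta_VD minimum angular separation between the V and D
#'   representatives, degrees.
#' @param M_min minimum per-frame vector magnitude for a frame to join a
#'   phase, px(vx)/frame.
#' @param M_avg minimum mean speed of the V phase, px(vx)/frame.
#' @param M_total minimum total displacement (sum of magnitudes over V and
#'   D), px(vx).
#' @param window_N sliding-window half-width (frames) of the direction
#'   similarity score; the window spans `2 * window_N + 1` frames.
#' @param max_gap largest tolerated gap (frames) between the V and D
#'   segmentations before the candidate is discarded.
#' @param enforce_dorsal_halfplane logical; additionally require the D-phase
#'   representative to have a positive component along the dorsal axis
#'   (used for lateral projections, where a single dorsal axis exists).
#' @return An object of class `wave_params`.
#' @export
wave_params <- function(preset = NULL, theta_r = 40, theta_V = 60,
                        theta_D = 60, theta_VD = 30, M_min = 0.5,
                        M_avg = 1.0, M_total = 10, window_N = 2, max_gap = 2,
                        enforce_dorsal_halfplane = FALSE) {
  if (!is.null(preset)) {
    presets <- list(
      lateral = list(theta_r = 40, theta_V = 60, theta_D = 60, theta_VD = 30,
                     M_min = 0.5, M_avg = 1.0, M_total = 10,
                     enforce_dorsal_halfplane = TRUE),
      volume = list(theta_r = 50, theta_V = 60, theta_D = 60, theta_VD = 30,
                    M_min = 0.5, M_avg = 1.0, M_total = 10,
                    enforce_dorsal_halfplane = FALSE),
      cylinder = list(theta_r = 50, theta_V = 40, theta_D = 40, theta_VD = 30,
                      M_min = 1.0, M_avg = 3.0, M_total = 10,
                      enforce_dorsal_halfplane = FALSE)
    )
    if (!preset %in% names(presets)) {
      stop("unknown preset: ", preset, " (use lateral, volume or cylinder)")
    }
    p <- presets[[preset]]
    supplied <- names(match.call())[-1]
    for (nm in names(p)) {
      if (!nm %in% supplied) assign(nm, p[[nm]])
    }
  }
  p <- list(theta_r = theta_r, theta_V = theta_V, theta_D = theta_D,
            theta_VD = theta_VD, M_min = M_min, M_avg = M_avg,
            M_total = M_total, window_N = as.integer(window_N),
            max_gap = as.integer(max_gap),
            enforce_dorsal_halfplane = isTRUE(enforce_dorsal_halfplane))
  for (a in c("theta_r", "theta_V", "theta_D", "theta_VD")) {
    if (p[[a]] <= 0 || p[[a]] >= 180) stop(a, " must be in (0, 180) degrees")
  }
  if (p$M_min < 0 || p$M_avg < 0 || p$M_total < 0) {
    stop("magnitude thresholds must be >= 0")
  }
  if (p$window_N < 1) stop("window_N must be >= 1")
  if (p$max_gap < 0) stop("max_gap must be >= 0")
  structure(p, class = "wave_params")
}

#' @export
print.wave_params <- function(x, ...) {
  cat("<wave_params>\n")
  cat(sprintf("  theta_r=%g  theta_V=%g  theta_D=%g  theta_VD=%g (deg)\n",
              x$theta_r, x$theta_V, x$theta_D, x$theta_VD))
  cat(sprintf("  M_min=%g  M_avg=%g (per frame)  M_total=%g\n",
              x$M_min, x$M_avg, x$M_total))
  cat(sprintf("  window_N=%d  max_gap=%d  dorsal halfplane: %s\n",
              x$window_N, x$max_gap, x$enforce_dorsal_halfplane))
  invisible(x)
}

#' Reference direction field
#'
#' The a-priori unit direction the V phase is expected to follow, either one
#' constant vector broadcast over the grid or a per-node field (needed when
#' the ventral direction varies across the map, e.g. on cylinder
#' projections). Components follow array axis order: `(y, x)` in 2D with the
#' row axis as the dorsoventral axis (ventral = negative y), `(z, y, x)` in
#' 3D.
#'
#' Presets:
#' \describe{
#'   \item{`"lateral"`}{`r = (-sin 45, -cos 45)` in `(y, x)` order, i.e. the
#'     posteroventral diagonal, with dorsal axis `(+1, 0)`.}
#'   \item{`"volume"`}{the 3D ventral direction tilted by 8.4 degrees about
#'     the anteroposterior axis, `(z, y, x) =
#'     (-cos 45 cos 8.4, sin 45 cos 8.4, -sin 8.4)`.}
#' }
#' For cylinder projections use [cylinder_reference_field()].
#'
#' @param r unit vector (constant reference) or array `(<grid dims>, D)` of
#'   per-node unit vectors; or a preset name.
#' @param dorsal_axis optional unit vector of the dorsal axis, required when
#'   `enforce_dorsal_halfplane` is on.
#' @return An object of class `reference_field`.
#' @export
reference_field <- function(r, dorsal_axis = NULL) {
  if (is.character(r)) {
    switch(r,
      lateral = {
        rr <- c(-sin(deg2rad(45)), -cos(deg2rad(45)))
        if (is.null(dorsal_axis)) dorsal_axis <- c(1, 0)
        r <- rr
      },
      volume = {
        r <- c(-cos(deg2rad(45)) * cos(deg2rad(8.4)),
               sin(deg2rad(45)) * cos(deg2rad(8.4)),
               -sin(deg2rad(8.4)))
      },
      stop("unknown reference preset: ", r)
    )
  }
  if (is.array(r) && length(dim(r)) >= 2) {
    nd <- dim(r)[length(dim(r))]
    nrm <- sqrt(apply(r^2, seq_len(length(dim(r)) - 1), sum))
    if (any(abs(nrm - 1) > 1e-9)) stop("per-node reference vectors must be unit-norm")
  } else {
    r <- as.numeric(r)
    if (abs(vec_norm(r) - 1) > 1e-9) stop("reference vector must be unit-norm")
  }
  if (!is.null(dorsal_axis) && abs(vec_norm(dorsal_axis) - 1) > 1e-9) {
    stop("dorsal_axis must be unit-norm")
  }
  structure(list(r = r, dorsal_axis = dorsal_axis), class = "reference_field")
}

#' Two-sided reference field for cylinder projections
#'
#' Cylinder maps show both lateral sides of the embryo, so the ventral
#' direction flips sign across the map: columns left of `split_col` get the
#' left-side reference and the remaining columns the mirrored one. Both
#' point ventrally (`ry = -sin 45`) with opposite `rx = -/+ cos 45`.
#'
#' @param grid_dims integer `(ny, nx)` node grid shape.
#' @param split_col first column of the right side (1-based).
#' @return A `reference_field` with a per-node direction array.
#' @export
cylinder_reference_field <- function(grid_dims, split_col) {
  stopifnot(length(grid_dims) == 2, split_col >= 1, split_col <= grid_dims[2] + 1)
  r <- array(0, c(grid_dims, 2))
  ry <- -sin(deg2rad(45))
  rx <- cos(deg2rad(45))
  for (j in seq_len(grid_dims[2])) {
    side <- if (j < split_col) -1 else 1
    r[, j, 1] <- ry
    r[, j, 2] <- side * rx
  }
  reference_field(r)
}

# reference vector at a node, for constant or per-node fields
ref_at <- function(refs, pos) {
  r <- refs$r
  if (is.array(r) && length(dim(r)) >= 2) {
    nd <- dim(r)[length(dim(r))]
    idx <- c(as.list(pos), list(seq_len(nd)))
    as.numeric(do.call(`[`, c(list(r), idx, list(drop = TRUE))))
  } else {
    r
  }
}
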