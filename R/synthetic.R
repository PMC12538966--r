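#' Specification of one injected two-phase wave
#'
#' Describes a ground-truth contraction wave: a spatial region (a disk on
#' the node grid), a start frame, the durations, directions and speeds of
#' its V and D phases, and an optional linear onset ramp. Directions use
#' `(y, x)` component order like the rest of the package.
#'
#' @param center disk centre `(y, x)` in node coordinates.
#' @param radius disk radius in nodes.
#' @param t_start first frame of the V phase.
#' @param V_duration,D_duration phase lengths in frames (>= 1).
#' @param V_direction,D_direction unit direction vectors.
#' @param V_speed,D_speed phase speeds in px/frame (> 0).
#' @param onset_ramp frames over which each phase ramps linearly up to full
#'   speed (0 = sharp onset).
#' @return An object of class `wave_spec`.
#' @export
wave_spec <- function(center, radius, t_start, V_duration, D_duration,
                      V_direction, D_direction, V_speed = 2, D_speed = 1.5,
                      onset_ramp = 0) {
  if (V_duration < 1 || D_duration < 1) stop("phase durations must be >= 1")
  if (V_speed <= 0 || D_speed <= 0) stop("phase speeds must be > 0")
  for (d in list(V_direction, D_direction)) {
    if (abs(vec_norm(d) - 1) > 1e-9) stop("phase directions must be unit-norm")
  }
  structure(
    list(center = center, radius = radius, t_start = as.integer(t_start),
         V_duration = as.integer(V_duration),
         D_duration = as.integer(D_duration),
         V_direction = V_direction, D_direction = D_direction,
         V_speed = V_speed, D_speed = D_speed,
         onset_ramp = as.integer(onset_ramp)),
    class = "wave_spec"
  )
}

disk_mask <- function(gs, center, radius) {
  yy <- matrix(seq_len(gs[1]), gs[1], gs[2])
  xx <- matrix(seq_len(gs[2]), gs[1], gs[2], byrow = TRUE)
  (yy - center[1])^2 + (xx - center[2])^2 <= radius^2
}

#' Synthetic vector field with injected two-phase waves
#'
#' Builds a ground-truth-bearing vector-field sequence: a background flow,
#' plus the specified wave phase vectors inside each spec's region and
#' frames, plus isotropic zero-mean Gaussian noise on every component. The
#' ground-truth label volume marks exactly the specified
#' (region x frame x phase) cells. Scenes are bit-reproducible from
#' `seed`.
#'
#' @param shape integer `(T, ny, nx)`: time steps and node grid shape.
#' @param specs list of [wave_spec()]s; waves sharing nodes must not
#'   overlap in time.
#' @param noise_sigma standard deviation of the additive component noise
#'   (px/frame).
#' @param background_flow constant `(y, x)` drift added everywhere.
#' @param seed RNG seed.
#' @return An object of class `synthetic_scene`: list with `fields` (a
#'   `vector_field_sequence`), `truth` (integer label array
#'   `(T, ny, nx)`), `specs` and `seed`.
#' @export
make_wave_field <- function(shape, specs = list(), noise_sigma = 0,
                            background_flow = c(0, 0), seed = 1) {
  stopifnot(length(shape) == 3)
  tt <- shape[1]
  gs <- shape[-1]
  if (inherits(specs, "wave_spec")) specs <- list(specs)
  vec <- array(0, c(tt, gs, 2))
  truth <- array(0L, c(tt, gs))
  claimed <- array(FALSE, c(tt, gs))
  nsp <- prod(gs)
  for (sp in specs) {
    region <- disk_mask(gs, sp$center, sp$radius)
    frames_v <- sp$t_start:(sp$t_start + sp$V_duration - 1)
    frames_d <- (sp$t_start + sp$V_duration):
      (sp$t_start + sp$V_duration + sp$D_duration - 1)
    if (min(frames_v) < 1 || max(frames_d) > tt) stop("wave exceeds the sequence")
    phase_amp <- function(i, dur) {
      if (sp$onset_ramp > 0 && i <= sp$onset_ramp) i / sp$onset_ramp else 1
    }
    for (phase in 1:2) {
      frames <- if (phase == 1) frames_v else frames_d
      dir <- if (phase == 1) sp$V_direction else sp$D_direction
      speed <- if (phase == 1) sp$V_speed else sp$D_speed
      for (i in seq_along(frames)) {
        t <- frames[i]
        cells <- which(region)
        tl <- t + tt * (cells - 1)
        if (any(claimed[tl])) {
          stop("overlapping wave specs at frame ", t)
        }
        claimed[tl] <- TRUE
        truth[tl] <- phase
        amp <- speed * phase_amp(i, length(frames))
        vec[tl] <- vec[tl] + amp * dir[1]
        vec[tl + tt * nsp] <- vec[tl + tt * nsp] + amp * dir[2]
      }
    }
  }
  vec[, , , 1] <- vec[, , , 1] + background_flow[1]
  vec[, , , 2] <- vec[, , , 2] + background_flow[2]
  if (noise_sigma > 0) {
    set.seed(seed)
    vec <- vec + array(rnorm(length(vec), 0, noise_sigma), dim(vec))
  }
  structure(
    list(fields = vector_field_sequence(vec), truth = truth,
         specs = specs, seed = seed),
    class = "synthetic_scene"
  )
}

#' Synthetic nuclei-like particle image sequence
#'
#' Gaussian spots (an idealized nuclear label under a light-sheet
#' microscope) advected frame by frame by a prescribed displacement,
#' rendered analytically at sub-pixel positions. Particles wrap around the
#' image borders so spot density is conserved (no births or deaths).
#'
#' @param shape integer `(T, ny, nx)`.
#' @param n_particles number of spots.
#' @param displacement per-frame displacement: a length-2 `(dy, dx)` vector
#'   (constant), a `(T-1) x 2` matrix, or a function `f(pos, t)` mapping an
#'   `n x 2` position matrix to an `n x 2` displacement matrix.
#' @param psf_sigma Gaussian spot radius in px.
#' @param photon_noise Gaussian noise scale; noise s.d. per pixel is
#'   `photon_noise * sqrt(intensity + 0.01)` (a Poisson-like approximation).
#' @param seed RNG seed.
#' @return numeric array `(T, ny, nx)` of intensities in `[0, ~1]`.
#' @export
make_particle_sequence <- function(shape, n_particles = 200,
                                   displacement = c(0, 0), psf_sigma = 1.5,
                                   photon_noise = 0, seed = 1) {
  stopifnot(length(shape) == 3, n_particles >= 1)
  tt <- shape[1]
  gs <- shape[-1]
  set.seed(seed)
  pos <- cbind(runif(n_particles, 1, gs[1]), runif(n_particles, 1, gs[2]))
  disp_at <- function(p, t) {
    if (is.function(displacement)) {
      displacement(p, t)
    } else if (is.matrix(displacement)) {
      matrix(displacement[t, ], nrow(p), 2, byrow = TRUE)
    } else {
      matrix(displacement, nrow(p), 2, byrow = TRUE)
    }
  }
  render <- function(p) {
    img <- matrix(0, gs[1], gs[2])
    r <- ceiling(4 * psf_sigma)
    for (i in seq_len(nrow(p))) {
      cy <- p[i, 1]; cx <- p[i, 2]
      ys <- max(1, floor(cy - r)):min(gs[1], ceiling(cy + r))
      xs <- max(1, floor(cx - r)):min(gs[2], ceiling(cx + r))
      g <- exp(-((ys - cy)^2) / (2 * psf_sigma^2)) %o%
        exp(-((xs - cx)^2) / (2 * psf_sigma^2))
      img[ys, xs] <- img[ys, xs] + g
    }
    img
  }
  out <- array(0, c(tt, gs))
  for (t in seq_len(tt)) {
    img <- render(pos)
    if (photon_noise > 0) {
      img <- img + matrix(rnorm(length(img), 0,
                                photon_noise * sqrt(pmax(img, 0) + 0.01)),
                          gs[1], gs[2])
    }
    out[t, , ] <- img
    if (t < tt) {
      pos <- pos + disp_at(pos, t)
      # wrap to conserve density
      pos[, 1] <- ((pos[, 1] - 1) %% gs[1]) + 1
      pos[, 2] <- ((pos[, 2] - 1) %% gs[2]) + 1
    }
  }
  out
}

#' Analytic cylinder-with-caps distortion grid
#'
#' Distortion factors for an idealized cylinder projection of a capsule
#' (cylinder body with spherical caps), the geometry of an insect egg. The
#' equatorial body rows carry no distortion (factors exactly 1). Toward the
#' poles the map shortens pole-to-pole distances, so the longitudinal
#' correction factor `1 / cos(alpha)` grows above 1, while the map
#' stretches circumferential distances, so the latitudinal factor
#' `cos(alpha)` shrinks below 1 (`alpha` = polar angle on the cap,
#' evaluated at each tile-row centre).
#'
#' @param shape_px map size `(H, W)` in pixels; axis 1 runs pole to pole.
#' @param cap_fraction fraction of the map height occupied by each polar
#'   cap, in (0, 0.5).
#' @param tile_size tile edge length in pixels (default 10).
#' @return A [distortion_grid()].
#' @export
make_cylinder_distortion <- function(shape_px, cap_fraction = 0.2,
                                     tile_size = 10) {
  stopifnot(length(shape_px) == 2)
  if (cap_fraction <= 0 || cap_fraction >= 0.5) {
    stop("cap_fraction must be in (0, 0.5)")
  }
  n_rows <- ceiling(shape_px[1] / tile_size)
  n_cols <- ceiling(shape_px[2] / tile_size)
  hc <- cap_fraction * shape_px[1]  # cap height in px
  lon <- matrix(1, n_rows, n_cols)
  lat <- matrix(1, n_rows, n_cols)
  row_centers <- (seq_len(n_rows) - 0.5) * tile_size
  for (i in seq_len(n_rows)) {
    rc <- row_centers[i]
    # distance into the cap (from the cap base toward the pole), in px
    into_top <- hc - rc
    into_bot <- rc - (shape_px[1] - hc)
    into <- max(into_top, into_bot, 0)
    if (into > 0) {
      u <- min(into / hc, 0.999)  # sin(alpha); tile centres stay off the pole
      ca <- sqrt(1 - u^2)         # cos(alpha)
      lon[i, ] <- 1 / ca
      lat[i, ] <- ca
    }
  }
  distortion_grid(lon, lat, tile_size)
}

#' Miniature two-phase wave scene
#'
#' The package's default study scene: a 100-step vector-field sequence on a
#' 36 x 48 node grid mimicking, in miniature, a lateral-projection
#' recording of late embryonic development. Five contraction waves
#' (posteroventral V phase, 3 frames at 2 px/frame; dorsal D phase `= -V`
#' direction, 5 frames at 1.5 px/frame) recur in one lateral region before
#' the rupture frame (80), and one post-rupture wave follows in a shifted
#' region with its D direction rotated by 60 degrees (V-D angle 120
#' degrees instead of 180). Isotropic Gaussian vector noise of scale
#' `noise_sigma` is added everywhere.
#'
#' @param seed RNG seed.
#' @param noise_sigma vector-component noise s.d. (px/frame), default 0.2.
#' @return A `synthetic_scene` with an extra element `rupture_frame` (80).
#' @export
mini_embryo_scene <- function(seed = 1, noise_sigma = 0.2) {
  v_dir <- c(-sin(deg2rad(45)), -cos(deg2rad(45)))  # posteroventral
  d_pre <- -v_dir                                   # anterodorsal
  # post-rupture: D rotated 60 degrees from the pre-rupture D direction
  ang <- deg2rad(60)
  rot <- matrix(c(cos(ang), -sin(ang), sin(ang), cos(ang)), 2, 2)
  d_post <- as.numeric(rot %*% d_pre)
  pre_starts <- c(10, 24, 38, 52, 66)
  specs <- lapply(pre_starts, function(t0) {
    wave_spec(center = c(18, 20), radius = 10, t_start = t0,
              V_duration = 3, D_duration = 5,
              V_direction = v_dir, D_direction = d_pre,
              V_speed = 2.0, D_speed = 1.5)
  })
  specs[[length(specs) + 1]] <- wave_spec(
    center = c(18, 32), radius = 8, t_start = 86,
    V_duration = 3, D_duration = 5,
    V_direction = v_dir, D_direction = d_post,
    V_speed = 2.0, D_speed = 1.5
  )
  scene <- make_wave_field(c(100, 36, 48), specs, noise_sigma = noise_sigma,
                           seed = seed)
  scene$rupture_frame <- 80L
  scene
}
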