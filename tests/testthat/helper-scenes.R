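# Shared fixture builders (all generated in code).

lateral_ref <- function() c(-sin(pi / 4), -cos(pi / 4))

# the canonical worked series: quiet, 5 frames of speed 2 along r,
# 5 frames opposite, quiet again
canonical_series <- function(len = 30, v_frames = 11:15, d_frames = 16:20,
                             speed = 2) {
  r <- lateral_ref()
  s <- matrix(0, len, 2)
  s[v_frames, ] <- matrix(speed * r, length(v_frames), 2, byrow = TRUE)
  s[d_frames, ] <- matrix(-speed * r, length(d_frames), 2, byrow = TRUE)
  s
}

# random particle image for PIV tests
particle_image <- function(shape = c(80, 80), n = 150, sigma = 1.5,
                           seed = 1) {
  make_particle_sequence(c(1, shape), n_particles = n, psf_sigma = sigma,
                         seed = seed)[1, , ]
}

# circular shift of a matrix by integer (dy, dx)
circshift <- function(m, s) {
  ny <- nrow(m)
  nx <- ncol(m)
  m[((seq_len(ny) - 1 - s[1]) %% ny) + 1,
    ((seq_len(nx) - 1 - s[2]) %% nx) + 1]
}

# rotation matrix acting on (y, x) component vectors
rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2, 2, byrow = TRUE)
}
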