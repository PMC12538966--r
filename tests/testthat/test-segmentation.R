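r45 <- lateral_ref()

test_that("direction similarity behaves as a windowed alignment score", {
  s <- matrix(rep(3 * r45, each = 10), 10, 2)
  expect_equal(direction_similarity(s, r45, 2), rep(1, 10))
  expect_equal(direction_similarity(-s, r45, 2), rep(-1, 10))

  # three-term mean at the centre of (+r, -r, +r)
  s3 <- rbind(r45, -r45, r45)
  expect_equal(direction_similarity(s3, r45, 1)[2], 1 / 3)

  # bounded and magnitude invariant
  set.seed(21)
  sr <- matrix(rnorm(40), 20, 2)
  rho <- direction_similarity(sr, r45, 3)
  expect_true(all(rho >= -1 & rho <= 1))
  scales <- runif(20, 0.1, 10)
  expect_equal(direction_similarity(sr * scales, r45, 3), rho)

  expect_error(direction_similarity(matrix(0, 0, 2), r45, 2), "empty")
})

test_that("candidate pairs come from strict extrema with plateau-first rule", {
  expect_equal(nrow(find_candidate_pairs(1:10 / 10)), 0)
  p <- find_candidate_pairs(c(0, 1, 0, -1, 0))
  expect_equal(unname(p), matrix(c(2L, 4L), 1))

  # two bumps, each followed by a dip
  rho <- c(0, 1, 0, -1, 0, 2, 0, -2, 0)
  p2 <- find_candidate_pairs(rho)
  expect_equal(unname(p2), matrix(c(2L, 6L, 4L, 8L), 2))

  # plateau maxima take their first frame
  p3 <- find_candidate_pairs(c(0, 1, 1, 0, -1, 0))
  expect_equal(unname(p3), matrix(c(2L, 5L), 1))
})

test_that("candidate screening applies reference, separation and half-plane rules", {
  params <- wave_params(preset = "lateral")
  s <- matrix(0, 10, 2)
  s[3, ] <- 2 * r45
  s[7, ] <- -2 * r45
  expect_true(check_candidate(s, 3, 7, r45, params, c(1, 0))$accept)

  # representative 50 degrees off the reference with theta_r = 40
  s2 <- s
  s2[3, ] <- 2 * (rot2(50) %*% r45)
  chk <- check_candidate(s2, 3, 7, r45, params, c(1, 0))
  expect_false(chk$accept)
  expect_equal(chk$reason, "reference_angle")

  # V and D only 10 degrees apart with theta_VD = 30
  s3 <- s
  s3[7, ] <- 2 * (rot2(10) %*% r45)
  chk3 <- check_candidate(s3, 3, 7, r45, params, c(1, 0))
  expect_false(chk3$accept)
  expect_equal(chk3$reason, "vd_separation")

  # zero vector at an endpoint
  s4 <- s
  s4[7, ] <- 0
  expect_false(check_candidate(s4, 3, 7, r45, params, c(1, 0))$accept)

  # D pointing ventrally fails the dorsal half-plane check
  s5 <- s
  s5[7, ] <- 2 * (rot2(40) %*% r45)  # still ventral-ish
  chk5 <- check_candidate(s5, 3, 7, r45, params, c(1, 0))
  expect_false(chk5$accept)
  expect_equal(chk5$reason, "dorsal_halfplane")

  expect_error(check_candidate(s, 7, 3, r45, params), "range")
})

test_that("phase expansion grows to coherent, fast-enough frames", {
  s <- matrix(rep(2 * r45, each = 10), 10, 2)
  expect_equal(expand_phase(s, 5, 60, 0.5, c(1, 10)), 1:10)

  # magnitude gate stops at weak neighbours
  s2 <- s
  s2[4, ] <- 0.3 * r45
  s2[6, ] <- 0.3 * r45
  expect_equal(expand_phase(s2, 5, 60, 0.5, c(1, 10)), 5)

  # rotating series: growth stops when the deviation from the running
  # average exceeds the coherence angle; compare to explicit simulation
  s3 <- matrix(0, 15, 2)
  for (t in 1:15) s3[t, ] <- 2 * (rot2(15 * (t - 8)) %*% r45)
  got <- expand_phase(s3, 8, 40, 0.5, c(1, 15))
  want <- oracle_expand(s3, 8, 40, 0.5, 1, 15)
  expect_equal(got, want)
  expect_true(length(got) < 15)  # the rotation does break coherence

  expect_error(expand_phase(matrix(0, 5, 2), 3, 60, 0.5, c(1, 5)), "zero")
})

test_that("interface frames are assigned to the best-matching phase", {
  s <- matrix(0, 12, 2)
  s[2:4, ] <- matrix(2 * r45, 3, 2, byrow = TRUE)
  s[8:10, ] <- matrix(-2 * r45, 3, 2, byrow = TRUE)

  # adjacent sets pass through unchanged
  s0 <- rbind(s[1:6, ], s[8:12, ])
  res0 <- assign_interface(s, 2:4, 5:8, max_gap = 2)
  expect_true(res0$accept)

  # gap frame close to the V direction joins V
  s[5, ] <- 0.1 * (rot2(5) %*% r45)
  res <- assign_interface(s, 2:4, 8:10, max_gap = 3)
  expect_true(res$accept)
  expect_true(5 %in% res$V)

  # exact angular tie goes to V
  s_tie <- matrix(0, 6, 2)
  s_tie[1:2, ] <- matrix(c(1, 0), 2, 2, byrow = TRUE)
  s_tie[5:6, ] <- matrix(c(-1, 0), 2, 2, byrow = TRUE)
  s_tie[3, ] <- c(0, 1)  # orthogonal to both phase averages
  res_tie <- assign_interface(s_tie, 1:2, 5:6, max_gap = 3)
  expect_true(3 %in% res_tie$V)

  # gap beyond max_gap rejects the wave
  res_far <- assign_interface(s, 2:4, 8:10, max_gap = 2)
  expect_false(res_far$accept)

  expect_error(assign_interface(s, 2:5, 5:8, 2), "overlap")
})

test_that("speed filtering enforces M_avg and M_total", {
  params <- wave_params(preset = "lateral")
  rec <- list(mean_speed_V = 0.8, total_displacement = 20)
  expect_false(filter_wave(rec, params))

  # V: 3 frames at 2.0, D: 3 frames at 1.5 -> total 10.5 >= 10
  rec2 <- list(mean_speed_V = 2.0, total_displacement = 3 * 2 + 3 * 1.5)
  expect_true(filter_wave(rec2, params))

  rec3 <- list(mean_speed_V = 2.0, total_displacement = 9.9)
  expect_false(filter_wave(rec3, params))
})

test_that("the canonical two-phase series yields exactly one wave", {
  s <- canonical_series()
  w <- segment_position(s, r45, wave_params(preset = "lateral"),
                        dorsal_axis = c(1, 0))
  expect_equal(nrow(w), 1)
  expect_equal(w$v_start, 11L)
  expect_equal(w$v_end, 15L)
  expect_equal(w$d_start, 16L)
  expect_equal(w$d_end, 20L)
  expect_equal(w$mean_speed_v, 2)
  expect_equal(w$total_displacement, 20)
})

test_that("repeated patterns yield one wave each; zero series yields none", {
  expect_equal(nrow(segment_position(matrix(0, 40, 2), r45,
                                     wave_params(preset = "lateral"),
                                     c(1, 0))), 0)
  # 5 repetitions separated by 10 quiet frames
  block <- canonical_series(len = 20, v_frames = 6:10, d_frames = 11:15)
  s <- do.call(rbind, rep(list(block), 5))
  w <- segment_position(s, r45, wave_params(preset = "lateral"), c(1, 0))
  expect_equal(nrow(w), 5)
  expect_equal(w$v_start, 6L + 20L * (0:4))
  expect_equal(w$d_end, 15L + 20L * (0:4))
})

test_that("widening theta_r never loses waves; raising M_avg never adds them", {
  set.seed(31)
  n_waves <- function(params) {
    count <- 0
    for (k in 1:30) {
      set.seed(k)
      s <- random_alphabet_series(12)
      count <- count + nrow(segment_position(s, r45, params, c(1, 0)))
    }
    count
  }
  thetas <- c(20, 40, 60, 90)
  counts <- sapply(thetas, function(th) {
    n_waves(wave_params(theta_r = th, theta_VD = 30, M_min = 0.5,
                        M_avg = 1, M_total = 3))
  })
  expect_true(all(diff(counts) >= 0))

  mavgs <- c(0.5, 1, 1.5, 2.5)
  counts_m <- sapply(mavgs, function(m) {
    n_waves(wave_params(theta_r = 60, theta_VD = 30, M_min = 0.5,
                        M_avg = m, M_total = 3))
  })
  expect_true(all(diff(counts_m) <= 0))
})

test_that("segmentation is equivariant under joint rotation of field and reference", {
  params <- wave_params(preset = "lateral",
                        enforce_dorsal_halfplane = FALSE)
  for (k in 1:10) {
    set.seed(100 + k)
    # continuous random vectors: generic position, no coincidental ties
    s <- matrix(rnorm(24, sd = 1.5), 12, 2)
    ang <- runif(1, 0, 360)
    R <- rot2(ang)
    s_rot <- t(R %*% t(s))
    r_rot <- as.numeric(R %*% r45)
    w1 <- segment_position(s, r45, params)
    w2 <- segment_position(s_rot, r_rot, params)
    expect_equal(w1[, c("t_max", "t_min", "v_start", "v_end",
                        "d_start", "d_end")],
                 w2[, c("t_max", "t_min", "v_start", "v_end",
                        "d_start", "d_end")])
  }
})

test_that("segment_position matches the brute-force oracle on random series", {
  params <- wave_params(preset = "lateral")
  set.seed(77)
  n_mismatch <- 0
  for (k in 1:300) {
    len <- sample(5:12, 1)
    s <- random_alphabet_series(len)
    got <- waves_as_list(segment_position(s, r45, params, c(1, 0)))
    want <- oracle_segment(s, r45, params, c(1, 0))
    if (!isTRUE(all.equal(got, want))) n_mismatch <- n_mismatch + 1
  }
  expect_equal(n_mismatch, 0)
})
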