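test_that("identical frames give zero displacement on all valid nodes", {
  img <- particle_image(c(64, 64), n = 120, seed = 3)
  cfg <- piv_config(interrogation_size = 24, search_margin = 4, grid_step = 12)
  vf <- compute_piv_pair(img, img, cfg = cfg)
  expect_true(all(vf$validity == 1))
  expect_true(all(vf$vectors == 0))
})

test_that("integer circular shifts are recovered exactly (subpixel off)", {
  img <- particle_image(c(80, 80), n = 200, seed = 5)
  cfg <- piv_config(interrogation_size = 24, search_margin = 5,
                    grid_step = 12, subpixel = FALSE)
  for (s in list(c(3, 2), c(-4, 4), c(5, 0), c(0, -5))) {
    shifted <- circshift(img, s)
    vf <- compute_piv_pair(img, shifted, cfg = cfg)
    gs <- grid_shape(vf)
    # interior nodes: circular wrap only affects windows at the image edge
    iy <- 2:(gs[1] - 1)
    ix <- 2:(gs[2] - 1)
    expect_true(all(vf$vectors[1, iy, ix, 1] == s[1]),
                info = paste("dy for shift", paste(s, collapse = ",")))
    expect_true(all(vf$vectors[1, iy, ix, 2] == s[2]),
                info = paste("dx for shift", paste(s, collapse = ",")))
  }
})

test_that("sub-pixel displacements are recovered within 0.2 px", {
  # render the same particles at positions p and p + delta (analytic, not
  # interpolated) and compare against the known fractional displacement
  delta <- c(0.4, -0.3)
  set.seed(11)
  imgs <- make_particle_sequence(c(2, 80, 80), n_particles = 200,
                                 displacement = delta, psf_sigma = 2,
                                 seed = 11)
  cfg <- piv_config(interrogation_size = 24, search_margin = 4,
                    grid_step = 12, subpixel = TRUE)
  vf <- compute_piv_pair(imgs[1, , ], imgs[2, , ], cfg = cfg)
  gs <- grid_shape(vf)
  iy <- 2:(gs[1] - 1)
  ix <- 2:(gs[2] - 1)
  err_y <- abs(vf$vectors[1, iy, ix, 1] - delta[1])
  err_x <- abs(vf$vectors[1, iy, ix, 2] - delta[2])
  expect_lt(max(err_y), 0.2)
  expect_lt(max(err_x), 0.2)
})

test_that("an all-zero mask invalidates every node", {
  img <- particle_image(c(64, 64), seed = 2)
  mask <- array(0, dim(img))
  vf <- compute_piv_pair(img, img, mask = mask,
                         cfg = piv_config(interrogation_size = 16,
                                          search_margin = 2))
  expect_true(all(vf$validity == 0))
  expect_true(all(vf$vectors == 0))
})

test_that("shrinking the mask never creates new valid nodes", {
  img <- particle_image(c(64, 64), seed = 7)
  cfg <- piv_config(interrogation_size = 16, search_margin = 2, grid_step = 8)
  set.seed(42)
  mask_big <- array(as.numeric(matrix(runif(64 * 64), 64) > 0.3), c(64, 64))
  mask_small <- mask_big
  mask_small[1:40, ] <- 0
  v_big <- compute_piv_pair(img, img, mask = mask_big, cfg = cfg)
  v_small <- compute_piv_pair(img, img, mask = mask_small, cfg = cfg)
  expect_true(all(v_small$validity <= v_big$validity))
})

test_that("PIV works on 3D volumes", {
  set.seed(9)
  vol <- array(runif(28^3), c(28, 28, 28))
  s <- c(2, -1, 1)
  shifted <- vol[((seq_len(28) - 1 - s[1]) %% 28) + 1,
                 ((seq_len(28) - 1 - s[2]) %% 28) + 1,
                 ((seq_len(28) - 1 - s[3]) %% 28) + 1]
  vf <- compute_piv_pair(vol, shifted,
                         cfg = piv_config(interrogation_size = 12,
                                          search_margin = 3, grid_step = 8,
                                          subpixel = FALSE))
  gs <- grid_shape(vf)
  mid <- as.list(ceiling(gs / 2))
  v_mid <- vf$vectors[1, mid[[1]], mid[[2]], mid[[3]], ]
  expect_equal(as.numeric(v_mid), s)
})

test_that("sequence PIV shares one grid and propagates a static mask", {
  img <- particle_image(c(64, 64), seed = 4)
  seq3 <- array(0, c(3, 64, 64))
  for (t in 1:3) seq3[t, , ] <- img
  cfg <- piv_config(interrogation_size = 16, search_margin = 2, grid_step = 8)
  vf <- compute_piv_sequence(seq3, cfg = cfg)
  expect_equal(n_steps(vf), 2)
  expect_true(all(vf$vectors == 0))

  # constant advection: every slice recovers (dy, dx)
  d <- c(3, 2)
  imgs <- make_particle_sequence(c(4, 72, 72), n_particles = 220,
                                 displacement = d, psf_sigma = 1.5, seed = 8)
  vfa <- compute_piv_sequence(imgs, cfg = piv_config(
    interrogation_size = 24, search_margin = 4, grid_step = 12,
    subpixel = FALSE))
  gs <- grid_shape(vfa)
  inner_y <- 2:(gs[1] - 1)
  inner_x <- 2:(gs[2] - 1)
  for (t in 1:3) {
    expect_true(all(abs(vfa$vectors[t, inner_y, inner_x, 1] - d[1]) <= 0.5))
    expect_true(all(abs(vfa$vectors[t, inner_y, inner_x, 2] - d[2]) <= 0.5))
  }

  # a mask restricted to a band keeps only band nodes valid
  mask <- array(0, c(64, 64))
  mask[1:24, ] <- 1
  vfm <- compute_piv_sequence(seq3, mask = mask, cfg = cfg)
  valid_rows <- which(rowSums(vfm$validity[1, , ]) > 0)
  expect_true(all(valid_rows <= 3))
  expect_true(any(vfm$validity == 1) && any(vfm$validity == 0))

  expect_error(compute_piv_sequence(array(0, c(1, 32, 32))), "2 frames")
})

test_that("average velocity matches direct computation and is rotation invariant", {
  vec <- array(0, c(4, 5, 6, 2))
  vec[, , , 1] <- 3
  vec[, , , 2] <- 4
  vf <- vector_field_sequence(vec)
  expect_equal(average_velocity(vf)$mean_speed, rep(5, 4))

  vec2 <- array(0, c(1, 2, 2, 2))
  vec2[1, 1, , 1] <- 0
  vec2[1, 2, , 1] <- 2
  expect_equal(average_velocity(vector_field_sequence(vec2))$mean_speed, 1)

  set.seed(13)
  vecr <- array(rnorm(3 * 4 * 5 * 2), c(3, 4, 5, 2))
  vfr <- vector_field_sequence(vecr)
  brute <- sapply(1:3, function(t) {
    mean(sapply(1:4, function(i) sapply(1:5, function(j) {
      sqrt(sum(vecr[t, i, j, ]^2))
    })))
  })
  expect_equal(average_velocity(vfr)$mean_speed, brute)

  R <- rot2(37)
  vrot <- vecr
  for (i in 1:4) for (j in 1:5) for (t in 1:3) {
    vrot[t, i, j, ] <- R %*% vecr[t, i, j, ]
  }
  expect_equal(average_velocity(vector_field_sequence(vrot))$mean_speed,
               average_velocity(vfr)$mean_speed)
})

test_that("PIV input validation", {
  img <- particle_image(c(32, 32), seed = 1)
  expect_error(compute_piv_pair(img, img[1:16, ]), "shape")
  expect_error(compute_piv_pair(img, img, mask = array(1, c(16, 16))), "shape")
  blank <- array(0, c(32, 32))
  vf <- compute_piv_pair(blank, blank,
                         cfg = piv_config(interrogation_size = 16,
                                          search_margin = 2))
  expect_true(all(vf$validity == 0))
})
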