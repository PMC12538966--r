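test_that("distortion correction multiplies components by their tile factors", {
  vec <- array(0, c(1, 4, 4, 2))
  vec[1, , , 1] <- 2
  vec[1, , , 2] <- 3
  vf <- vector_field_sequence(vec, grid_step = 10, grid_origin = 5)

  ident <- distortion_grid(matrix(1, 4, 4), matrix(1, 4, 4), tile_size = 10)
  expect_equal(correct_distortion(vf, ident)$vectors, vf$vectors)

  g <- distortion_grid(matrix(0.5, 4, 4), matrix(2, 4, 4), tile_size = 10)
  out <- correct_distortion(vf, g)
  expect_true(all(out$vectors[1, , , 1] == 1))
  expect_true(all(out$vectors[1, , , 2] == 6))

  # per-tile lookup is nearest-tile
  lon <- matrix(1, 4, 4)
  lon[2, ] <- 3
  g2 <- distortion_grid(lon, matrix(1, 4, 4), tile_size = 10)
  out2 <- correct_distortion(vf, g2)
  expect_true(all(out2$vectors[1, 2, , 1] == 6))
  expect_true(all(out2$vectors[1, c(1, 3, 4), , 1] == 2))

  # a node beyond the tile coverage is an error
  vf_big <- vector_field_sequence(vec, grid_step = 20, grid_origin = 5)
  expect_error(correct_distortion(vf_big, g), "outside")
})

test_that("correcting with a grid and then its reciprocal is the identity", {
  set.seed(17)
  vec <- array(rnorm(5 * 6 * 8 * 2), c(5, 6, 8, 2))
  vf <- vector_field_sequence(vec, grid_step = 10, grid_origin = 5)
  lon <- matrix(runif(48, 0.5, 2), 6, 8)
  lat <- matrix(runif(48, 0.5, 2), 6, 8)
  g <- distortion_grid(lon, lat, 10)
  back <- correct_distortion(correct_distortion(vf, g), invert_distortion(g))
  expect_equal(back$vectors, vf$vectors, tolerance = 1e-12)
  # direction signs are preserved per component
  once <- correct_distortion(vf, g)
  expect_true(all(sign(once$vectors) == sign(vf$vectors)))
})

test_that("the analytic capsule grid is undistorted at the equator and monotone poleward", {
  g <- make_cylinder_distortion(c(200, 120), cap_fraction = 0.25,
                                tile_size = 10)
  n <- nrow(g$longitudinal)
  mid <- (n %/% 2) + c(0, 1)
  expect_true(all(g$longitudinal[mid, ] == 1))
  expect_true(all(g$latitudinal[mid, ] == 1))
  # toward the top pole the longitudinal correction grows above 1 and the
  # latitudinal correction shrinks below 1
  top_lon <- g$longitudinal[1:5, 1]
  top_lat <- g$latitudinal[1:5, 1]
  expect_true(all(diff(top_lon) < 0))  # decreasing away from the pole
  expect_true(all(diff(top_lat) > 0))
  expect_true(all(top_lon >= 1))
  expect_true(all(top_lat <= 1))

  # longitudinal factor matches the numeric meridian arc length per tile:
  # with map coordinate u = sin(alpha) on the cap, the true arc per map
  # length is d(alpha)/d(u) = 1/cos(alpha)
  hc <- 0.25 * 200
  for (i in 1:4) {
    u_mid <- (hc - (i - 0.5) * 10) / hc
    expect_equal(g$longitudinal[i, 1], 1 / cos(asin(min(u_mid, 0.999))),
                 tolerance = 1e-9)
  }
  # away from the immediate pole, the tile-centre factor approximates the
  # exact mean arc ratio of its tile within 5%
  for (i in 2:4) {
    u1 <- (hc - i * 10) / hc
    u2 <- (hc - (i - 1) * 10) / hc
    arc <- asin(u2) - asin(u1)
    expect_lt(abs(g$longitudinal[i, 1] - arc / (u2 - u1)) / (arc / (u2 - u1)),
              0.05)
  }
})

test_that("corrected vector lengths approximate geodesic displacement on the cap", {
  # a vector of 10 map px along the meridian inside the cap, corrected by
  # its tile factor, should match the true arc length within 5%
  g <- make_cylinder_distortion(c(200, 120), cap_fraction = 0.25,
                                tile_size = 10)
  hc <- 50
  for (tile in 2:4) {
    u_lo <- (hc - tile * 10) / hc
    u_hi <- (hc - (tile - 1) * 10) / hc
    true_arc <- (asin(u_hi) - asin(u_lo)) * hc      # physical, R = hc px
    corrected <- 10 * g$longitudinal[tile, 1]
    expect_lt(abs(corrected - true_arc) / true_arc, 0.05)
  }
})

test_that("surface extraction recovers a spherical shell", {
  n <- 40
  cen <- (n + 1) / 2
  ax <- seq_len(n)
  dd <- array(0, c(n, n, n))
  for (z in ax) dd[z, , ] <- sqrt(outer((z - cen)^2 + (ax - cen)^2,
                                        (ax - cen)^2, `+`))
  vol <- array(0, c(n, n, n))
  vol[dd <= 13] <- 1  # solid bright ball of radius 13
  m <- extract_surface_mask(vol, threshold = 0.5, alpha = 1,
                            shell_in = 3, shell_out = 2)
  # shell of thickness shell_in + shell_out + 1 centred at radius 13
  inside <- dd <= 13 - 3 - 1.5
  outside <- dd >= 13 + 2 + 1.5
  band <- dd >= 13 - 3 + 0.5 & dd <= 13 + 2 - 0.5
  expect_true(all(m[inside] == 0))
  expect_true(all(m[outside] == 0))
  expect_gt(mean(m[band]), 0.97)
})

test_that("alpha bridges shell holes to a closed surface", {
  n <- 36
  cen <- (n + 1) / 2
  ax <- seq_len(n)
  dd <- array(0, c(n, n, n))
  for (z in ax) dd[z, , ] <- sqrt(outer((z - cen)^2 + (ax - cen)^2,
                                        (ax - cen)^2, `+`))
  shell <- array(0, c(n, n, n))
  shell[dd >= 10 & dd <= 12] <- 1
  # punch a ~5-voxel hole through the top cap
  zi <- slice.index(shell, 1)
  yi <- slice.index(shell, 2)
  xi <- slice.index(shell, 3)
  shell[zi <= cen - 9 & abs(yi - cen) <= 2 & abs(xi - cen) <= 2] <- 0
  m <- extract_surface_mask(shell, threshold = 0.5, alpha = 3,
                            shell_in = 1, shell_out = 1)
  # closed-shell property: flooding the background from the border never
  # reaches the centre
  open <- m == 0
  reached <- waveseg:::flood_from_border(open)
  expect_false(reached[cen, cen, cen])
  expect_error(extract_surface_mask(array(0, c(8, 8, 8)), 0.5), "foreground")
})

test_that("mask union is a voxelwise OR", {
  a <- array(0L, c(5, 5, 5))
  b <- array(0L, c(5, 5, 5))
  a[1:2, , ] <- 1L
  b[4:5, , ] <- 1L
  u <- combine_masks(list(a, b))
  expect_equal(sum(u), sum(a) + sum(b))
  expect_identical(combine_masks(list(a, a))[, , ], a[, , ])
  expect_identical(combine_masks(list(a, b)), combine_masks(list(b, a)))
  expect_error(combine_masks(list(a, array(0L, c(4, 4, 4)))), "differ")
})
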