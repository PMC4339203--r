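test_that("scale profile of a ramp matches the enumerated 26-shell value", {
  d <- c(12, 12, 12)
  v <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d) # v(x,y,z) = x
  pr <- scale_profile(v, center = c(6, 6, 6), scales = 2)
  # radius-1 Chebyshev shell: 18 of 26 offsets have |dx| = 1
  expect_equal(pr$mads[1], 18 / 26, tolerance = 1e-12)
  expect_equal(pr$n_pairs[1], 26L)
  expect_equal(pr$n_pairs[2], 98L)
})

test_that("scale profile equals brute-force shell enumeration", {
  set.seed(301)
  v <- array(rnorm(16^3), c(16, 16, 16))
  offs <- lapply(1:4, function(s) {
    o <- as.matrix(expand.grid(-s:s, -s:s, -s:s))
    o[pmax(abs(o[, 1]), abs(o[, 2]), abs(o[, 3])) == s, , drop = FALSE]
  })
  for (ctr in list(c(8, 8, 8), c(1, 2, 16), c(16, 1, 5))) {
    pr <- scale_profile(v, center = ctr, scales = 4)
    ref <- vapply(1:4, function(s) {
      q <- cbind(oracle_mirror(ctr[1] + offs[[s]][, 1], 16),
                 oracle_mirror(ctr[2] + offs[[s]][, 2], 16),
                 oracle_mirror(ctr[3] + offs[[s]][, 3], 16))
      mean(abs(v[q] - v[ctr[1], ctr[2], ctr[3]]))
    }, numeric(1))
    expect_equal(pr$mads, ref, tolerance = 1e-12)
  }
})

test_that("cropped profiles drop out-of-volume and out-of-mask pairs", {
  set.seed(302)
  v <- array(rnorm(10^3), c(10, 10, 10))
  pr <- scale_profile(v, center = c(1, 1, 1), scales = 2, boundary = "crop")
  expect_equal(pr$n_pairs[1], 7L)  # corner keeps the 2x2x2 cube minus itself
  m <- array(TRUE, dim(v)); m[, , 1] <- FALSE
  pr2 <- scale_profile(v, center = c(5, 5, 2), scales = 2, boundary = "crop",
                       mask = m)
  expect_equal(pr2$n_pairs[1], 17L) # 26 minus the 9 shell voxels in slice 1
})

test_that("Hurst regression recovers exact power laws and matches lm", {
  r <- 1:4
  pr <- list(distances = r, mads = 2.3 * r^0.7)
  fit <- hurst_regression(pr)
  expect_equal(fit$H, 0.7, tolerance = 1e-10)
  expect_equal(fit$intercept, log(2.3), tolerance = 1e-10)
  # constant increments: flat log-log line
  expect_equal(hurst_regression(list(distances = r, mads = rep(3, 4)))$H, 0,
               tolerance = 1e-12)
  # arbitrary 5-point profile against lm()
  set.seed(303)
  y <- exp(rnorm(5))
  fit2 <- hurst_regression(list(distances = 1:5, mads = y))
  ref <- unname(coef(lm(log(y) ~ log(1:5))))
  expect_equal(fit2$H, ref[2], tolerance = 1e-12)
  expect_equal(fit2$intercept, ref[1], tolerance = 1e-12)
  # zero scales are dropped; fewer than 2 left is an error
  expect_error(hurst_regression(list(distances = r, mads = c(0, 0, 0, 1))),
               class = "mnf_invalid_profile")
})

test_that("fractal map equals the per-voxel brute-force oracle", {
  set.seed(304)
  v <- array(rnorm(12^3), c(12, 12, 12))
  fm <- fractal_map(v, scales = 4)
  ref <- oracle_fractal_map(v, scales = 4)
  expect_equal(fm$fd, ref, tolerance = 1e-10)
})

test_that("fractal map is affine invariant and degenerates to FD 2 on flats", {
  v <- vol_data_for_test(make_fbm_volume(0.5, 24, seed = 305))
  fm <- fractal_map(v)
  fm2 <- fractal_map(3.7 * v + 12)
  expect_equal(fm2$fd, fm$fd, tolerance = 1e-9)
  const <- array(5, c(12, 12, 12))
  fmc <- fractal_map(const)
  expect_true(all(fmc$fd == 2))
  expect_true(all(fmc$degenerate))
})

test_that("ROI-mean FD tracks the roughness of fBm fields", {
  fd_means <- vapply(c(0.2, 0.5, 0.8), function(H) {
    v <- vol_data_for_test(make_fbm_volume(H, 48, seed = 306))
    subband_feature(fractal_map(v))
  }, numeric(1))
  # I = 3 - H: rougher fields (low H) have the higher fractal dimension
  expect_true(all(diff(fd_means) < 0))
  expect_true(all(fd_means >= 2 & fd_means <= 3))
})

test_that("subband features are masked means of the fractal map", {
  d <- c(6, 6, 6)
  fd <- array(2.4, d)
  fm <- structure(list(fd = fd, valid = array(TRUE, d)),
                  class = "fractal_map")
  expect_equal(subband_feature(fm), 2.4)
  fd2 <- array(rep(c(2, 3), each = prod(d) / 2), d)
  fm2 <- structure(list(fd = fd2, valid = array(TRUE, d)),
                   class = "fractal_map")
  expect_equal(subband_feature(fm2), 2.5)
  msk <- array(c(TRUE, FALSE), d)
  fm3 <- structure(list(fd = fd2, valid = msk), class = "fractal_map")
  acc <- 0; n <- 0
  for (i in seq_along(fd2)) if (msk[i]) { acc <- acc + fd2[i]; n <- n + 1 }
  expect_equal(subband_feature(fm3), acc / n)
})

test_that("differential termination stops when level differences stop growing", {
  expect_equal(mnf3d:::mnf_termination(c(0.20, 0.05)), 2L)
  expect_equal(mnf3d:::mnf_termination(c(0.05, 0.20, 0.10)), 3L)
  expect_equal(mnf3d:::mnf_termination(c(0.05, 0.20)), 2L) # unterminated: hits end
})

test_that("descriptor has 8 features per level per map and lies in [2,3]", {
  ph <- helper_phantom(1.1, 1.5, size = 32, seed = 307)
  pv <- fit_parametric_volume(ph$envelope, lattice_size = 5)
  de <- suppressMessages(mnf_descriptor(pv, max_levels = 3))
  expect_equal(length(de$features), 2 * 8 * de$levels_used)
  expect_true(all(de$features >= 2 & de$features <= 3))
  expect_equal(sum(grepl("^f_mu_L1_", names(de$features))), 8L)
  expect_equal(sum(grepl("^f_omega_L1_", names(de$features))), 8L)
  expect_equal(length(de$d_trace), de$levels_used)
  # pure function of its inputs
  de2 <- suppressMessages(mnf_descriptor(pv, max_levels = 3))
  expect_identical(de$features, de2$features)
})

test_that("descriptor is invariant to affine rescaling of the parametric maps", {
  ph <- helper_phantom(1.3, 2, size = 32, seed = 308)
  pv <- fit_parametric_volume(ph$envelope, lattice_size = 5)
  pv2 <- pv
  pv2$mu <- 3.7 * pv$mu + 12
  pv2$omega <- 0.4 * pv$omega + 5
  d1 <- suppressMessages(mnf_descriptor(pv, max_levels = 2))
  d2 <- suppressMessages(mnf_descriptor(pv2, max_levels = 2))
  expect_equal(unname(d1$features), unname(d2$features), tolerance = 1e-8)
})
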