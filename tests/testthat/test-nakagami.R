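test_that("density matches closed forms and normalizes", {
  # mu = 1 is the Rayleigh case: 2 x exp(-x^2) at omega = 1
  expect_equal(dnakagami(1, 1, 1), 2 * exp(-1), tolerance = 1e-14)
  sigma <- 0.8
  xg <- seq(0, 5, by = 0.05)
  expect_equal(dnakagami(xg, 1, 2 * sigma^2),
               xg / sigma^2 * exp(-xg^2 / (2 * sigma^2)),
               tolerance = 1e-12)
  # direct (non-log) evaluation of the density formula as oracle
  mu <- 2; omega <- 3; x <- 1.2
  direct <- 2 * (mu / omega)^mu / gamma(mu) * x^(2 * mu - 1) *
    exp(-mu * x^2 / omega)
  expect_equal(dnakagami(x, mu, omega), direct, tolerance = 1e-10)
  for (p in list(c(0.6, 2.5), c(1, 1), c(2, 3), c(0.8, 0.5), c(3, 7))) {
    q <- integrate(dnakagami, 0, Inf, mu = p[1], omega = p[2],
                   rel.tol = 1e-10)
    expect_lt(abs(q$value - 1), 1e-6)
  }
  expect_error(dnakagami(1, -1, 1), class = "mnf_parameter_error")
})

test_that("moment estimators reproduce the hand-computed example", {
  est <- estimate_moments(c(0.5, 1, 1.5, 2))
  # omega = mean(x^2) = 1.875; mu = omega^2 / (mean(x^4) - omega^2)
  expect_equal(est$omega, 1.875, tolerance = 1e-12)
  expect_equal(est$mu, 3.515625 / 2.015625, tolerance = 1e-12)
  expect_error(estimate_moments(c(2, 2, 2)), class = "mnf_degenerate_sample")
  expect_error(estimate_moments(numeric(0)), class = "mnf_insufficient_data")
})

test_that("MLE scale equals mean squared amplitude exactly", {
  for (i in 1:20) {
    x <- rnakagami(50 + 7 * i, mu = 0.4 + 0.2 * i, omega = 0.5 + i, seed = i)
    expect_equal(estimate_mle(x)$omega, mean(x^2), tolerance = 1e-12)
  }
})

test_that("MLE recovers parameters and satisfies its preconditions", {
  x <- rnakagami(1e5, 2, 1, seed = 55)
  fit <- estimate_mle(x)
  expect_lt(abs(fit$mu - 2) / 2, 0.03)
  expect_error(estimate_mle(1.5), class = "mnf_insufficient_data")
  expect_error(estimate_mle(rep(2, 20)), class = "mnf_degenerate_sample")
  expect_error(estimate_mle(c(-1, rnakagami(20, 1, 1, seed = 1))),
               class = "mnf_parameter_error")
})

test_that("MLE equals the independent Gamma fit on squared samples", {
  skip_if_not_installed("fitdistrplus")
  x <- rnakagami(5000, 1.3, 2.2, seed = 77)
  fit <- estimate_mle(x)
  ref <- fitdistrplus::fitdist(x^2, "gamma",
                               start = list(shape = 1, rate = 1))
  expect_equal(fit$mu, unname(ref$estimate["shape"]), tolerance = 1e-4)
})

test_that("MLE is scale equivariant", {
  x <- rnakagami(500, 0.9, 1.7, seed = 88)
  a <- estimate_mle(x)
  b <- estimate_mle(2.7 * x)
  expect_equal(b$mu, a$mu, tolerance = 1e-8)
  expect_equal(b$omega, 2.7^2 * a$omega, tolerance = 1e-10)
})

test_that("sliding parametric volume recovers a homogeneous field", {
  ph <- helper_phantom(1.5, 2.0, size = 32, seed = 91)
  pv <- fit_parametric_volume(ph$envelope, lattice_size = 7)
  expect_true(all(pv$mu[pv$valid] > 0))
  expect_lt(abs(mean(pv$mu[pv$valid]) - 1.5) / 1.5, 0.10)
  expect_lt(abs(mean(pv$omega[pv$valid]) - 2.0) / 2.0, 0.05)
  # the sliding estimate at a voxel equals the scalar MLE on its window
  win <- ph$envelope$data[13:19, 13:19, 13:19]
  ref <- estimate_mle(as.vector(win))
  expect_equal(pv$mu[16, 16, 16], ref$mu, tolerance = 1e-10)
  expect_equal(pv$omega[16, 16, 16], ref$omega, tolerance = 1e-12)
})

test_that("excluded voxels are never read (NaN poisoning)", {
  ph <- helper_phantom(1.2, 1.5, size = 24, seed = 93)
  v <- ph$envelope$data
  mask <- array(TRUE, dim(v))
  mask[1:12, , ] <- FALSE
  poisoned <- v
  poisoned[!mask] <- NaN
  for (stride in c("sliding", "block")) {
    pv <- fit_parametric_volume(poisoned, mask = mask, lattice_size = 5,
                                stride = stride)
    expect_true(all(!pv$valid[1:12, , ]))
    expect_true(all(is.finite(pv$mu[pv$valid])))
    clean <- fit_parametric_volume(v, mask = mask, lattice_size = 5,
                                   stride = stride)
    expect_identical(pv$mu, clean$mu)
  }
})

test_that("two-region phantom recovers the energy contrast", {
  spec <- phantom_spec(32, c(1, 1), inclusions = list(
    list(center = c(16, 16, 16), radius = 9, mu = 1, omega = 4)), seed = 95)
  ph <- make_phantom(spec)
  pv <- fit_parametric_volume(ph$envelope, lattice_size = 5)
  # judge only voxels whose whole 5-window sits in a single region
  ax <- 1:32
  rad <- sqrt(outer(outer((ax - 16)^2, (ax - 16)^2, `+`), (ax - 16)^2, `+`))
  inner <- rad <= 9 - 3
  outer_pure <- rad >= 9 + 3
  edge <- array(FALSE, dim(rad)); edge[4:29, 4:29, 4:29] <- TRUE
  ratio <- mean(pv$omega[inner & pv$valid]) /
    mean(pv$omega[outer_pure & edge & pv$valid])
  expect_gt(ratio, 3.2)
  expect_lt(ratio, 4.8)
})

test_that("empty ROI and tiny lattices are rejected", {
  ph <- helper_phantom(1, 1, size = 16, seed = 97)
  expect_error(fit_parametric_volume(ph$envelope,
                                     mask = array(FALSE, c(16, 16, 16))),
               class = "mnf_parameter_error")
  expect_error(fit_parametric_volume(ph$envelope, lattice_size = 1),
               class = "mnf_parameter_error")
  expect_error(optimize_lattice_size(ph$envelope, sizes = 1:5),
               class = "mnf_parameter_error")
})

test_that("lattice-size RMSE is flat for homogeneous texture, inflated by mixing", {
  ph <- helper_phantom(1.2, 2, size = 32, seed = 3)
  r <- optimize_lattice_size(ph$envelope, sizes = 2:12)
  expect_true(all(is.finite(r$rmse)))
  expect_lt((max(r$rmse) - min(r$rmse)) / mean(r$rmse), 0.15)

  ctrs <- as.matrix(expand.grid(c(8, 16, 24), c(8, 16, 24), c(8, 16, 24)))
  incs <- lapply(seq_len(nrow(ctrs)), function(i)
    list(center = ctrs[i, ], radius = 2.5, mu = 1, omega = 8))
  ph2 <- make_phantom(phantom_spec(32, c(1, 1), incs, seed = 4))
  sizes <- c(2, 3, 5, 7, 9, 12, 15)
  r2 <- optimize_lattice_size(ph2$envelope, sizes = sizes)
  expect_lt(r2$best, max(sizes))
  # lattices larger than the 5-voxel heterogeneity scale mix regions
  expect_gt(r2$rmse[sizes == 12], r2$rmse[sizes == 3])
})

test_that("scattering regimes follow the five-category scheme", {
  res <- classify_scattering(c(0.3, 0.5, 0.7, 1, 1.5), rep(1, 5))
  expect_equal(as.character(res$mu_category),
               c("pre-Rician", "generalized Rician", "pre-Rayleigh",
                 "Rayleigh", "post-Rayleigh"))
  reso <- classify_scattering(rep(1, 4), c(2.9, 3, 6.9, 7))
  expect_equal(as.character(reso$omega_category),
               c("low", "mid", "mid", "high"))
  # boundary tolerance on the measure-zero categories
  expect_equal(as.character(classify_scattering(1 + 1e-8, 1)$mu_category),
               "Rayleigh")
  expect_error(classify_scattering(-1, 1), class = "mnf_parameter_error")
})
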