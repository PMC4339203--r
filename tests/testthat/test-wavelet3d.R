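test_that("Daubechies filter pair satisfies the orthonormal filter-bank identities", {
  f <- daub8_filters()
  expect_equal(sum(f$h0), sqrt(2), tolerance = 1e-12)
  expect_equal(sum(f$h0^2), 1, tolerance = 1e-12)
  # double-shift orthogonality
  for (k in 1:3)
    expect_lt(abs(sum(f$h0[1:(8 - 2 * k)] * f$h0[(1 + 2 * k):8])), 1e-12)
  # quadrature mirror relation
  expect_equal(f$h1, (-1)^(0:7) * rev(f$h0), tolerance = 1e-15)
  # 4 vanishing moments annihilate cubics
  for (p in 0:3)
    expect_lt(abs(sum(f$h1 * (0:7)^p)), 1e-10)
})

test_that("octant step matches the brute-force tensor-product oracle", {
  set.seed(201)
  v <- array(rnorm(8^3), c(8, 8, 8))
  bands <- octant_step(v)
  ref <- oracle_octant_step(v)
  expect_named(bands, names(ref))
  for (nm in names(ref))
    expect_equal(bands[[nm]], ref[[nm]], tolerance = 1e-10)
})

test_that("dilated (level 2) octant step matches the oracle", {
  set.seed(202)
  v <- array(rnorm(16^3), c(16, 16, 16))
  bands <- octant_step(v, level = 2)
  ref <- oracle_octant_step(v, level = 2)
  for (nm in c("LLL", "HLH", "HHH"))
    expect_equal(bands[[nm]], ref[[nm]], tolerance = 1e-10)
})

test_that("constant volumes pass only through the lowpass path", {
  v <- array(3.7, c(10, 10, 10))
  bands <- octant_step(v)
  expect_equal(bands$LLL, array(3.7 * 2^(3 / 2), dim(v)), tolerance = 1e-12)
  for (nm in setdiff(names(bands), "LLL"))
    expect_lt(max(abs(bands[[nm]])), 1e-10)
})

test_that("highpass bands annihilate a linear ramp along their axis", {
  d <- c(16, 16, 16)
  v <- array(rep(seq_len(d[1]), times = prod(d[2:3])), d) # ramp along axis 1
  bands <- octant_step(v)
  interior <- 6:11
  for (nm in c("HLL", "HLH", "HHL", "HHH"))
    expect_lt(max(abs(bands[[nm]][interior, interior, interior])), 1e-8)
  # lowpass-along-x bands keep the ramp (sanity that the test can fail)
  expect_gt(max(abs(bands$LLL[interior, interior, interior])), 1)
})

test_that("volumes below the filter span are rejected with the minimum size", {
  v <- array(rnorm(7^3), c(7, 7, 7))
  expect_error(octant_step(v), "8")
  v16 <- array(rnorm(16^3), c(16, 16, 16))
  expect_error(octant_step(v16, level = 3), "32")
})

test_that("packet tree node counts follow the expansion policy", {
  set.seed(203)
  v <- array(rnorm(16^3), c(16, 16, 16))
  t1 <- wp_decompose(v, max_levels = 1)
  expect_length(t1$nodes, 1 + 8)           # root + 8 leaves
  t2 <- wp_decompose(v, max_levels = 2, policy = "full")
  expect_length(t2$nodes, 1 + 8 + 64)
  expect_true(all(vapply(t2$nodes, function(n) identical(dim(n), dim(v)),
                         logical(1))))
  expect_identical(t2$nodes$root, v)
  # depth clipping: a 16^3 volume cannot support level 3 (span 32)
  expect_warning(t3 <- wp_decompose(v, max_levels = 3, policy = "selective"),
                 "clipped")
  expect_equal(t3$levels, 2L)
})

test_that("selective policy expands the node with the largest fractal signature", {
  set.seed(204)
  v <- vol_data_for_test(make_fbm_volume(0.4, 24, seed = 204))
  tr <- wp_decompose(v, max_levels = 2, policy = "selective")
  # exactly one level-1 node got children
  lvl2 <- grep("/", names(tr$nodes), value = TRUE)
  parents <- unique(sub("/.*$", "", lvl2))
  expect_length(parents, 1L)
  expect_length(lvl2, 8L)
  # and it is the argmax of the independently computed signatures
  sig <- vapply(octant_step(v), function(b)
    subband_feature(fractal_map(b, scales = 4)), numeric(1))
  expect_identical(parents, names(sig)[which.max(sig)])
})

test_that("undecimated transform commutes with interior translation", {
  set.seed(205)
  d <- c(20, 20, 20)
  v <- array(rnorm(prod(d)), d)
  vs <- v
  vs[2:20, , ] <- v[1:19, , ] # shift content by +1 along axis 1
  b <- octant_step(v)
  bs <- octant_step(vs)
  keep <- 7:14 # interior: beyond filter span of the boundary
  for (nm in c("LLL", "HHH", "LHL"))
    expect_equal(bs[[nm]][keep + 1, keep, keep], b[[nm]][keep, keep, keep],
                 tolerance = 1e-10)
})

test_that("the transform is linear node-wise", {
  set.seed(206)
  d <- c(12, 12, 12)
  u <- array(rnorm(prod(d)), d)
  v <- array(rnorm(prod(d)), d)
  a <- 2.5; b <- -1.3
  mix <- octant_step(a * u + b * v)
  bu <- octant_step(u)
  bv <- octant_step(v)
  for (nm in names(mix))
    expect_equal(mix[[nm]], a * bu[[nm]] + b * bv[[nm]], tolerance = 1e-8)
})

test_that("white noise energizes all eight level-1 bands", {
  set.seed(207)
  v <- array(rnorm(12^3), c(12, 12, 12))
  bands <- octant_step(v)
  energies <- vapply(bands, function(x) sum(x^2), numeric(1))
  expect_true(all(energies > 0))
})
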