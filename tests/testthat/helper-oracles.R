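# Independent brute-force oracles used by the unit and acceptance tests.
# These deliberately avoid the package's code paths: mirror reflection via
# an explicit periodic index table, the octant transform via the direct
# tensor-product definition, and the fractal map via per-voxel shell
# enumeration with lm()-based regression.

# mirror reflection through an explicit reflected period table
oracle_mirror <- function(i, n) {
  if (n == 1) return(rep(1L, length(i)))
  period <- c(seq_len(n), seq(n - 1, 2))
  period[((i - 1) %% length(period)) + 1]
}

# direct tensor-product octant transform: each output voxel is the full
# 8 x 8 x 8 weighted sum over mirrored tap positions
oracle_octant_step <- function(v, level = 1) {
  f <- daub8_filters()
  d <- dim(v)
  dil <- 2^(level - 1)
  taps <- ((1:8) - 5) * dil
  weights <- list()
  for (a in c("L", "H")) for (b in c("L", "H")) for (cc in c("L", "H")) {
    ha <- if (a == "L") f$h0 else f$h1
    hb <- if (b == "L") f$h0 else f$h1
    hc <- if (cc == "L") f$h0 else f$h1
    weights[[paste0(a, b, cc)]] <- outer(outer(ha, hb), hc)
  }
  out <- lapply(weights, function(w) array(0, d))
  for (x in seq_len(d[1])) {
    xi <- oracle_mirror(x + taps, d[1])
    for (y in seq_len(d[2])) {
      yi <- oracle_mirror(y + taps, d[2])
      for (z in seq_len(d[3])) {
        zi <- oracle_mirror(z + taps, d[3])
        tb <- v[xi, yi, zi]
        for (nm in names(weights))
          out[[nm]][x, y, z] <- sum(weights[[nm]] * tb)
      }
    }
  }
  out
}

# per-voxel shell enumeration + lm() log-log regression fractal map
oracle_fractal_map <- function(v, scales = 4) {
  d <- dim(v)
  offs <- lapply(seq_len(scales), function(s) {
    o <- as.matrix(expand.grid(-s:s, -s:s, -s:s))
    o[pmax(abs(o[, 1]), abs(o[, 2]), abs(o[, 3])) == s, , drop = FALSE]
  })
  # each shell's regression abscissa is its mean Euclidean pair distance
  dists <- vapply(offs, function(o) mean(sqrt(rowSums(o^2))), numeric(1))
  fd <- array(NA_real_, d)
  for (x in seq_len(d[1])) for (y in seq_len(d[2])) for (z in seq_len(d[3])) {
    mads <- vapply(seq_len(scales), function(s) {
      q <- cbind(oracle_mirror(x + offs[[s]][, 1], d[1]),
                 oracle_mirror(y + offs[[s]][, 2], d[2]),
                 oracle_mirror(z + offs[[s]][, 3], d[3]))
      mean(abs(v[q] - v[x, y, z]))
    }, numeric(1))
    ok <- mads > 0
    h <- if (sum(ok) < 2) 1 else
      unname(coef(lm(log(mads[ok]) ~ log(dists[ok])))[2])
    fd[x, y, z] <- 3 - min(max(h, 0), 1)
  }
  fd
}

# pooled axis-aligned increment estimate of the Hurst exponent of a field
oracle_pooled_hurst <- function(v, scales = 4) {
  mad_axis <- function(d) {
    n <- dim(v)
    mean(c(abs(v[seq_len(n[1] - d) + d, , ] - v[seq_len(n[1] - d), , ]),
           abs(v[, seq_len(n[2] - d) + d, ] - v[, seq_len(n[2] - d), ]),
           abs(v[, , seq_len(n[3] - d) + d] - v[, , seq_len(n[3] - d)])))
  }
  y <- vapply(seq_len(scales), mad_axis, numeric(1))
  unname(coef(lm(log(y) ~ log(seq_len(scales))))[2])
}

# small homogeneous phantom for parametric-fit tests
helper_phantom <- function(mu, omega, size = 32, seed = 1) {
  make_phantom(phantom_spec(size, c(mu, omega), seed = seed))
}

vol_data_for_test <- function(x) as.array(x)
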