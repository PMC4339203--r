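#' Sample Nakagami-distributed envelope amplitudes
#'
#' Draws i.i.d. amplitudes from the Nakagami distribution with shape `mu`
#' and scale `omega`. If x is Nakagami(mu, omega) then x^2 is
#' Gamma(shape = mu, scale = omega / mu), so sampling is exact via a Gamma
#' transform — no rejection step. At `mu = 1` the law reduces to
#' Rayleigh(sigma) with `omega = 2 sigma^2`.
#'
#' @param n number of draws (>= 1).
#' @param mu shape parameter (> 0); governs the scattering regime.
#' @param omega scale parameter (> 0); equals the mean squared amplitude
#'   (local backscattered energy).
#' @param seed optional integer seed; when given, the draw is a pure
#'   function of `(n, mu, omega, seed)` and the global RNG state is left
#'   untouched.
#' @return Numeric vector of `n` positive amplitudes.
#' @export
rnakagami <- function(n, mu, omega, seed = NULL) {
  check_positive_scalar(mu, "mu")
  check_positive_scalar(omega, "omega")
  if (!is.numeric(n) || length(n) != 1L || n < 1)
    stop_mnf("mnf_parameter_error", "'n' must be a positive count")
  local_seed(seed, sqrt(rgamma(n, shape = mu, scale = omega / mu)))
}

#' Specify a speckle lesion phantom
#'
#' Describes a 3D Nakagami speckle phantom: homogeneous background speckle
#' plus spherical inclusions at controlled (mu, omega) contrast, emulating
#' gray-scale lesion targets of a few voxels to tens of voxels in diameter.
#' An inclusion may optionally carry a spatially correlated texture: its
#' omega field is modulated by a log-normal fractional-Brownian-motion
#' surface with Hurst exponent `hurst` and log-amplitude `texture_amp`,
#' emulating heterogeneous backscattered energy inside a lesion (smooth,
#' necrotic-like texture at high `hurst`; rough, active-like texture at low
#' `hurst`).
#'
#' @param grid_size integer length-3 (or scalar) voxels per axis.
#' @param background numeric `c(mu, omega)` of the background speckle.
#' @param inclusions list of inclusions, each a list with `center` (voxel
#'   coordinates, length 3), `radius` (voxels, > 0), `mu`, `omega`, and
#'   optionally `hurst` in (0,1) and `texture_amp` (>= 0, default 0.5 when
#'   `hurst` is given).
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size, background, inclusions = list(), seed = 1L) {
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 3L)
  grid_size <- as.integer(grid_size)
  if (length(grid_size) != 3L || any(grid_size < 4L))
    stop_mnf("mnf_parameter_error", "'grid_size' must be 3 axis sizes >= 4")
  if (length(background) != 2L || any(background <= 0))
    stop_mnf("mnf_parameter_error", "'background' must be positive c(mu, omega)")
  for (inc in inclusions) {
    if (is.null(inc$center) || is.null(inc$radius) ||
        is.null(inc$mu) || is.null(inc$omega))
      stop_mnf("mnf_parameter_error",
               "each inclusion needs center, radius, mu, omega")
    if (inc$radius <= 0 || inc$mu <= 0 || inc$omega <= 0)
      stop_mnf("mnf_parameter_error",
               "inclusion radius, mu and omega must be positive")
    if (any(inc$center - inc$radius < 1) ||
        any(inc$center + inc$radius > grid_size))
      stop_mnf("mnf_parameter_error", "inclusion must lie within the grid")
    if (!is.null(inc$hurst) && (inc$hurst <= 0 || inc$hurst >= 1))
      stop_mnf("mnf_parameter_error", "inclusion 'hurst' must be in (0, 1)")
  }
  structure(list(grid_size = grid_size,
                 background = as.numeric(background),
                 inclusions = inclusions,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a speckle lesion phantom volume
#'
#' Draws every voxel from its region's Nakagami law: background voxels from
#' the background (mu, omega), inclusion voxels from their inclusion's
#' parameters (with optional fBm-modulated omega, see [phantom_spec()]).
#' The companion label volume marks background as 0 and the i-th inclusion
#' as i. Overlapping inclusions are rejected because voxel labels would be
#' ambiguous.
#'
#' @param spec a [phantom_spec()].
#' @param spacing voxel spacing in mm passed to the output volume.
#' @return list with `envelope` (an [envelope_volume()]) and `labels`
#'   (integer array of region indices).
#' @export
make_phantom <- function(spec, spacing = c(1, 1, 1)) {
  if (!inherits(spec, "phantom_spec"))
    stop_mnf("mnf_parameter_error", "'spec' must be a phantom_spec")
  d <- spec$grid_size
  labels <- array(0L, d)
  balls <- vector("list", length(spec$inclusions))
  if (length(spec$inclusions)) {
    ax <- lapply(1:3, function(a) seq_len(d[a]))
    for (i in seq_along(spec$inclusions)) {
      inc <- spec$inclusions[[i]]
      dx2 <- outer(outer((ax[[1]] - inc$center[1])^2,
                         (ax[[2]] - inc$center[2])^2, `+`),
                   (ax[[3]] - inc$center[3])^2, `+`)
      ball <- dx2 <= inc$radius^2
      if (any(labels[ball] != 0L))
        stop_mnf("mnf_overlap_error",
                 "inclusions %d and %d overlap: labels would be ambiguous",
                 unique(labels[ball][labels[ball] != 0L])[1], i)
      labels[ball] <- i
      balls[[i]] <- ball
    }
  }
  nvox <- prod(d)
  env <- local_seed(spec$seed, {
    x <- array(rnakagami(nvox, spec$background[1], spec$background[2]), d)
    for (i in seq_along(spec$inclusions)) {
      inc <- spec$inclusions[[i]]
      idx <- which(balls[[i]])
      omega_vox <- rep(inc$omega, length(idx))
      if (!is.null(inc$hurst)) {
        amp <- if (is.null(inc$texture_amp)) 0.5 else inc$texture_amp
        tex_seed <- sample.int(.Machine$integer.max - 1L, 1L)
        field <- vol_data(make_fbm_volume(inc$hurst, d, seed = tex_seed,
                                          min_size = 4L))
        z <- (field[idx] - mean(field[idx])) / max(sd(field[idx]), 1e-12)
        omega_vox <- inc$omega * exp(amp * z)
      }
      x[idx] <- sqrt(rgamma(length(idx), shape = inc$mu,
                            scale = omega_vox / inc$mu))
    }
    x
  })
  list(envelope = envelope_volume(env, spacing, mask = NULL), labels = labels)
}

#' Synthesize a 3D fractional Brownian motion volume
#'
#' Spectral synthesis: white Gaussian noise is shaped in the Fourier domain
#' by an isotropic power spectral density proportional to f^-(2H + 3), the
#' fBm exponent convention for a 3D field. The density is alias-folded
#' (summed over `2*folds + 1` spectral replicas per axis) so the sampled
#' field keeps the above-Nyquist power that sampling a continuous fBm
#' would fold into the grid — without folding, small-lag increments come
#' out too smooth and the apparent H is inflated, worst for rough (low-H)
#' fields. The DC component is zeroed; the real part of the inverse FFT is
#' standardized to unit variance and shifted to be non-negative. The
#' expected mean absolute increment of the field then scales as
#' distance^H over small lags, up to the periodicity of the spectral
#' approximation.
#'
#' @param hurst Hurst exponent H in (0, 1): low H gives rough texture, high
#'   H smooth texture.
#' @param size voxels per axis (scalar or length 3), each >= 16.
#' @param seed integer RNG seed.
#' @param spacing voxel spacing in mm.
#' @param folds spectral replicas per axis and side used in the alias sum.
#' @param min_size minimum allowed axis size (internal callers may lower it).
#' @return An [envelope_volume()] with non-negative voxel values.
#' @export
make_fbm_volume <- function(hurst, size, seed = NULL, spacing = c(1, 1, 1),
                            folds = 2L, min_size = 16L) {
  if (!is.numeric(hurst) || length(hurst) != 1L || hurst <= 0 || hurst >= 1)
    stop_mnf("mnf_parameter_error", "'hurst' must lie in (0, 1)")
  if (length(size) == 1L) size <- rep(size, 3L)
  size <- as.integer(size)
  if (length(size) != 3L || any(size < min_size))
    stop_mnf("mnf_parameter_error", "'size' must be >= %d per axis", min_size)
  freq_axis <- function(n) {
    k <- c(0:floor(n / 2), -(ceiling(n / 2) - 1):-1)[seq_len(n)]
    k / n
  }
  fx <- freq_axis(size[1]); fy <- freq_axis(size[2]); fz <- freq_axis(size[3])
  amp2 <- array(0, size)
  for (m1 in -folds:folds) for (m2 in -folds:folds) for (m3 in -folds:folds) {
    g2 <- outer(outer((fx + m1)^2, (fy + m2)^2, `+`), (fz + m3)^2, `+`)
    pos <- g2 > 0
    amp2[pos] <- amp2[pos] + g2[pos]^(-(hurst + 1.5))
  }
  amp <- sqrt(amp2)
  amp[1, 1, 1] <- 0
  noise <- local_seed(seed, array(rnorm(prod(size)), size))
  field <- Re(fft(fft(noise) * amp, inverse = TRUE)) / prod(size)
  field <- (field - mean(field)) / max(sd(field), 1e-300)
  envelope_volume(field - min(field), spacing)
}

#' Generate a labeled two-class phantom cohort
#'
#' Builds `n_per_class` phantoms per class from two [phantom_spec()]
#' templates. Per volume, inclusion centers are jittered by integer offsets
#' and radii by a relative factor (seeded), emulating anatomical variation
#' across subjects; each phantom gets its own derived seed. The returned
#' mask covers the lesion (all inclusion voxels).
#'
#' @param n_per_class volumes per class (>= 2).
#' @param class_specs named list of two `phantom_spec` templates; names are
#'   used as class labels (defaults `"progressive"`, `"non-progressive"`).
#' @param seed master integer seed; the cohort is a pure function of
#'   `(n_per_class, class_specs, seed)`.
#' @param jitter_center max absolute integer jitter of inclusion centers.
#' @param jitter_radius max relative jitter of inclusion radii.
#' @return list of records, each with `envelope`, `labels`, `mask`,
#'   `class`, `id`; the manifest (id, class) is attached as attribute
#'   `"manifest"`.
#' @export
make_cohort <- function(n_per_class, class_specs, seed = 1L,
                        jitter_center = 2L, jitter_radius = 0.1) {
  if (n_per_class < 2L)
    stop_mnf("mnf_parameter_error", "'n_per_class' must be >= 2")
  if (length(class_specs) != 2L ||
      !all(vapply(class_specs, inherits, TRUE, "phantom_spec")))
    stop_mnf("mnf_parameter_error", "'class_specs' must be two phantom_spec")
  strip <- function(s) s[setdiff(names(s), "seed")]
  if (identical(strip(unclass(class_specs[[1]])),
                strip(unclass(class_specs[[2]]))))
    warning("class templates are identical: classes are not separable by construction")
  cls <- names(class_specs)
  if (is.null(cls)) cls <- c("progressive", "non-progressive")

  n_total <- 2L * n_per_class
  seeds <- derive_seeds(seed, 3L * n_total)
  out <- vector("list", n_total)
  idx <- 0L
  for (c_i in 1:2) {
    template <- class_specs[[c_i]]
    for (v_i in seq_len(n_per_class)) {
      idx <- idx + 1L
      jitter_seed <- seeds[3L * idx - 2L]
      phantom_seed <- seeds[3L * idx - 1L]
      spec_v <- local_seed(jitter_seed, {
        incs <- lapply(template$inclusions, function(inc) {
          ctr <- inc$center + sample(-jitter_center:jitter_center, 3L,
                                     replace = TRUE)
          rad <- inc$radius * runif(1, 1 - jitter_radius, 1 + jitter_radius)
          # clamp so the jittered ball still fits inside the grid
          ctr <- pmin(pmax(ctr, ceiling(1 + rad)),
                      floor(template$grid_size - rad))
          modifyList(inc, list(center = ctr, radius = rad))
        })
        phantom_spec(template$grid_size, template$background, incs,
                     seed = phantom_seed)
      })
      ph <- make_phantom(spec_v)
      out[[idx]] <- list(envelope = ph$envelope, labels = ph$labels,
                         mask = ph$labels > 0L, class = cls[c_i],
                         id = sprintf("%s_%02d", gsub("[^A-Za-z0-9]", "", cls[c_i]), v_i))
    }
  }
  attr(out, "manifest") <- data.frame(
    id = vapply(out, `[[`, "", "id"),
    class = vapply(out, `[[`, "", "class"),
    stringsAsFactors = FALSE)
  out
}

#' Demonstration two-class cohort templates
#'
#' Canonical phantom templates for a clearly separated two-class study:
#' \describe{
#'   \item{progressive}{pre-Rayleigh inclusion (mu = 0.7, sparse
#'     scatterers), low backscattered energy (omega = 2) and rough
#'     fine-scale texture (Hurst 0.25) — emulating uniformly aggressive
#'     tumor tissue.}
#'   \item{non-progressive}{post-Rayleigh inclusion (mu = 1.5), brighter
#'     (omega = 4, hyperechogenic) and smooth (Hurst 0.85) — emulating
#'     necrotic, functionally low-activity regions responding to
#'     treatment.}
#' }
#' Both share a Rayleigh background (mu = 1, omega = 1) and a spherical
#' inclusion of the given radius at the grid center.
#'
#' @param grid_size voxels per axis (default 48).
#' @param radius inclusion radius in voxels (default 14).
#' @return Named list of two [phantom_spec()] templates for
#'   [make_cohort()].
#' @export
mnf_demo_specs <- function(grid_size = 48L, radius = 14L) {
  ctr <- rep(round((grid_size + 1) / 2), 3L)
  list(
    "progressive" = phantom_spec(grid_size, c(1, 1), inclusions = list(
      list(center = ctr, radius = radius, mu = 0.7, omega = 2,
           hurst = 0.25, texture_amp = 1.0))),
    "non-progressive" = phantom_spec(grid_size, c(1, 1), inclusions = list(
      list(center = ctr, radius = radius, mu = 1.5, omega = 4,
           hurst = 0.85, texture_amp = 1.0))))
}
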