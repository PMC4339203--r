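# mnf3d — Multifractal Nakagami Features for 3D Ultrasound

`mnf3d` quantifies tumor texture heterogeneity in volumetric RF-envelope
ultrasound. It is aimed at quantitative-ultrasound researchers who want
to characterize tissue — e.g. predict chemotherapy response of liver
tumors — from the statistics of the backscattered envelope rather than
from B-mode intensity.

## The method

The envelope amplitude x under all scattering regimes follows the
Nakagami law

    N(x | mu, omega) = 2/Gamma(mu) * (mu/omega)^mu * x^(2mu-1) * exp(-mu x^2 / omega)

with shape `mu` (scattering regime: pre-Rician < 0.5 ... Rayleigh = 1
... post-Rayleigh > 1) and scale `omega = E[x^2]` (local backscattered
energy). The package:

1. fits `(mu, omega)` by maximum likelihood over cubic voxel lattices
   (x^2 is Gamma, so the fit is a digamma Newton iteration), producing
   voxel-wise **parametric volumes**, with out-of-ROI voxels eliminated
   from every fit and an RMSE-based sweep to choose the lattice size;
2. decomposes each parametric map with an **overcomplete (undecimated)
   octant Daubechies 8-tap wavelet-packet transform** — 8 sub-bands per
   level, all input-sized, deeper levels expanding the sub-band with the
   strongest fractal signature;
3. computes per-voxel **fractal maps** from the fractional Brownian
   motion increment model `E|dv| = K dr^H`: the log–log slope of mean
   absolute increments over Chebyshev shells gives the local Hurst
   exponent H and fractal dimension `I = 3 - H` in [2, 3];
4. averages each sub-band's fractal map into one feature and stops the
   decomposition adaptively when the between-band feature spread stops
   growing (`D_{i+1} <= D_i`), yielding the **MNF descriptor** of
   `2 maps x 8 bands x levels` features;
5. classifies descriptors with a Gaussian naive-Bayes model under
   leave-one-out or repeated stratified k-fold cross-validation,
   reporting recall, FP rate, accuracy, precision, F-measure, Jaccard,
   Dice and rank-based ROC area.

Synthetic generators (Nakagami speckle via the exact Gamma transform,
lesion phantoms with controlled contrast and fBm-textured inclusions,
alias-folded spectral fBm volumes, jittered two-class cohorts) make the
whole pipeline runnable and testable without any acquisition.

## Worked example

```r
library(mnf3d)

# estimate Nakagami parameters from 1000 envelope samples
x   <- rnakagami(1000, mu = 0.8, omega = 2, seed = 42)
fit <- estimate_mle(x)
fit
#> <nakagami_params> mu = 0.790635, omega = 2.04718
classify_scattering(fit$mu, fit$omega)
#>    mu_category omega_category
#> 1 pre-Rayleigh            low

# a 48^3 lesion phantom: post-Rayleigh, bright, smooth-textured inclusion
spec <- phantom_spec(48, c(1, 1), inclusions = list(
  list(center = c(24, 24, 24), radius = 14, mu = 1.5, omega = 4,
       hurst = 0.85, texture_amp = 1)), seed = 7)
ph <- make_phantom(spec)

# parametric volume over the lesion, then the MNF descriptor
pv <- fit_parametric_volume(ph$envelope, mask = ph$labels > 0)
pv
#> <nakagami_volume> 48 x 48 x 48 voxels, lattice 7 (sliding), 11513 valid
#>   mu: median 1.11  omega: median 4.4
desc <- mnf_descriptor(pv, mask = ph$labels > 0)
desc
#> <mnf_descriptor> 32 features (2 maps x 8 bands x 2 levels)
#>   D trace: 0.474, 0.088
```

The descriptor terminated at level 2 (the level-difference statistic
fell from 0.474 to 0.088), giving 32 features; each feature is a mean
fractal dimension in [2, 3] — e.g. `f_mu_L1_LLL = 2.323` for the
smoothed shape map versus ~2.8 for its detail bands, whose speckle
residue is rough.

A full two-class experiment is one call:

```r
cohort <- make_cohort(10, mnf_demo_specs(), seed = 2024)
tab    <- extract_features(cohort)
cross_validate(as.matrix(tab[, -(1:3)]), tab$class, scheme = "loo")
```

A command-line front end with `simulate`, `fit-nakagami`,
`fractal-map`, `features` and `run` subcommands is installed at
`inst/cli/mnf3d.R` (config-driven runs via `run_mnf()`).

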