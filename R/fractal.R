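# Mean Euclidean pair distance of the Chebyshev shell at max-norm radius
# d, for d = 1..scales. The fBm model is a power law in the Euclidean pair
# distance; a shell at max-norm radius d mixes Euclidean distances in
# [d, d*sqrt(3)], and regressing its mean increment against log d instead
# of the shell's own mean distance compresses the slope by about 7% of H.
chebyshev_shell_distances <- function(scales) {
  vapply(seq_len(scales), function(d) {
    o <- as.matrix(expand.grid(-d:d, -d:d, -d:d))
    o <- o[pmax(abs(o[, 1]), abs(o[, 2]), abs(o[, 3])) == d, , drop = FALSE]
    mean(sqrt(rowSums(o^2)))
  }, numeric(1))
}

#' Multi-scale increment profile of a single voxel
#'
#' For scales d = 1..`scales`, computes the mean absolute intensity
#' difference between the center voxel and all voxels on the Chebyshev
#' (max-norm) shell of radius d — the local increment statistic of the
#' fractional Brownian motion model `E|dv| = K * dr^H`, in which `dr` is
#' the Euclidean voxel-pair distance. Each shell's `dr` is therefore its
#' mean Euclidean pair distance (1.42, 2.75, ... voxels), not the max-norm
#' radius itself.
#'
#' @param volume 3D array or [envelope_volume()].
#' @param center integer length-3 voxel index of the profiled voxel.
#' @param scales number of shells j (>= 2).
#' @param boundary `"mirror"` reflects shell voxels falling outside the
#'   array (whole-sample symmetric extension, as used by [fractal_map()]);
#'   `"crop"` intersects each shell with the volume (and `mask`, if given).
#' @param mask optional logical array; with `boundary = "crop"`, shell
#'   voxels outside the mask are dropped.
#' @return Object of class `scale_profile`: `distances` (mean Euclidean
#'   pair distance per shell), `mads` (mean absolute differences),
#'   `n_pairs` (voxel pairs per scale).
#' @export
scale_profile <- function(volume, center, scales = 4L,
                          boundary = c("mirror", "crop"), mask = NULL) {
  boundary <- match.arg(boundary)
  v <- vol_data(volume)
  d <- dim(v)
  if (scales < 2L)
    stop_mnf("mnf_parameter_error", "'scales' must be >= 2")
  center <- as.integer(center)
  if (length(center) != 3L || any(center < 1L) || any(center > d))
    stop_mnf("mnf_parameter_error", "'center' must index a voxel of the volume")
  if (!is.null(mask) && !identical(dim(mask), d))
    stop_mnf("mnf_parameter_error", "mask dimensions must match the volume")
  vc <- v[center[1], center[2], center[3]]
  mads <- numeric(scales)
  n_pairs <- integer(scales)
  for (s in seq_len(scales)) {
    off <- expand.grid(dx = -s:s, dy = -s:s, dz = -s:s)
    off <- off[pmax(abs(off$dx), abs(off$dy), abs(off$dz)) == s, ]
    q <- cbind(center[1] + off$dx, center[2] + off$dy, center[3] + off$dz)
    if (boundary == "mirror") {
      q <- cbind(mirror_index(q[, 1], d[1]), mirror_index(q[, 2], d[2]),
                 mirror_index(q[, 3], d[3]))
    } else {
      inside <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      q <- q[inside, , drop = FALSE]
      if (!is.null(mask) && nrow(q)) q <- q[mask[q], , drop = FALSE]
    }
    n_pairs[s] <- nrow(q)
    mads[s] <- if (nrow(q)) mean(abs(v[q] - vc)) else NA_real_
  }
  usable <- which(is.finite(mads) & n_pairs > 0L)
  if (length(usable) < 2L)
    stop_mnf("mnf_invalid_profile",
             "fewer than 2 usable scales at voxel (%d, %d, %d)",
             center[1], center[2], center[3])
  structure(list(distances = chebyshev_shell_distances(scales), mads = mads,
                 n_pairs = n_pairs),
            class = "scale_profile")
}

#' Hurst exponent by log-log regression of an increment profile
#'
#' Ordinary least-squares fit of `log(mads)` against `log(distances)`; the
#' slope is the Hurst exponent H of the fBm model `E|dv| = K * dr^H` and
#' the intercept is `log K`. Scales with a zero (or undefined) mean
#' increment carry no log information and are dropped; at least two usable
#' scales must remain.
#'
#' @param profile a [scale_profile()], or any list with numeric `distances`
#'   and `mads`.
#' @return list with `H` (slope, unclamped) and `intercept`.
#' @export
hurst_regression <- function(profile) {
  ok <- is.finite(profile$mads) & profile$mads > 0 &
    is.finite(profile$distances) & profile$distances > 0
  if (sum(ok) < 2L)
    stop_mnf("mnf_invalid_profile",
             "need >= 2 scales with positive mean increments")
  x <- log(profile$distances[ok])
  y <- log(profile$mads[ok])
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  list(H = slope, intercept = yb - slope * xb)
}

#' Voxel-wise fractal map of a volume
#'
#' Estimates, for every in-ROI voxel, the local Hurst exponent H by
#' regressing log mean-absolute-increment against log mean shell distance
#' over Chebyshev shells of radius 1..`scales` (boundaries whole-sample
#' mirror-extended), and maps it to the local fractal dimension
#' `I = 3 - H`. H is clamped to [0, 1] so I lies in the surface-dimension
#' range [2, 3] for 3D data; the raw regression slope is kept in
#' `hurst_raw` for diagnostics. Voxels whose neighborhood is flat at every
#' scale (all increments zero) are assigned H = 1, I = 2 — the smoothest
#' value — and flagged in `degenerate`. The map is invariant to affine
#' intensity transforms `v -> a*v + b` (a > 0): shifts cancel in the
#' increments and positive scaling only moves the regression intercept.
#'
#' @param volume 3D array or [envelope_volume()] (wavelet sub-bands may be
#'   negative; only increments are used).
#' @param mask optional ROI mask selecting which voxels receive an
#'   estimate; shell neighbors are always taken from the full
#'   (mirror-extended) array.
#' @param scales number of shell radii j (default 4).
#' @return Object of class `fractal_map`: arrays `fd` (I), `hurst`
#'   (clamped H), `hurst_raw`, logical `valid` and `degenerate`, and
#'   `scales`.
#' @export
fractal_map <- function(volume, mask = NULL, scales = 4L) {
  v <- vol_data(volume)
  m <- vol_mask(volume, mask)
  if (scales < 2L)
    stop_mnf("mnf_parameter_error", "'scales' must be >= 2")
  if (!any(m)) stop_mnf("mnf_parameter_error", "ROI is empty")
  d <- dim(v)
  res <- shell_increment_sums(as.numeric(v), as.integer(d),
                              as.integer(scales), TRUE)
  nvox <- prod(d)
  mads <- matrix(NA_real_, nvox, scales)
  for (s in seq_len(scales))
    mads[, s] <- res$sums[[s]] / res$counts[[s]]
  lr <- log(chebyshev_shell_distances(scales))
  lrc <- lr - mean(lr)
  denom <- sum(lrc^2)

  hurst_raw <- rep(NA_real_, nvox)
  degen <- rep(FALSE, nvox)
  sel <- which(as.vector(m))
  pos <- mads[sel, , drop = FALSE] > 0
  allpos <- rowSums(pos) == scales
  # fast path: every scale usable -> vectorized centered OLS slope
  if (any(allpos)) {
    i <- sel[allpos]
    ly <- log(mads[i, , drop = FALSE])
    hurst_raw[i] <- (ly %*% lrc) / denom
  }
  # slow path: some zero-increment scales; drop them, or flag degenerate
  part <- sel[!allpos]
  for (i in part) {
    ok <- pos[match(i, sel), ]
    if (sum(ok) < 2L) {
      hurst_raw[i] <- 1
      degen[i] <- TRUE
    } else {
      x <- lr[ok]; y <- log(mads[i, ok])
      xc <- x - mean(x)
      hurst_raw[i] <- sum(xc * (y - mean(y))) / sum(xc^2)
    }
  }
  hurst <- pmin(pmax(hurst_raw, 0), 1)
  fd <- 3 - hurst
  structure(list(fd = array(fd, d), hurst = array(hurst, d),
                 hurst_raw = array(hurst_raw, d), valid = m,
                 degenerate = array(degen, d), scales = as.integer(scales)),
            class = "fractal_map")
}

#' @export
print.fractal_map <- function(x, ...) {
  cat(sprintf("<fractal_map> %s voxels, %d scales, %d valid\n",
              paste(dim(x$fd), collapse = " x "), x$scales, sum(x$valid)))
  if (any(x$valid))
    cat(sprintf("  FD: mean %.3f  [%.3f, %.3f]\n",
                mean(x$fd[x$valid]), min(x$fd[x$valid]), max(x$fd[x$valid])))
  invisible(x)
}

#' Mean fractal feature of a sub-band
#'
#' The scalar fractal signature of one wavelet sub-band: the mean
#' fractal-dimension value over the valid (in-ROI) voxels of its fractal
#' map.
#'
#' @param fmap a [fractal_map()].
#' @return Numeric scalar in [2, 3].
#' @export
subband_feature <- function(fmap) {
  if (!inherits(fmap, "fractal_map"))
    stop_mnf("mnf_parameter_error", "'fmap' must be a fractal_map")
  ok <- fmap$valid & is.finite(fmap$fd)
  if (!any(ok)) stop_mnf("mnf_parameter_error", "no valid voxels in fractal map")
  mean(fmap$fd[ok])
}

# Differential termination rule on a per-level difference trace D:
# decomposition stops at the first level i >= 2 with D[i] <= D[i-1];
# returns the stop level, or length(D) (unterminated) if never satisfied.
mnf_termination <- function(d_trace) {
  if (length(d_trace) >= 2L)
    for (i in 2:length(d_trace)) if (d_trace[i] <= d_trace[i - 1]) return(i)
  length(d_trace)
}

#' Multifractal Nakagami feature descriptor
#'
#' Builds the MNF descriptor of a Nakagami parametric volume. For each
#' parametric map (shape mu and scale omega): invalid voxels are filled
#' with the valid-voxel mean, the map is expanded one octant wavelet-packet
#' level at a time ([octant_step()]), and each of the 8 sub-bands is
#' summarized by its mean fractal dimension ([fractal_map()],
#' [subband_feature()]) — 8 features per level per map. Deeper levels
#' re-expand the sub-band with the most significant fractal signature
#' (largest mean FD). After each level i the differential statistic
#' `D_i = max_j |f_{i,j} - f_{i,j+1}|` (maximum over adjacent sub-band
#' pairs and over the two maps) is compared with the previous level's;
#' decomposition terminates adaptively when `D_{i+1} <= D_i`, i.e. when a
#' new level no longer adds FD-signature spread. The feature vector
#' concatenates the shape-map block then the scale-map block, 8 features
#' per level each, so its length is `2 * 8 * levels_used`.
#'
#' @param param_volume a `nakagami_volume` from [fit_parametric_volume()].
#' @param mask optional ROI mask; combined with the volume's valid mask.
#' @param max_levels maximum decomposition depth (default 3).
#' @param scales shell radii per fractal map (default 4).
#' @return Object of class `mnf_descriptor`: named `features`,
#'   `levels_used`, logical `terminated`, `d_trace` (per-level D), and the
#'   expansion `paths` per map.
#' @export
mnf_descriptor <- function(param_volume, mask = NULL, max_levels = 3L,
                           scales = 4L) {
  if (!inherits(param_volume, "nakagami_volume"))
    stop_mnf("mnf_parameter_error",
             "'param_volume' must come from fit_parametric_volume()")
  d <- dim(param_volume$mu)
  roi <- param_volume$valid
  if (!is.null(mask)) {
    if (!identical(dim(mask), d))
      stop_mnf("mnf_parameter_error", "mask dimensions must match the volume")
    roi <- roi & mask
  }
  if (!any(roi)) stop_mnf("mnf_parameter_error", "ROI is empty")
  fill <- function(a) {
    a[!roi | !is.finite(a)] <- mean(a[roi & is.finite(a)])
    a
  }
  maps <- list(mu = fill(param_volume$mu), omega = fill(param_volume$omega))
  filters <- daub8_filters()
  limit <- max(1L, floor(log2(min(d) / 8) + 1))
  max_levels <- min(max_levels, limit)

  current <- maps
  paths <- list(mu = character(), omega = character())
  feats <- list(mu = list(), omega = list())
  d_trace <- numeric(0)
  levels_used <- 0L
  terminated <- FALSE
  for (lev in seq_len(max_levels)) {
    lev_d <- numeric(0)
    for (mp in names(maps)) {
      bands <- octant_step(current[[mp]], filters, level = lev)
      f <- vapply(bands, function(b)
        subband_feature(fractal_map(b, mask = roi, scales = scales)),
        numeric(1))
      feats[[mp]][[lev]] <- f
      lev_d <- c(lev_d, max(abs(diff(f))))
      best <- names(f)[which.max(f)]
      paths[[mp]] <- c(paths[[mp]], best)
      current[[mp]] <- bands[[best]]
    }
    d_trace <- c(d_trace, max(lev_d))
    levels_used <- lev
    if (lev >= 2L && d_trace[lev] <= d_trace[lev - 1L]) {
      terminated <- TRUE
      break
    }
  }
  if (!terminated && max_levels >= 2L)
    message(sprintf(
      "MNF decomposition reached max_levels = %d without satisfying the differential criterion",
      max_levels))
  features <- unlist(lapply(names(maps), function(mp) {
    blk <- unlist(lapply(seq_len(levels_used), function(l)
      setNames(feats[[mp]][[l]],
               sprintf("f_%s_L%d_%s", mp, l, names(feats[[mp]][[l]])))))
    blk
  }))
  structure(list(features = features, levels_used = levels_used,
                 terminated = terminated, d_trace = d_trace, paths = paths,
                 scales = as.integer(scales)),
            class = "mnf_descriptor")
}

#' @export
print.mnf_descriptor <- function(x, ...) {
  cat(sprintf("<mnf_descriptor> %d features (2 maps x 8 bands x %d level%s)%s\n",
              length(x$features), x$levels_used,
              if (x$levels_used > 1) "s" else "",
              if (x$terminated) "" else " [unterminated]"))
  cat(sprintf("  D trace: %s\n", paste(signif(x$d_trace, 3), collapse = ", ")))
  invisible(x)
}
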