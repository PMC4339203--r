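#' Orthogonal 8-tap Daubechies analysis filters
#'
#' Returns the 8-tap Daubechies scaling (lowpass, `h0`) and wavelet
#' (highpass, `h1`) filter pair with 4 vanishing moments, L2-normalized so
#' that `sum(h0) = sqrt(2)` and `sum(h0^2) = 1`. The highpass filter is the
#' quadrature mirror `h1[k] = (-1)^k h0[N-1-k]`; its 4 vanishing moments
#' annihilate polynomials up to cubics, which makes the detail bands of
#' smooth trends vanish while speckle-scale structure passes through.
#'
#' @return list of class `filter_pair` with numeric `h0`, `h1` (length 8).
#' @export
daub8_filters <- function() {
  h0 <- c( 0.2303778133088965,   0.7148465705529157,
           0.6308807679298589,  -0.027983769416859854,
          -0.18703481171909309,  0.030841381835560764,
           0.0328830116668852,  -0.010597401785069032)
  n <- length(h0)
  h1 <- (-1)^(0:(n - 1)) * rev(h0)
  structure(list(h0 = h0, h1 = h1), class = "filter_pair")
}

# A-trous 1-D convolution of a 3D array along one axis: taps are spaced by
# `dilation` voxels, the signal is whole-sample mirror-extended, and the
# output keeps the input size (undecimated). Tap k sits at offset
# (k - 4) * dilation relative to the output voxel.
conv_axis <- function(v, h, axis, dilation = 1L) {
  d <- dim(v)
  n <- d[axis]
  out <- array(0, d)
  for (k in seq_along(h)) {
    idx <- mirror_index(seq_len(n) + (k - 5L) * dilation, n)
    shifted <- switch(axis,
                      v[idx, , , drop = FALSE],
                      v[, idx, , drop = FALSE],
                      v[, , idx, drop = FALSE])
    out <- out + h[k] * shifted
  }
  out
}

octant_names <- function() {
  c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")
}

#' One level of the overcomplete octant wavelet decomposition
#'
#' Applies the separable lowpass/highpass filter pair along the three axes
#' of the volume, producing the 8 octant sub-bands LLL, LLH, LHL, LHH,
#' HLL, HLH, HHL, HHH (letter order = axis order). The transform is
#' undecimated (a-trous): at level `level` the filter taps are spaced by
#' `2^(level-1)` voxels and every sub-band keeps the input size, so the
#' representation is overcomplete and shift-tolerant. Boundaries are
#' whole-sample mirror-extended along each axis.
#'
#' @param volume 3D array (or [envelope_volume()]).
#' @param filters a `filter_pair`; defaults to [daub8_filters()].
#' @param level decomposition level (>= 1) controlling the tap dilation.
#' @return Named list of 8 sub-band arrays, each the size of the input.
#' @export
octant_step <- function(volume, filters = daub8_filters(), level = 1L) {
  v <- vol_data(volume)
  dil <- 2L^(as.integer(level) - 1L)
  span <- length(filters$h0) * dil
  if (min(dim(v)) < span)
    stop_mnf("mnf_parameter_error",
             "volume too small for level %d: every axis must have >= %d voxels",
             level, span)
  lx <- conv_axis(v, filters$h0, 1L, dil)
  hx <- conv_axis(v, filters$h1, 1L, dil)
  xs <- list(L = lx, H = hx)
  out <- vector("list", 8L)
  names(out) <- octant_names()
  for (a in c("L", "H")) {
    for (b in c("L", "H")) {
      xy <- conv_axis(xs[[a]], if (b == "L") filters$h0 else filters$h1, 2L, dil)
      for (cc in c("L", "H")) {
        out[[paste0(a, b, cc)]] <-
          conv_axis(xy, if (cc == "L") filters$h0 else filters$h1, 3L, dil)
      }
    }
  }
  out
}

#' Overcomplete octant wavelet-packet decomposition
#'
#' Recursively expands the volume into an octant wavelet-packet tree. All 8
#' sub-bands are produced at level 1; at deeper levels the expansion policy
#' decides which nodes receive children:
#' \describe{
#'   \item{`"full"`}{every node is expanded (complete packet tree, 8^i
#'     nodes at level i).}
#'   \item{`"selective"`}{only the node with the most significant fractal
#'     signature — the largest ROI-mean fractal-map value, see
#'     [fractal_map()] — is expanded per level, following the principle of
#'     growing the basis by fractal signature rather than energy.}
#' }
#' The depth is clipped so the effective filter span `8 * 2^(level-1)`
#' never exceeds the smallest axis.
#'
#' @param volume 3D array or [envelope_volume()].
#' @param max_levels maximum decomposition depth (default 3).
#' @param policy `"full"` or `"selective"`.
#' @param mask optional ROI mask used for the fractal signatures.
#' @param signature_scales number of increment scales for the signature
#'   fractal maps.
#' @return Object of class `wavelet_packet_tree`: `nodes` is a named list
#'   of sub-band volumes keyed by path (e.g. `"HLH"`, `"HLH/LLL"`), plus
#'   the root volume under `"root"`; `levels` is the depth reached.
#' @export
wp_decompose <- function(volume, max_levels = 3L,
                         policy = c("full", "selective"),
                         mask = NULL, signature_scales = 4L) {
  policy <- match.arg(policy)
  v <- vol_data(volume)
  if (max_levels < 1L)
    stop_mnf("mnf_parameter_error", "'max_levels' must be >= 1")
  limit <- max(1L, floor(log2(min(dim(v)) / 8) + 1))
  if (max_levels > limit) {
    warning(sprintf("max_levels clipped from %d to %d for a %s volume",
                    max_levels, limit, paste(dim(v), collapse = "x")))
    max_levels <- limit
  }
  filters <- daub8_filters()
  nodes <- list(root = v)
  frontier <- list(root = v)
  for (lev in seq_len(max_levels)) {
    expand <- names(frontier)
    if (lev > 1L && policy == "selective" && length(expand) > 1L) {
      sig <- vapply(frontier, function(b) {
        subband_feature(fractal_map(b, mask = mask, scales = signature_scales))
      }, numeric(1))
      expand <- names(frontier)[which.max(sig)]
    }
    new_frontier <- list()
    for (path in expand) {
      kids <- octant_step(frontier[[path]], filters, level = lev)
      prefix <- if (path == "root") "" else paste0(path, "/")
      names(kids) <- paste0(prefix, names(kids))
      nodes <- c(nodes, kids)
      new_frontier <- c(new_frontier, kids)
    }
    frontier <- new_frontier
  }
  structure(list(nodes = nodes, levels = as.integer(max_levels),
                 policy = policy, input_dim = dim(v)),
            class = "wavelet_packet_tree")
}

#' @export
print.wavelet_packet_tree <- function(x, ...) {
  cat(sprintf("<wavelet_packet_tree> %d nodes (incl. root), %d level(s), policy '%s'\n",
              length(x$nodes), x$levels, x$policy))
  invisible(x)
}
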