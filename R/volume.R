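#' Envelope volume container
#'
#' Lightweight container for a 3D RF-envelope amplitude volume: a numeric
#' array, the voxel spacing in mm, and an optional region-of-interest mask.
#' Most functions in the package accept either a plain 3D array or an
#' `envelope_volume`.
#'
#' @param data numeric 3D array of non-negative envelope amplitudes.
#' @param spacing numeric length-3 voxel spacing in mm (x, y, slice).
#' @param mask optional logical array of the same dimension marking the
#'   region of interest.
#' @return An object of class `envelope_volume`.
#' @export
envelope_volume <- function(data, spacing = c(1, 1, 1), mask = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop_mnf("mnf_parameter_error", "'data' must be a 3D array")
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_mnf("mnf_parameter_error", "'spacing' must be 3 positive values")
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(data)))
      stop_mnf("mnf_parameter_error", "'mask' dimensions must match 'data'")
    mask <- array(as.logical(mask), dim(data))
  }
  structure(list(data = data, spacing = as.numeric(spacing), mask = mask),
            class = "envelope_volume")
}

#' @export
print.envelope_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<envelope_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x ")))
  if (!is.null(x$mask))
    cat(sprintf("  ROI: %d voxels (%.1f%%)\n", sum(x$mask),
                100 * mean(x$mask)))
  invisible(x)
}

#' @export
dim.envelope_volume <- function(x) dim(x$data)

#' @export
as.array.envelope_volume <- function(x, ...) x$data

# Extract the data array from an envelope_volume or pass a 3D array through.
vol_data <- function(x) {
  if (inherits(x, "envelope_volume")) return(x$data)
  if (is.array(x) && length(dim(x)) == 3L) return(x)
  stop_mnf("mnf_parameter_error", "expected a 3D array or envelope_volume")
}

vol_mask <- function(x, mask = NULL) {
  d <- dim(vol_data(x))
  if (is.null(mask) && inherits(x, "envelope_volume")) mask <- x$mask
  if (is.null(mask)) return(array(TRUE, d))
  if (!identical(dim(mask), d))
    stop_mnf("mnf_parameter_error", "mask dimensions must match the volume")
  array(as.logical(mask), d)
}

vol_spacing <- function(x) {
  if (inherits(x, "envelope_volume")) x$spacing else c(1, 1, 1)
}
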