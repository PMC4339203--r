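#' Read and write envelope volumes
#'
#' Volumes are stored either as NIfTI (voxel spacing in the header, via
#' RNifti) or as raw little-endian float32 with a JSON sidecar
#' (`{shape, spacing_mm, dtype, byte_order}`). The format is chosen by
#' file extension: `.nii` / `.nii.gz` for NIfTI, anything else for
#' raw + sidecar (`<path>.json`).
#'
#' @param x an [envelope_volume()] (or 3D array) to write.
#' @param path file path.
#' @return `read_volume` returns an [envelope_volume()]; `write_volume`
#'   returns `path` invisibly.
#' @export
write_volume <- function(x, path) {
  v <- vol_data(x)
  spacing <- vol_spacing(x)
  if (grepl("\\.nii(\\.gz)?$", path)) {
    arr <- v
    attr(arr, "pixdim") <- spacing
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
    jsonlite::write_json(
      list(shape = dim(v), spacing_mm = spacing, dtype = "float32",
           byte_order = "little"),
      paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path)) {
    img <- RNifti::readNifti(path)
    spacing <- RNifti::pixdim(img)[1:3]
    envelope_volume(array(as.numeric(img), dim(img)[1:3]), spacing)
  } else {
    meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
    n <- prod(meta$shape)
    con <- file(path, "rb")
    on.exit(close(con))
    v <- readBin(con, "numeric", n = n, size = 4L,
                 endian = meta$byte_order)
    envelope_volume(array(v, meta$shape), meta$spacing_mm)
  }
}

#' Export a Nakagami parametric volume
#'
#' Writes the shape and scale maps as two NIfTI files (`<prefix>_mu.nii.gz`
#' and `<prefix>_omega.nii.gz`; invalid voxels as NA/NaN) plus JSON
#' metadata recording the lattice configuration and the invalid-cell
#' count.
#'
#' @param pvol a `nakagami_volume` from [fit_parametric_volume()].
#' @param prefix output path prefix.
#' @return Invisibly, the vector of written paths.
#' @export
export_parametric_maps <- function(pvol, prefix) {
  if (!inherits(pvol, "nakagami_volume"))
    stop_mnf("mnf_parameter_error", "'pvol' must be a nakagami_volume")
  paths <- c(mu = paste0(prefix, "_mu.nii.gz"),
             omega = paste0(prefix, "_omega.nii.gz"),
             meta = paste0(prefix, "_nakagami.json"))
  write_volume(envelope_volume(pvol$mu, pvol$spacing), paths["mu"])
  write_volume(envelope_volume(pvol$omega, pvol$spacing), paths["omega"])
  jsonlite::write_json(
    list(lattice = pvol$lattice, n_valid = sum(pvol$valid),
         n_invalid = sum(!pvol$valid)),
    paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}

#' Export a fractal map
#'
#' Writes the fractal-dimension volume as NIfTI plus JSON metadata (scales
#' used, counts of valid and degenerate voxels).
#'
#' @param fmap a [fractal_map()].
#' @param prefix output path prefix.
#' @param spacing voxel spacing for the NIfTI header.
#' @return Invisibly, the vector of written paths.
#' @export
export_fractal_map <- function(fmap, prefix, spacing = c(1, 1, 1)) {
  if (!inherits(fmap, "fractal_map"))
    stop_mnf("mnf_parameter_error", "'fmap' must be a fractal_map")
  paths <- c(fd = paste0(prefix, "_fd.nii.gz"),
             meta = paste0(prefix, "_fd.json"))
  fd <- fmap$fd
  fd[!fmap$valid] <- NA_real_
  write_volume(envelope_volume(fd, spacing), paths["fd"])
  jsonlite::write_json(
    list(scales = fmap$scales, n_valid = sum(fmap$valid),
         n_degenerate = sum(fmap$degenerate)),
    paths["meta"], auto_unbox = TRUE)
  invisible(paths)
}

#' Write a cross-validation metrics report as JSON
#'
#' @param report an `mnf_metrics` object from [cross_validate()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  if (!inherits(report, "mnf_metrics"))
    stop_mnf("mnf_parameter_error", "'report' must be an mnf_metrics object")
  out <- list(scheme = report$scheme, positive = report$positive,
              metrics = as.list(report$metrics),
              positive_class = as.list(report$positive_class))
  if (!is.null(report$sd)) out$sd <- as.list(report$sd)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
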