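#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving data, affine and datatype on
#' round-trip for the supported dtypes.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @return `read_nifti`: the image as an array (with RNifti metadata).
#' @export
read_nifti <- function(path) {
  RNifti::readNifti(path)
}

#' @rdname read_nifti
#' @param volume Numeric array (3-D or 4-D).
#' @param voxel_size_mm Isotropic voxel spacing written into the header.
#' @export
write_nifti <- function(volume, path, voxel_size_mm = 2) {
  img <- RNifti::asNifti(volume)
  RNifti::pixdim(img) <- rep(voxel_size_mm, min(3L, length(dim(volume))))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a 4-D DWI volume with FSL sidecar files
#'
#' @param nifti_path 4-D NIfTI path.
#' @param bval_path,bvec_path FSL-format sidecar paths.
#' @param voxel_size_mm Spacing override (default: from the header).
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, voxel_size_mm = NULL) {
  img <- read_nifti(nifti_path)
  scheme <- read_bval_bvec(bval_path, bvec_path)
  if (length(dim(img)) != 4L) stop("DWI NIfTI must be 4-D")
  if (dim(img)[4] != n_volumes(scheme)) {
    stop(sprintf("DWI has %d volumes but bval/bvec list %d",
                 dim(img)[4], n_volumes(scheme)))
  }
  vs <- voxel_size_mm %||% RNifti::pixdim(img)[1]
  structure(
    list(signal = array(as.numeric(img), dim(img)), scheme = scheme,
         s0 = NA_real_, noise_sigma = NA_real_, voxel_size_mm = vs),
    class = "dwi_volume"
  )
}

#' @rdname read_dwi
#' @param dwi A `dwi_volume`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @export
write_dwi <- function(dwi, prefix) {
  write_nifti(dwi$signal, paste0(prefix, ".nii.gz"), dwi$voxel_size_mm)
  write_bval_bvec(dwi$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(prefix)
}

#' Read / write an ALPS ROI specification as YAML
#'
#' @param path YAML file with fields `center_proj`, `center_assoc`,
#'   `edge_mm`, `voxel_size_mm`, `units` (voxel or mm), `hemisphere`.
#' @return An [alps_roi_spec()].
#' @export
read_alps_roi <- function(path) {
  y <- yaml::read_yaml(path)
  alps_roi_spec(
    center_proj = unlist(y$center_proj),
    center_assoc = unlist(y$center_assoc),
    edge_mm = y$edge_mm %||% 3,
    voxel_size_mm = y$voxel_size_mm %||% 2,
    units = y$units %||% "voxel",
    hemisphere = y$hemisphere %||% "left"
  )
}

#' @rdname read_alps_roi
#' @param spec An [alps_roi_spec()].
#' @export
write_alps_roi <- function(spec, path) {
  yaml::write_yaml(list(
    center_proj = as.integer(spec$center_proj),
    center_assoc = as.integer(spec$center_assoc),
    edge_mm = spec$edge_mm, voxel_size_mm = spec$voxel_size_mm,
    units = "voxel", hemisphere = spec$hemisphere
  ), path)
  invisible(path)
}

#' Read / write a variable-type registry as YAML
#'
#' @param path YAML file path.
#' @param registry A registry tibble (see [default_variable_registry()]).
#' @export
write_variable_registry <- function(registry, path) {
  yaml::write_yaml(lapply(seq_len(nrow(registry)), function(i) {
    as.list(registry[i, ])
  }), path)
  invisible(path)
}

#' @rdname write_variable_registry
#' @export
read_variable_registry <- function(path) {
  rows <- yaml::read_yaml(path)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::as_tibble(lapply(r, function(x) if (is.null(x)) NA else x))
  }))
}
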