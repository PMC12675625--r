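#' ALPS region-of-interest specification
#'
#' Two cubical ROIs — one in the projection-fiber area, one in the
#' association-fiber area of the left (low-x) hemisphere — on contiguous
#' axial slices where perivascular spaces run along the x axis. Cube
#' placement in a study with SWI venograms is manual; here it is supplied
#' as configuration (voxel or mm coordinates), with
#' [default_alps_roi()] placing the cubes at the centers of a phantom's
#' periventricular slabs.
#'
#' The physical cube edge (`edge_mm`, default 3) is realized per axis as
#' the odd voxel count whose extent is closest to `edge_mm`
#' (ties toward the smaller count), so a 3 mm cube at 2 mm spacing is a
#' single voxel and at 1 mm spacing is 3 x 3 x 3 voxels.
#'
#' @param center_proj,center_assoc Length-3 voxel indices (1-based) of the
#'   two cube centers, or mm coordinates when `units = "mm"`.
#' @param edge_mm Cube edge length in mm (> 0), default 3.
#' @param voxel_size_mm Isotropic voxel spacing used for the mm-to-voxel
#'   conversion.
#' @param units `"voxel"` (default) or `"mm"`.
#' @param hemisphere Label only; `"left"` by convention (low-x half).
#' @return Object of class `alps_roi_spec`.
#' @export
alps_roi_spec <- function(center_proj, center_assoc, edge_mm = 3,
                          voxel_size_mm = 2, units = c("voxel", "mm"),
                          hemisphere = "left") {
  units <- match.arg(units)
  if (edge_mm <= 0) stop("edge_mm must be positive")
  conv <- function(x) {
    if (units == "mm") as.integer(round(x / voxel_size_mm)) + 1L else as.integer(round(x))
  }
  half <- (odd_voxel_count(edge_mm, voxel_size_mm) - 1L) / 2L
  spec <- structure(
    list(center_proj = conv(center_proj), center_assoc = conv(center_assoc),
         edge_mm = edge_mm, voxel_size_mm = voxel_size_mm,
         half_width = as.integer(half), hemisphere = hemisphere),
    class = "alps_roi_spec"
  )
  spec$slice_indices <- (spec$center_proj[3] - half):(spec$center_proj[3] + half)
  spec
}

odd_voxel_count <- function(edge_mm, voxel_size_mm) {
  n <- edge_mm / voxel_size_mm
  lo <- max(1, 2 * floor((n - 1) / 2) + 1)  # odd below or equal-ish
  hi <- lo + 2
  if (abs(n - lo) <= abs(n - hi)) as.integer(lo) else as.integer(hi)
}

#' @rdname alps_roi_spec
#' @param truth A `phantom_truth`; cube centers default to the centroids
#'   of its periventricular projection and association slabs.
#' @export
default_alps_roi <- function(truth, edge_mm = 3) {
  ctr <- function(label) {
    w <- which(truth$label_map == phantom_labels[[label]], arr.ind = TRUE)
    if (nrow(w) == 0) stop("phantom has no ", label, " voxels")
    as.integer(round(colMeans(w)))
  }
  alps_roi_spec(ctr("pv_projection"), ctr("pv_association"),
                edge_mm = edge_mm, voxel_size_mm = truth$voxel_size_mm)
}

roi_voxels <- function(center, half, dims) {
  rng <- lapply(1:3, function(a) (center[a] - half):(center[a] + half))
  if (any(vapply(1:3, function(a) rng[[a]][1] < 1 || max(rng[[a]]) > dims[a], TRUE))) {
    stop(sprintf(
      "ALPS ROI cube centered at (%s) with half-width %d exceeds the %s grid",
      paste(center, collapse = ","), half, paste(dims, collapse = "x")
    ))
  }
  as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
}

#' Mean axis diffusivities over an ROI
#'
#' Per voxel, the diffusivity along image axis a is `e_a' D e_a`, i.e. the
#' diagonal tensor entry Dxx / Dyy / Dzz (x = left-right, y =
#' anterior-posterior, z = inferior-superior); the ROI value is the
#' arithmetic mean. Errors if any ROI voxel lies outside the fitted mask,
#' listing the offending voxels.
#'
#' @param tensor_field A [fit_tensor_lls()] result.
#' @param center Length-3 voxel center of the cube.
#' @param half_width Integer half-width in voxels (cube edge = 2*hw + 1).
#' @return Named vector `c(Dxx, Dyy, Dzz)` of ROI means in mm^2/s.
#' @export
axis_diffusivities <- function(tensor_field, center, half_width = 0L) {
  vox <- roi_voxels(center, half_width, tensor_field$dims)
  lin <- vox[, 1] + tensor_field$dims[1] * (vox[, 2] - 1L) +
    prod(tensor_field$dims[1:2]) * (vox[, 3] - 1L)
  pos <- match(lin, tensor_field$voxel_index)
  if (anyNA(pos)) {
    bad <- vox[is.na(pos), , drop = FALSE]
    stop(sprintf(
      "ALPS ROI overlaps the mask boundary at voxel(s): %s",
      paste(apply(bad, 1, paste, collapse = ","), collapse = "; ")
    ))
  }
  c(Dxx = mean(tensor_field$tensors[pos, "Dxx"]),
    Dyy = mean(tensor_field$tensors[pos, "Dyy"]),
    Dzz = mean(tensor_field$tensors[pos, "Dzz"]))
}

#' DTI-ALPS index
#'
#' `index = mean(Dxproj, Dxassoc) / mean(Dyproj, Dzassoc)`: the ratio of
#' x-axis (perivascular-direction) diffusivity in the projection- and
#' association-fiber ROIs to the diffusivities perpendicular to both the
#' perivascular space and the dominant fibers. A higher index indicates
#' better glymphatic function.
#'
#' @param d_x_proj,d_x_assoc,d_y_proj,d_z_assoc Mean diffusivities in
#'   mm^2/s, all strictly positive.
#' @return The dimensionless ALPS index.
#' @examples
#' alps_index(1.2e-3, 1.2e-3, 0.8e-3, 0.8e-3)  # 1.5
#' @export
alps_index <- function(d_x_proj, d_x_assoc, d_y_proj, d_z_assoc) {
  v <- c(d_x_proj, d_x_assoc, d_y_proj, d_z_assoc)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all four diffusivities must be positive (invalid tensor fit?)")
  }
  mean(c(d_x_proj, d_x_assoc)) / mean(c(d_y_proj, d_z_assoc))
}

#' Per-subject ALPS results for a cohort
#'
#' Applies one common-space ROI specification to every subject's tensor
#' field and returns a tibble with the four diffusivities and the ALPS
#' index per subject. Subjects whose fit fails inside the ROIs are
#' reported in the `failed` attribute and excluded from the table, never
#' silently dropped.
#'
#' @param subject_tensor_fields Named list of `tensor_field` objects.
#' @param roi_spec An [alps_roi_spec()].
#' @param group Optional per-subject group labels (recycled into the table).
#' @return A tibble with columns `subject`, optional `group`, `d_x_proj`,
#'   `d_x_assoc`, `d_y_proj`, `d_z_assoc`, `alps_index`.
#' @export
alps_cohort <- function(subject_tensor_fields, roi_spec, group = NULL) {
  ids <- names(subject_tensor_fields) %||%
    sprintf("subj%03d", seq_along(subject_tensor_fields))
  rows <- vector("list", length(ids))
  failed <- character()
  for (i in seq_along(ids)) {
    res <- tryCatch({
      dp <- axis_diffusivities(subject_tensor_fields[[i]],
                               roi_spec$center_proj, roi_spec$half_width)
      da <- axis_diffusivities(subject_tensor_fields[[i]],
                               roi_spec$center_assoc, roi_spec$half_width)
      tibble::tibble(
        subject = ids[i],
        d_x_proj = dp[["Dxx"]], d_x_assoc = da[["Dxx"]],
        d_y_proj = dp[["Dyy"]], d_z_assoc = da[["Dzz"]],
        alps_index = alps_index(dp[["Dxx"]], da[["Dxx"]],
                                dp[["Dyy"]], da[["Dzz"]])
      )
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, stats::setNames(conditionMessage(res), ids[i]))
    } else {
      rows[[i]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!is.null(group)) {
    out <- dplyr::left_join(
      out, tibble::tibble(subject = ids, group = group), by = "subject"
    ) |> dplyr::relocate(dplyr::all_of("group"), .after = "subject")
  }
  if (length(failed)) {
    warning(sprintf("%d subject(s) excluded after failed fits: %s",
                    length(failed), paste(names(failed), collapse = ", ")))
  }
  attr(out, "failed") <- failed
  class(out) <- c("alps_cohort", class(out))
  out
}

#' @rdname alps_cohort
#' @param object An `alps_cohort` tibble.
#' @param ... Unused.
#' @method glance alps_cohort
#' @export
glance.alps_cohort <- function(object, ...) {
  if (!"group" %in% names(object)) {
    return(tibble::tibble(n = nrow(object),
                          mean_index = mean(object$alps_index)))
  }
  object |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_index = mean(.data$alps_index),
                     sd_index = stats::sd(.data$alps_index),
                     .groups = "drop")
}

#' @rdname alps_cohort
#' @method autoplot alps_cohort
#' @export
autoplot.alps_cohort <- function(object, ...) {
  if (!"group" %in% names(object)) object$group <- "all"
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$alps_index)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.12, colour = "firebrick", size = 1.4) +
    ggplot2::labs(x = NULL, y = "DTI-ALPS index") +
    ggplot2::theme_minimal()
}
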