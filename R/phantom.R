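#' Tissue label enumeration for digital phantoms
#'
#' Fixed label coding used by [make_phantom()]: background (0), CSF (1),
#' cortical GM ribbon (2), two straight WM tracts (3, 4), their crossing
#' region (5), and the periventricular projection- and association-fiber
#' slabs flanking the CSF block (6, 7) in which perivascular (x-axis)
#' diffusivity is modulated.
#'
#' @export
phantom_labels <- c(
  background = 0L, csf = 1L, gm = 2L,
  wm_tract_1 = 3L, wm_tract_2 = 4L, wm_crossing = 5L,
  pv_projection = 6L, pv_association = 7L
)

#' Generate a ground-truth microstructure phantom
#'
#' Builds a digital head phantom in a common space: a brain box with a
#' 2-voxel cortical GM ribbon, a central CSF block (lateral-ventricle
#' analogue), two cylindrical WM tracts crossing at 90 degrees, and two
#' periventricular slabs — projection fibers (superior-inferior, +z) and
#' association fibers (anterior-posterior, +y) — in the left (low-x)
#' hemisphere. Each voxel carries NODDI ground truth (ICVF, ODI, ISO) and
#' one (or, in the crossing, two) fiber orientations. The perivascular
#' gain multiplies x-axis extra-neurite diffusivity in the periventricular
#' labels, encoding glymphatic flow: higher gain, better flow.
#'
#' The "patient" condition lowers ODI by `odi_delta` in `odi_regions` and
#' uses a lower perivascular gain than the "control" condition.
#'
#' @param grid_shape Integer triple, default `c(40, 48, 40)`.
#' @param voxel_size_mm Isotropic voxel spacing, default 2.
#' @param condition `"control"` or `"patient"`.
#' @param condition_params Optional overrides: `odi_delta` (default 0.1;
#'   0 for controls), `odi_regions` (default `c("wm_tract_1", "gm")`),
#'   `perivascular_gain` (default 1.6 control / 1.25 patient),
#'   `jitter_sd` (voxelwise truth jitter, default 0).
#' @param seed Integer seed (drives the optional jitter).
#' @return An object of class `phantom_truth`.
#' @export
make_phantom <- function(grid_shape = c(40L, 48L, 40L), voxel_size_mm = 2,
                         condition = c("control", "patient"),
                         condition_params = list(), seed = 1L) {
  condition <- match.arg(condition)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L) stop("grid_shape must have length 3")
  if (any(grid_shape < 16L)) {
    stop("grid too small for the tract layout: every dimension must be >= 16")
  }
  defaults <- list(
    odi_delta = if (condition == "patient") 0.1 else 0,
    odi_regions = c("wm_tract_1", "gm"),
    perivascular_gain = if (condition == "patient") 1.25 else 1.6,
    jitter_sd = 0
  )
  p <- utils::modifyList(defaults, condition_params)
  if (p$odi_delta < 0 || p$odi_delta > 1) stop("odi_delta must lie in [0, 1]")
  if (p$perivascular_gain < 0) stop("perivascular_gain must be >= 0")
  if (!all(p$odi_regions %in% names(phantom_labels))) {
    stop("unknown odi_regions label name")
  }

  nx <- grid_shape[1]; ny <- grid_shape[2]; nz <- grid_shape[3]
  fr <- function(f, n) pmax(1L, pmin(n, as.integer(round(f * n))))
  lab <- array(phantom_labels[["background"]], grid_shape)

  ix <- fr(0.1, nx):fr(0.9, nx)
  iy <- fr(0.1, ny):fr(0.9, ny)
  iz <- fr(0.1, nz):fr(0.9, nz)

  # GM ribbon: 2-voxel shell just inside the brain box
  lab[ix, iy, iz] <- phantom_labels[["gm"]]
  core_x <- fr(0.1, nx) + 2L; core_X <- fr(0.9, nx) - 2L
  core_y <- fr(0.1, ny) + 2L; core_Y <- fr(0.9, ny) - 2L
  core_z <- fr(0.1, nz) + 2L; core_Z <- fr(0.9, nz) - 2L
  lab[core_x:core_X, core_y:core_Y, core_z:core_Z] <- phantom_labels[["background"]]

  # CSF block (ventricle analogue)
  csf_x <- fr(0.42, nx):fr(0.55, nx)
  csf_y <- fr(0.38, ny):fr(0.60, ny)
  csf_z <- fr(0.40, nz):fr(0.62, nz)
  lab[csf_x, csf_y, csf_z] <- phantom_labels[["csf"]]

  # periventricular slabs, left (low-x) hemisphere
  proj_x <- fr(0.28, nx):fr(0.38, nx)
  asso_x <- fr(0.15, nx):fr(0.25, nx)
  lab[proj_x, csf_y, csf_z] <- phantom_labels[["pv_projection"]]
  lab[asso_x, csf_y, csf_z] <- phantom_labels[["pv_association"]]

  # WM tracts: tubes along y (tract 1) and along x (tract 2), crossing
  tube_r <- max(1.5, 0.045 * min(nx, nz))
  cx1 <- 0.5 * (nx + 1); cz <- 0.80 * (nz + 1)
  cy2 <- 0.5 * (ny + 1)
  xg <- seq_len(nx); yg <- seq_len(ny); zg <- seq_len(nz)
  in1 <- outer(xg, zg, function(x, z) (x - cx1)^2 + (z - cz)^2 <= tube_r^2)
  in2 <- outer(yg, zg, function(y, z) (y - cy2)^2 + (z - cz)^2 <= tube_r^2)
  t1 <- array(FALSE, grid_shape); t2 <- array(FALSE, grid_shape)
  yr <- fr(0.125, ny):fr(0.875, ny)
  xr <- fr(0.125, nx):fr(0.875, nx)
  for (y in yr) t1[, y, ][in1] <- TRUE
  for (x in xr) t2[x, , ][in2] <- TRUE
  lab[t1] <- phantom_labels[["wm_tract_1"]]
  lab[t2 & !t1] <- phantom_labels[["wm_tract_2"]]
  lab[t1 & t2] <- phantom_labels[["wm_crossing"]]

  # per-label NODDI ground truth (control values)
  base <- list(
    csf            = c(icvf = 0.00, odi = 1.00, iso = 1.00),
    gm             = c(icvf = 0.45, odi = 0.70, iso = 0.15),
    wm_tract_1     = c(icvf = 0.70, odi = 0.20, iso = 0.03),
    wm_tract_2     = c(icvf = 0.70, odi = 0.20, iso = 0.03),
    wm_crossing    = c(icvf = 0.70, odi = 0.20, iso = 0.03),
    pv_projection  = c(icvf = 0.60, odi = 0.15, iso = 0.05),
    pv_association = c(icvf = 0.60, odi = 0.15, iso = 0.05)
  )
  icvf <- array(0, grid_shape); odi <- array(1, grid_shape)
  iso <- array(0, grid_shape)
  for (nm in names(base)) {
    m <- lab == phantom_labels[[nm]]
    icvf[m] <- base[[nm]][["icvf"]]
    odi[m] <- base[[nm]][["odi"]]
    iso[m] <- base[[nm]][["iso"]]
  }
  for (nm in p$odi_regions) {
    m <- lab == phantom_labels[[nm]]
    odi[m] <- pmax(0.01, odi[m] - p$odi_delta)
  }

  if (p$jitter_sd > 0) {
    set.seed(as.integer(seed))
    tissue <- lab %in% phantom_labels[c("gm", "wm_tract_1", "wm_tract_2",
                                        "wm_crossing", "pv_projection",
                                        "pv_association")]
    n <- sum(tissue)
    icvf[tissue] <- round(pmin(0.99, pmax(0.01,
      icvf[tissue] + stats::rnorm(n, 0, p$jitter_sd))), 3)
    odi[tissue] <- round(pmin(0.99, pmax(0.01,
      odi[tissue] + stats::rnorm(n, 0, p$jitter_sd))), 3)
  }
  iso[lab == phantom_labels[["csf"]]] <- 1

  # fiber orientations: mu1 everywhere WM/GM, mu2 only in the crossing
  mu1 <- array(NA_real_, c(grid_shape, 3L))
  mu2 <- array(NA_real_, c(grid_shape, 3L))
  set_mu <- function(arr, mask, v) {
    for (k in 1:3) {
      sl <- arr[, , , k]; sl[mask] <- v[k]; arr[, , , k] <- sl
    }
    arr
  }
  mu1 <- set_mu(mu1, lab == phantom_labels[["gm"]], c(0, 0, 1))
  mu1 <- set_mu(mu1, lab == phantom_labels[["wm_tract_1"]], c(0, 1, 0))
  mu1 <- set_mu(mu1, lab == phantom_labels[["wm_tract_2"]], c(1, 0, 0))
  mu1 <- set_mu(mu1, lab == phantom_labels[["wm_crossing"]], c(0, 1, 0))
  mu2 <- set_mu(mu2, lab == phantom_labels[["wm_crossing"]], c(1, 0, 0))
  mu1 <- set_mu(mu1, lab == phantom_labels[["pv_projection"]], c(0, 0, 1))
  mu1 <- set_mu(mu1, lab == phantom_labels[["pv_association"]], c(0, 1, 0))
  mu1 <- set_mu(mu1, lab == phantom_labels[["csf"]], c(0, 0, 1))

  # GM probability map (for the GBSS analogue)
  gm_prob <- array(0, grid_shape)
  gm_prob[lab == phantom_labels[["gm"]]] <- 0.9
  gm_prob[lab == phantom_labels[["background"]] &
            slice_in_box(grid_shape, ix, iy, iz)] <- 0.15

  structure(
    list(
      label_map = lab, icvf_map = icvf, odi_map = odi, iso_map = iso,
      mu1 = mu1, mu2 = mu2, gm_prob_map = gm_prob,
      perivascular_gain = p$perivascular_gain,
      voxel_size_mm = voxel_size_mm, condition = condition,
      params = p, grid_shape = grid_shape
    ),
    class = "phantom_truth"
  )
}

slice_in_box <- function(grid_shape, ix, iy, iz) {
  a <- array(FALSE, grid_shape)
  a[ix, iy, iz] <- TRUE
  a
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf(
    "<phantom_truth> %s, grid %s @ %g mm, perivascular gain %.2f\n",
    x$condition, paste(x$grid_shape, collapse = "x"),
    x$voxel_size_mm, x$perivascular_gain
  ))
  tab <- table(factor(x$label_map, levels = phantom_labels,
                      labels = names(phantom_labels)))
  print(tab)
  invisible(x)
}

#' Brain (tissue) mask of a phantom
#' @param truth A `phantom_truth`.
#' @return Logical array, `TRUE` where the label is non-background.
#' @export
phantom_mask <- function(truth) {
  truth$label_map != phantom_labels[["background"]]
}
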