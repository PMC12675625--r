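#' Three-compartment diffusion signal (NODDI forward model)
#'
#' Closed-form compartment sum for one voxel:
#' `S = s0 * ((1 - iso) * (icvf * A_intra + (1 - icvf) * A_extra) + iso * exp(-b * d_iso))`.
#' The intra-neurite compartment is a stick of diffusivity `d_par`
#' dispersed by a Watson distribution of concentration
#' `kappa = kappa_from_odi(odi)` (evaluated by spherical quadrature); the
#' extra-neurite compartment is a Gaussian with the Watson-averaged
#' cylindrical tensor under the tortuosity constraint
#' `d_perp = d_par * (1 - icvf)`; the free-water compartment is isotropic
#' with diffusivity `d_iso`. With two orientations (crossing fibers) the
#' anisotropic compartments are averaged over the orientations with equal
#' weight. `pv_gain_x` multiplies the xx entry of the extra-neurite
#' tensor, modelling enhanced perivascular diffusion along the x axis.
#'
#' @param scheme An [acquisition_scheme()].
#' @param mu Fiber orientation(s): unit 3-vector or 2 x 3 matrix.
#' @param icvf,odi,iso NODDI parameters in `[0, 1]`.
#' @param d_par,d_iso Fixed compartment diffusivities in mm^2/s.
#' @param s0 Baseline (b = 0) signal, must be positive.
#' @param pv_gain_x Multiplier (>= 0) on extra-neurite x-axis diffusivity.
#' @return Numeric vector of noiseless signals, one per volume.
#' @export
noddi_signal <- function(scheme, mu, icvf, odi, iso,
                         d_par = 1.7e-3, d_iso = 3.0e-3,
                         s0 = 1, pv_gain_x = 1) {
  if (s0 <= 0) stop("s0 must be positive")
  stopifnot(icvf >= 0, icvf <= 1, iso >= 0, iso <= 1, odi >= 0, odi <= 1)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1)
  mu <- mu / sqrt(rowSums(mu^2))
  kappa <- kappa_from_odi(odi)
  b <- scheme$bvals
  g <- scheme$bvecs
  w <- b > 0
  aniso <- rep(0, length(b))
  d_perp <- d_par * (1 - icvf)
  tau <- watson_tau(kappa)
  for (r in seq_len(nrow(mu))) {
    cb <- abs(g[w, , drop = FALSE] %*% mu[r, ])[, 1]
    a_in <- .watson_stick(b[w], kappa, cb, d_par)
    # Watson-averaged extra-neurite tensor, evaluated along g
    gdg <- d_perp + (d_par - d_perp) * (tau * cb^2 + (1 - tau) * (1 - cb^2) / 2)
    if (pv_gain_x != 1) {
      dxx <- d_perp + (d_par - d_perp) *
        (tau * mu[r, 1]^2 + (1 - tau) * (1 - mu[r, 1]^2) / 2)
      gdg <- gdg + (pv_gain_x - 1) * dxx * g[w, 1]^2
    }
    a_ex <- exp(-b[w] * gdg)
    part <- rep(1, length(b))
    part[w] <- icvf * a_in + (1 - icvf) * a_ex
    aniso <- aniso + part / nrow(mu)
  }
  free <- exp(-b * d_iso)
  s0 * ((1 - iso) * aniso + iso * free)
}

#' Forward-simulate a multi-shell DWI volume from a phantom
#'
#' Evaluates the noiseless three-compartment signal at every tissue voxel
#' (voxels are grouped by identical ground-truth parameters, so piecewise
#' constant phantoms synthesize quickly), then optionally corrupts it with
#' Rician noise: the magnitude of the signal plus two independent Gaussian
#' channels of scale `noise_sigma`. Background voxels get zero signal
#' before noise. Deterministic given `seed`.
#'
#' @param truth A [make_phantom()] result.
#' @param scheme An [acquisition_scheme()].
#' @param s0 Baseline signal level (> 0).
#' @param noise_sigma Rician noise scale; 0 gives the exact noiseless sum.
#' @param seed Integer seed for the noise draws.
#' @param d_par,d_iso Fixed compartment diffusivities.
#' @return Object of class `dwi_volume`: list with `signal` (4-D array,
#'   volume index last), `scheme`, `s0`, `noise_sigma`, `voxel_size_mm`.
#' @export
synthesize_dwi <- function(truth, scheme, s0 = 1000, noise_sigma = 0,
                           seed = 1L, d_par = 1.7e-3, d_iso = 3.0e-3) {
  if (s0 <= 0) stop("s0 must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  stopifnot(inherits(truth, "phantom_truth"), inherits(scheme, "acquisition_scheme"))
  dims <- truth$grid_shape
  nvol <- n_volumes(scheme)
  sig <- array(0, c(dims, nvol))
  mask <- phantom_mask(truth)
  idx <- which(mask)
  pv <- truth$label_map %in% phantom_labels[c("pv_projection", "pv_association")]

  mu1f <- matrix(truth$mu1, ncol = 3)
  mu2f <- matrix(truth$mu2, ncol = 3)
  key <- paste(truth$icvf_map[idx], truth$odi_map[idx], truth$iso_map[idx],
               mu1f[idx, 1], mu1f[idx, 2], mu1f[idx, 3],
               ifelse(is.na(mu2f[idx, 1]), "-", mu2f[idx, 1]),
               pv[idx], sep = "|")
  nvox_total <- prod(dims)
  for (k in unique(key)) {
    vox <- idx[key == k]
    v0 <- vox[1]
    mu <- mu1f[v0, ]
    if (!is.na(mu2f[v0, 1])) mu <- rbind(mu, mu2f[v0, ])
    s <- noddi_signal(
      scheme, mu,
      icvf = truth$icvf_map[v0], odi = truth$odi_map[v0],
      iso = truth$iso_map[v0], d_par = d_par, d_iso = d_iso, s0 = s0,
      pv_gain_x = if (pv[v0]) truth$perivascular_gain else 1
    )
    for (j in seq_len(nvol)) sig[vox + (j - 1) * nvox_total] <- s[j]
  }

  if (noise_sigma > 0) {
    set.seed(as.integer(seed))
    n <- length(sig)
    sig <- sqrt((sig + stats::rnorm(n, 0, noise_sigma))^2 +
                  stats::rnorm(n, 0, noise_sigma)^2)
  }
  structure(
    list(signal = sig, scheme = scheme, s0 = s0, noise_sigma = noise_sigma,
         voxel_size_mm = truth$voxel_size_mm),
    class = "dwi_volume"
  )
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf(
    "<dwi_volume> %s grid, %d volumes, s0 = %g, noise sigma = %g\n",
    paste(d[1:3], collapse = "x"), d[4], x$s0, x$noise_sigma
  ))
  invisible(x)
}
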