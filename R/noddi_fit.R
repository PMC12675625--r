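#' Fit NODDI microstructure parameters per voxel
#'
#' Estimates ICVF, ODI and ISO (plus the Watson concentration kappa and an
#' orientation) for every masked voxel of a multi-shell acquisition by
#' minimizing the sum of squared residuals between the s0-normalized
#' signal and the three-compartment forward model of [noddi_signal()].
#' Estimation is a coarse grid search over
#' (icvf, odi, iso, orientation) — the predicted-signal library is cached
#' per scheme — followed by derivative-based local refinement of the
#' continuous parameters; the refinement orientation is initialized from
#' the diffusion-tensor principal eigenvector where available, otherwise
#' from the best grid orientation, and a refined solution is only accepted
#' if it improves the objective.
#'
#' Voxels with non-finite signals are masked out and reported in
#' `excluded`, never fitted.
#'
#' @param dwi A `dwi_volume` or 4-D array (then `scheme` is required).
#' @param scheme An [acquisition_scheme()]; must have at least 2 nonzero
#'   shells.
#' @param mask Logical 3-D array; default: positive mean b = 0 signal.
#' @param fixed_diffusivities Named vector `c(d_par=, d_iso=)` in mm^2/s.
#' @param grid_spec List with `n_icvf`, `n_odi`, `n_iso`, `n_orient`
#'   (defaults 11, 11, 6, 30).
#' @param refine Run local refinement after the grid search (default TRUE).
#' @param tensor_field Optional [fit_tensor_lls()] result on the same grid
#'   supplying per-voxel initial orientations; computed internally (with
#'   `include_max_b = TRUE`) when `NULL` and `refine = TRUE`.
#' @param refine_tol Convergence tolerance (factr-scale) of the local
#'   search, default 1e-6.
#' @return Object of class `noddi_params` with `icvf_map`, `odi_map`,
#'   `iso_map`, `kappa_map`, `fit_residual` (3-D arrays), orientation
#'   matrix `mu`, the fitted mask and `excluded` voxel indices.
#' @export
fit_noddi <- function(dwi, scheme = NULL, mask = NULL,
                      fixed_diffusivities = c(d_par = 1.7e-3, d_iso = 3.0e-3),
                      grid_spec = list(n_icvf = 11L, n_odi = 11L,
                                       n_iso = 6L, n_orient = 30L),
                      refine = TRUE, tensor_field = NULL,
                      refine_tol = 1e-6) {
  if (inherits(dwi, "dwi_volume")) {
    if (is.null(scheme)) scheme <- dwi$scheme
    sig <- dwi$signal
  } else {
    sig <- dwi
    if (is.null(scheme)) stop("scheme required when dwi is a bare array")
  }
  if (length(scheme$shells) < 2L) {
    stop("NODDI requires at least 2 nonzero shells")
  }
  d_par <- unname(fixed_diffusivities[["d_par"]])
  d_iso <- unname(fixed_diffusivities[["d_iso"]])
  dims <- dim(sig)[1:3]
  nvox_total <- prod(dims)
  b <- scheme$bvals
  if (is.null(mask)) {
    mask <- apply(sig[, , , b == 0, drop = FALSE], 1:3, mean) > 0
  }

  # exclude non-finite voxels up front
  finite_ok <- array(TRUE, dims)
  for (j in seq_len(dim(sig)[4])) {
    finite_ok <- finite_ok & is.finite(sig[, , , j])
  }
  excluded <- which(mask & !finite_ok)
  mask <- mask & finite_ok
  idx <- which(mask)
  nvox <- length(idx)
  if (nvox == 0L) stop("empty mask: nothing to fit")

  S <- matrix(0, length(b), nvox)
  for (j in seq_along(b)) S[j, ] <- sig[idx + (j - 1L) * nvox_total]
  s0 <- colMeans(S[b == 0, , drop = FALSE])
  S <- sweep(S, 2, s0, "/")

  lib <- noddi_library(scheme, grid_spec, d_par, d_iso)
  tab <- noddi_tables(scheme$shells, d_par)

  # grid search: argmin_combo ||P_combo - S_vox||^2, chunked over voxels
  p2 <- rowSums(lib$P^2)
  best <- integer(nvox); best_sse <- numeric(nvox)
  chunk <- 256L
  for (a in seq(1L, nvox, by = chunk)) {
    bnd <- min(a + chunk - 1L, nvox)
    M <- lib$P %*% S[, a:bnd, drop = FALSE]
    sse <- p2 - 2 * M + rep(colSums(S[, a:bnd, drop = FALSE]^2),
                            each = nrow(lib$P))
    jb <- max.col(-t(sse), ties.method = "first")
    best[a:bnd] <- jb
    best_sse[a:bnd] <- sse[cbind(jb, seq_len(bnd - a + 1L))]
  }

  par_icvf <- lib$combos$icvf[best]
  par_odi <- lib$combos$odi[best]
  par_iso <- lib$combos$iso[best]
  mu_fit <- lib$orient[lib$combos$orient[best], , drop = FALSE]
  resid <- best_sse

  if (refine) {
    if (is.null(tensor_field)) {
      tensor_field <- tryCatch(
        fit_tensor_lls(sig, scheme, mask = mask, include_max_b = TRUE),
        error = function(e) NULL
      )
    }
    tmap <- NULL
    if (!is.null(tensor_field)) {
      tmap <- match(idx, tensor_field$voxel_index)
    }
    for (i in seq_len(nvox)) {
      obj <- make_noddi_objective(S[, i], scheme, tab, d_par, d_iso)
      inits <- list(c(par_icvf[i], par_odi[i], par_iso[i],
                      mu_to_angles(mu_fit[i, ])))
      if (!is.null(tmap) && !is.na(tmap[i])) {
        e1 <- tensor_field$evecs[tmap[i], , 1]
        inits <- c(inits, list(c(par_icvf[i], par_odi[i], par_iso[i],
                                 mu_to_angles(e1))))
      }
      vals <- vapply(inits, obj, numeric(1))
      p0 <- inits[[which.min(vals)]]
      fit <- tryCatch(
        stats::optim(
          p0, obj, method = "L-BFGS-B",
          lower = c(1e-3, 0.005, 0, -10, -10),
          upper = c(0.999, 0.995, 1, 10, 10),
          control = list(factr = refine_tol / .Machine$double.eps)
        ),
        error = function(e) NULL
      )
      if (!is.null(fit) && fit$value < resid[i]) {
        par_icvf[i] <- fit$par[1]; par_odi[i] <- fit$par[2]
        par_iso[i] <- fit$par[3]
        mu_fit[i, ] <- angles_to_mu(fit$par[4], fit$par[5])
        resid[i] <- fit$value
      }
    }
  }

  to_map <- function(v, fill = 0) { a <- array(fill, dims); a[idx] <- v; a }
  structure(
    list(
      icvf_map = to_map(par_icvf), odi_map = to_map(par_odi),
      iso_map = to_map(par_iso),
      kappa_map = to_map(kappa_from_odi(pmax(par_odi, 1e-6))),
      fit_residual = to_map(resid), mu = mu_fit,
      mask = mask, voxel_index = idx, excluded = excluded,
      dims = dims, grid_spec = grid_spec,
      fixed_diffusivities = c(d_par = d_par, d_iso = d_iso)
    ),
    class = "noddi_params"
  )
}

#' @export
print.noddi_params <- function(x, ...) {
  cat(sprintf(
    "<noddi_params> %s grid, %d voxels fitted, %d excluded (non-finite)\n",
    paste(x$dims, collapse = "x"), length(x$voxel_index), length(x$excluded)
  ))
  invisible(x)
}

# predicted-signal library over the (icvf, odi, iso, orientation) grid,
# cached per (scheme, grid, diffusivities) for the session
.noddi_lib_env <- new.env(parent = emptyenv())

noddi_library <- function(scheme, grid_spec, d_par, d_iso) {
  key <- paste(
    format(c(scheme$bvals, as.vector(scheme$bvecs),
             unlist(grid_spec), d_par, d_iso), digits = 10),
    collapse = "|"
  )
  key <- paste0("k", substr(digest_simple(key), 1, 24))
  hit <- .noddi_lib_env[[key]]
  if (!is.null(hit)) return(hit)

  icvf_g <- seq(0.02, 0.98, length.out = grid_spec$n_icvf)
  odi_g <- seq(0.02, 0.98, length.out = grid_spec$n_odi)
  iso_g <- seq(0, 1, length.out = grid_spec$n_iso)
  orient <- fibonacci_directions(grid_spec$n_orient)

  b <- scheme$bvals
  w <- b > 0
  tab <- noddi_tables(scheme$shells, d_par)
  shell_of <- match(b[w], scheme$shells)
  free <- exp(-b * d_iso)
  cb_all <- abs(scheme$bvecs[w, , drop = FALSE] %*% t(orient))  # nw x n_orient

  n_combo <- length(icvf_g) * length(odi_g) * length(iso_g) * nrow(orient)
  P <- matrix(0, n_combo, length(b))
  combos <- data.frame(
    icvf = numeric(n_combo), odi = numeric(n_combo),
    iso = numeric(n_combo), orient = integer(n_combo)
  )
  row <- 0L
  for (oi in seq_along(odi_g)) {
    tau <- tab$tau_fun(odi_g[oi])
    a_in_all <- matrix(0, sum(w), nrow(orient))
    for (s in seq_along(scheme$shells)) {
      sel <- shell_of == s
      a_in_all[sel, ] <- interp_stick(tab, s, odi_g[oi],
                                      cb_all[sel, , drop = FALSE])
    }
    for (o in seq_len(nrow(orient))) {
      cb <- cb_all[, o]
      for (ic in seq_along(icvf_g)) {
        d_perp <- d_par * (1 - icvf_g[ic])
        gdg <- d_perp + (d_par - d_perp) *
          (tau * cb^2 + (1 - tau) * (1 - cb^2) / 2)
        part <- icvf_g[ic] * a_in_all[, o] + (1 - icvf_g[ic]) * exp(-b[w] * gdg)
        for (is_ in seq_along(iso_g)) {
          row <- row + 1L
          pr <- (1 - iso_g[is_]) * 1 + iso_g[is_] * 1  # b0 value = 1
          pred <- rep(pr, length(b))
          pred[w] <- (1 - iso_g[is_]) * part + iso_g[is_] * free[w]
          P[row, ] <- pred
          combos$icvf[row] <- icvf_g[ic]
          combos$odi[row] <- odi_g[oi]
          combos$iso[row] <- iso_g[is_]
          combos$orient[row] <- o
        }
      }
    }
  }
  lib <- list(P = P, combos = combos, orient = orient)
  .noddi_lib_env[[key]] <- lib
  lib
}

# residual objective for one voxel over (icvf, odi, iso, theta, phi)
make_noddi_objective <- function(s_norm, scheme, tab, d_par, d_iso) {
  b <- scheme$bvals
  w <- b > 0
  g <- scheme$bvecs[w, , drop = FALSE]
  bw <- b[w]
  shell_of <- match(bw, scheme$shells)
  free <- exp(-bw * d_iso)
  sw <- s_norm[w]
  b0_res <- sum((s_norm[!w] - 1)^2)
  function(p) {
    icvf <- p[1]; odi <- p[2]; iso <- p[3]
    mu <- angles_to_mu(p[4], p[5])
    cb <- abs(g %*% mu)[, 1]
    a_in <- numeric(length(bw))
    for (s in unique(shell_of)) {
      sel <- shell_of == s
      a_in[sel] <- interp_stick(tab, s, odi, cb[sel])
    }
    tau <- tab$tau_fun(odi)
    d_perp <- d_par * (1 - icvf)
    gdg <- d_perp + (d_par - d_perp) *
      (tau * cb^2 + (1 - tau) * (1 - cb^2) / 2)
    pred <- (1 - iso) * (icvf * a_in + (1 - icvf) * exp(-bw * gdg)) +
      iso * free
    sum((pred - sw)^2) + b0_res
  }
}

mu_to_angles <- function(mu) {
  mu <- mu / sqrt(sum(mu^2))
  c(acos(min(1, max(-1, mu[3]))), atan2(mu[2], mu[1]))
}

angles_to_mu <- function(theta, phi) {
  c(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
}

# tiny stable string hash (djb2), for cache keys only
digest_simple <- function(x) {
  v <- utf8ToInt(x)
  h <- 5381
  for (c in v) h <- (h * 33 + c) %% 2^31
  format(h, scientific = FALSE)
}
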