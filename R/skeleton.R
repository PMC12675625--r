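#' Voxelwise mean of subject maps
#'
#' @param maps List of 3-D arrays sharing one grid.
#' @return The voxelwise arithmetic mean map.
#' @export
mean_map <- function(maps) {
  stopifnot(length(maps) >= 1)
  d <- dim(maps[[1]])
  for (m in maps) {
    if (!identical(dim(m), d)) stop("subject maps have mismatched grids")
  }
  Reduce(`+`, maps) / length(maps)
}

# separable 3-D Gaussian smoothing (sigma in voxels, truncated at 3 sigma)
gaussian_smooth_3d <- function(arr, sigma = 1) {
  if (sigma <= 0) return(arr)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    out <- array(0, d)
    for (off in -r:r) {
      w <- k[off + r + 1]
      src <- pmin(pmax(seq_len(d[axis]) + off, 1L), d[axis])  # replicate edges
      if (axis == 1) out <- out + w * a[src, , , drop = FALSE]
      if (axis == 2) out <- out + w * a[, src, , drop = FALSE]
      if (axis == 3) out <- out + w * a[, , src, drop = FALSE]
    }
    out
  }
  conv_axis(conv_axis(conv_axis(arr, 1), 2), 3)
}

# central-difference gradient of a 3-D array along one axis
gradient_axis <- function(f, axis) {
  d <- dim(f)
  hi <- lo <- seq_len(d[axis])
  hi <- pmin(hi + 1L, d[axis]); lo <- pmax(lo - 1L, 1L)
  if (axis == 1) return((f[hi, , , drop = FALSE] - f[lo, , , drop = FALSE]) / 2)
  if (axis == 2) return((f[, hi, , drop = FALSE] - f[, lo, , drop = FALSE]) / 2)
  (f[, , hi, drop = FALSE] - f[, , lo, drop = FALSE]) / 2
}

# smoothed second-moment (structure) tensor of the gradient field,
# returned at the requested linear voxel indices as an n x 3 x 3 array;
# its principal eigenvector is the tract-perpendicular direction (radial
# at tract surfaces, cross-sectional at ridge lines)
structure_tensor_at <- function(f, idx, sigma = 1) {
  g <- lapply(1:3, function(a) gradient_axis(f, a))
  J <- array(0, c(length(idx), 3, 3))
  for (a in 1:3) {
    for (b in a:3) {
      Jab <- gaussian_smooth_3d(g[[a]] * g[[b]], sigma)
      J[, a, b] <- J[, b, a] <- Jab[idx]
    }
  }
  J
}

#' Skeletonize a mean FA map
#'
#' A voxel joins the skeleton iff its mean FA is at or above
#' `fa_threshold` (default 0.2) and it is a local maximum along the local
#' tract-perpendicular direction within +/- 1 voxel. The perpendicular
#' direction is the principal eigenvector of the smoothed second-moment
#' (structure) tensor of the Gaussian-smoothed (sigma = 1 voxel) mean FA
#' gradient — radial at tract surfaces and cross-sectional on ridge
#' lines, so tube interiors thin to their center line; the local-maximum
#' comparison uses the smoothed map so plateaus resolve consistently.
#'
#' @param mean_fa 3-D mean FA array (see [mean_map()]).
#' @param fa_threshold FA threshold in (0, 1), default 0.2.
#' @param voxel_size_mm Isotropic voxel spacing (metadata for projection).
#' @param smooth_sigma Smoothing sigma in voxels for the ridge estimate.
#' @return Object of class `skeleton_data`: logical `mask`, linear voxel
#'   indices `idx`, unit `perp` directions (n x 3), `dims`,
#'   `voxel_size_mm`.
#' @export
skeletonize <- function(mean_fa, fa_threshold = 0.2, voxel_size_mm = 2,
                        smooth_sigma = 1) {
  if (fa_threshold <= 0 || fa_threshold >= 1) {
    stop("fa_threshold must lie in (0, 1)")
  }
  d <- dim(mean_fa)
  sm <- gaussian_smooth_3d(mean_fa, smooth_sigma)
  cand <- which(mean_fa >= fa_threshold)
  if (length(cand) == 0L) {
    stop("empty skeleton: no voxel reaches the FA threshold; review fa_threshold")
  }
  J <- structure_tensor_at(sm, cand, smooth_sigma)
  perp <- matrix(0, length(cand), 3)
  for (i in seq_along(cand)) {
    e <- eigen(J[i, , ], symmetric = TRUE)
    perp[i, ] <- e$vectors[, 1]   # largest second moment
  }
  ar <- arrayInd(cand, d)
  off <- perp_step(perp)
  val0 <- sm[cand]
  ok <- rep(TRUE, length(cand))
  for (s in c(-1, 1)) {
    p <- ar + s * off
    inside <- p[, 1] >= 1 & p[, 1] <= d[1] & p[, 2] >= 1 & p[, 2] <= d[2] &
      p[, 3] >= 1 & p[, 3] <= d[3]
    nb <- rep(-Inf, length(cand))
    nb[inside] <- sm[p[inside, , drop = FALSE]]
    ok <- ok & (val0 >= nb)
  }
  keep <- which(ok)
  if (length(keep) == 0L) {
    stop("empty skeleton after the ridge test; review fa_threshold")
  }
  mask <- array(FALSE, d)
  mask[cand[keep]] <- TRUE
  structure(
    list(mask = mask, idx = cand[keep], perp = perp[keep, , drop = FALSE],
         dims = d, voxel_size_mm = voxel_size_mm),
    class = "skeleton_data"
  )
}

# nearest-voxel step for a unit direction (never the zero offset)
perp_step <- function(perp) {
  off <- round(perp)
  zero <- rowSums(abs(off)) == 0
  if (any(zero)) {
    a <- max.col(abs(perp[zero, , drop = FALSE]), ties.method = "first")
    for (j in which(zero)) {
      off[j, ] <- 0
      k <- max.col(abs(perp[j, , drop = FALSE]), ties.method = "first")
      off[j, k] <- sign(perp[j, k])
    }
  }
  off
}

#' @export
print.skeleton_data <- function(x, ...) {
  cat(sprintf("<skeleton_data> %d skeleton voxels on a %s grid\n",
              length(x$idx), paste(x$dims, collapse = "x")))
  invisible(x)
}

# candidate voxels along +/- the perpendicular direction, ordered by
# |step| so ties resolve to the nearest voxel (then the negative side)
perp_candidates <- function(skeleton, i, search_vox) {
  d <- skeleton$dims
  v <- arrayInd(skeleton$idx[i], d)[1, ]
  p <- skeleton$perp[i, ]
  steps <- c(0, as.vector(rbind(-seq_len(search_vox), seq_len(search_vox))))
  pos <- t(vapply(steps, function(t) v + round(t * p), numeric(3)))
  inside <- pos[, 1] >= 1 & pos[, 1] <= d[1] & pos[, 2] >= 1 &
    pos[, 2] <= d[2] & pos[, 3] >= 1 & pos[, 3] <= d[3]
  pos <- pos[inside, , drop = FALSE]
  lin <- pos[, 1] + d[1] * (pos[, 2] - 1) + d[1] * d[2] * (pos[, 3] - 1)
  lin[!duplicated(lin)]
}

#' Project a subject's WM metric onto the skeleton (TBSS analogue)
#'
#' For every skeleton voxel, the subject's maximum-FA voxel is located
#' along the +/- perpendicular direction within `search_mm`; the
#' projected value is the metric at that located voxel (so non-FA metrics
#' reuse the FA-derived projection voxel). Ties resolve to the nearest
#' candidate.
#'
#' @param subject_fa Subject FA 3-D array (drives the search).
#' @param subject_metric Metric 3-D array to project (may be the FA map
#'   itself).
#' @param skeleton A [skeletonize()] result.
#' @param search_mm Search half-length in mm (>= voxel size), default 6.
#' @return Numeric vector of projected values, one per skeleton voxel.
#' @export
project_wm_metric <- function(subject_fa, subject_metric, skeleton,
                              search_mm = 6) {
  stopifnot(identical(dim(subject_fa), skeleton$dims),
            identical(dim(subject_metric), skeleton$dims))
  if (search_mm < skeleton$voxel_size_mm) {
    stop("search_mm must be at least one voxel size")
  }
  K <- floor(search_mm / skeleton$voxel_size_mm)
  out <- numeric(length(skeleton$idx))
  for (i in seq_along(skeleton$idx)) {
    cand <- perp_candidates(skeleton, i, K)
    out[i] <- subject_metric[cand[which.max(subject_fa[cand])]]
  }
  out
}

#' Project GM metrics onto the skeleton with thresholding and Gaussian
#' hole-filling (GBSS analogue)
#'
#' Per subject and skeleton voxel, the metric is projected from the
#' greatest-GM-probability voxel along the perpendicular search segment.
#' A skeleton voxel is retained iff its projected GM probability exceeds
#' `gm_thresh` in more than `subject_frac` of the subjects. Where an
#' individual subject fails the threshold at a retained voxel, its value
#' is filled with the Gaussian-weighted (sigma = `sigma_mm`, distances in
#' mm between skeleton voxels) average of that subject's valid values at
#' other retained skeleton voxels within 3 sigma; a voxel with no valid
#' neighbor in range is reported unfillable and masked (NA) for that
#' subject.
#'
#' @param subject_gm_probs List of per-subject GM-probability 3-D arrays.
#' @param subject_metrics List of per-subject metric 3-D arrays.
#' @param skeleton A [skeletonize()] result.
#' @param gm_thresh GM-probability threshold, default 0.65.
#' @param subject_frac Required subject fraction, default 0.75.
#' @param sigma_mm Gaussian fill kernel sigma in mm, default 2.
#' @param search_mm Perpendicular search half-length in mm, default 6.
#' @return List with `values` (retained-voxel x subject matrix, filled),
#'   `validity` (same shape, pre-fill validity), `retained` (logical per
#'   skeleton voxel), `retained_idx` (linear voxel indices) and
#'   `unfillable` (data frame of voxel/subject pairs left NA).
#' @export
project_gm_metric <- function(subject_gm_probs, subject_metrics, skeleton,
                              gm_thresh = 0.65, subject_frac = 0.75,
                              sigma_mm = 2, search_mm = 6) {
  ns <- length(subject_gm_probs)
  stopifnot(ns == length(subject_metrics), ns >= 1)
  K <- max(1L, floor(search_mm / skeleton$voxel_size_mm))
  nsk <- length(skeleton$idx)
  prob <- matrix(0, nsk, ns)
  val <- matrix(0, nsk, ns)
  for (i in seq_len(nsk)) {
    cand <- perp_candidates(skeleton, i, K)
    for (s in seq_len(ns)) {
      j <- cand[which.max(subject_gm_probs[[s]][cand])]
      prob[i, s] <- subject_gm_probs[[s]][j]
      val[i, s] <- subject_metrics[[s]][j]
    }
  }
  validity <- prob > gm_thresh
  retained <- rowMeans(validity) > subject_frac
  ridx <- which(retained)
  vals <- val[ridx, , drop = FALSE]
  valid_r <- validity[ridx, , drop = FALSE]

  coords <- arrayInd(skeleton$idx[ridx], skeleton$dims) * skeleton$voxel_size_mm
  unfillable <- list()
  for (s in seq_len(ns)) {
    holes <- which(!valid_r[, s])
    donors <- which(valid_r[, s])
    for (h in holes) {
      if (length(donors)) {
        dist <- sqrt(rowSums((coords[donors, , drop = FALSE] -
                                matrix(coords[h, ], length(donors), 3,
                                       byrow = TRUE))^2))
        near <- dist <= 3 * sigma_mm
      } else {
        near <- logical(0)
      }
      if (any(near)) {
        w <- exp(-dist[near]^2 / (2 * sigma_mm^2))
        vals[h, s] <- sum(w * vals[donors[near], s]) / sum(w)
      } else {
        vals[h, s] <- NA_real_
        unfillable[[length(unfillable) + 1L]] <-
          data.frame(skeleton_voxel = ridx[h], subject = s)
      }
    }
  }
  list(
    values = vals, validity = valid_r, retained = retained,
    retained_idx = skeleton$idx[ridx],
    unfillable = if (length(unfillable)) do.call(rbind, unfillable)
    else data.frame(skeleton_voxel = integer(), subject = integer())
  )
}
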