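#' Linear least-squares diffusion tensor fit
#'
#' Log-signal linear regression of the single-tensor model
#' `S = S0 * exp(-b g' D g)` on the low-b portion of a multi-shell
#' acquisition. By default only volumes with `b < max_b` are used
#' (`b < 1000 s/mm^2` keeps the 6-direction shell of the reference
#' protocol, the exactly determined fit); `include_max_b = TRUE` switches
#' to `b <= max_b`, which admits the 30-direction b = 1000 shell and is
#' considerably more noise-robust.
#'
#' @param dwi A `dwi_volume`, or a 4-D array (then `scheme` is required).
#' @param scheme An [acquisition_scheme()] (taken from `dwi` if absent).
#' @param mask Logical 3-D array of voxels to fit; default: voxels whose
#'   mean b = 0 signal is positive.
#' @param max_b Shell cutoff in s/mm^2, default 1000.
#' @param include_max_b If `TRUE`, use `b <= max_b` instead of `b < max_b`.
#' @return Object of class `tensor_field`: per-voxel tensors (row order =
#'   `which(mask)`), eigenvalues (descending, clipped at 0 with
#'   `n_clipped` logged), orthonormal eigenvector triads, `fa_map`,
#'   `md_map`, principal-direction `color_fa` (RGB = |v1|), plus the mask
#'   and grid metadata.
#' @export
fit_tensor_lls <- function(dwi, scheme = NULL, mask = NULL,
                           max_b = 1000, include_max_b = FALSE) {
  if (inherits(dwi, "dwi_volume")) {
    if (is.null(scheme)) scheme <- dwi$scheme
    voxmm <- dwi$voxel_size_mm
    sig <- dwi$signal
  } else {
    sig <- dwi
    voxmm <- attr(dwi, "voxel_size_mm") %||% 1
    if (is.null(scheme)) stop("scheme required when dwi is a bare array")
  }
  stopifnot(length(dim(sig)) == 4L)
  if (dim(sig)[4] != n_volumes(scheme)) {
    stop(sprintf("DWI has %d volumes but the scheme lists %d",
                 dim(sig)[4], n_volumes(scheme)))
  }
  b <- scheme$bvals
  keep <- b == 0 | (if (include_max_b) b <= max_b else b < max_b)
  bw <- b[keep]
  gw <- scheme$bvecs[keep, , drop = FALSE]
  if (sum(bw == 0) < 1L) stop("shell filter left no b = 0 volume")
  dirs <- unique(round(abs(gw[bw > 0, , drop = FALSE]), 6))
  if (nrow(dirs) < 6L) {
    stop(sprintf(
      "shell filter b %s %g leaves only %d distinct directions; >= 6 required",
      if (include_max_b) "<=" else "<", max_b, nrow(dirs)
    ))
  }

  dims <- dim(sig)[1:3]
  if (is.null(mask)) {
    b0mean <- apply(sig[, , , b == 0, drop = FALSE], 1:3, mean)
    mask <- b0mean > 0
  }
  idx <- which(mask)
  nvox <- length(idx)
  nvox_total <- prod(dims)
  Y <- matrix(0, sum(keep), nvox)
  kv <- which(keep)
  for (j in seq_along(kv)) {
    Y[j, ] <- sig[idx + (kv[j] - 1L) * nvox_total]
  }
  n_nonpos <- sum(Y <= 0)
  Y[Y <= 0] <- min(Y[Y > 0], 1) * 1e-6
  X <- cbind(
    1,
    -bw * gw[, 1]^2, -bw * gw[, 2]^2, -bw * gw[, 3]^2,
    -2 * bw * gw[, 1] * gw[, 2], -2 * bw * gw[, 1] * gw[, 3],
    -2 * bw * gw[, 2] * gw[, 3]
  )
  beta <- qr.coef(qr(X), log(Y))   # 7 x nvox

  tensors <- t(beta[2:7, , drop = FALSE])  # Dxx Dyy Dzz Dxy Dxz Dyz
  colnames(tensors) <- c("Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  evals <- matrix(0, nvox, 3)
  evecs <- array(0, c(nvox, 3, 3))  # [, , k] = k-th eigenvector
  for (i in seq_len(nvox)) {
    D <- matrix(c(
      tensors[i, 1], tensors[i, 4], tensors[i, 5],
      tensors[i, 4], tensors[i, 2], tensors[i, 6],
      tensors[i, 5], tensors[i, 6], tensors[i, 3]
    ), 3, 3)
    e <- eigen(D, symmetric = TRUE)
    evals[i, ] <- e$values
    evecs[i, , ] <- e$vectors
  }
  n_clipped <- sum(evals < 0)
  evals[evals < 0] <- 0

  fa <- fa_from_eigenvalues(evals)
  fa_map <- array(0, dims); fa_map[idx] <- fa
  md_map <- array(0, dims); md_map[idx] <- rowMeans(evals)
  color <- array(0, c(dims, 3L))
  for (k in 1:3) {
    sl <- array(0, dims); sl[idx] <- abs(evecs[, k, 1]); color[, , , k] <- sl
  }
  structure(
    list(
      tensors = tensors, evals = evals, evecs = evecs,
      fa_map = fa_map, md_map = md_map, color_fa = color,
      mask = mask, voxel_index = idx, dims = dims,
      voxel_size_mm = voxmm, n_clipped = n_clipped,
      n_nonpositive_signals = n_nonpos,
      shell_filter = list(max_b = max_b, include_max_b = include_max_b,
                          n_directions = nrow(dirs))
    ),
    class = "tensor_field"
  )
}

#' Fractional anisotropy from eigenvalues
#'
#' `FA = sqrt(3/2) * ||lambda - mean(lambda)|| / ||lambda||`, clamped to
#' `[0, 1]`; zero tensors get FA = 0.
#'
#' @param evals Numeric matrix (n x 3) or length-3 vector of eigenvalues.
#' @return FA values in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(evals) {
  if (is.null(dim(evals))) evals <- matrix(evals, nrow = 1)
  m <- rowMeans(evals)
  num <- sqrt(rowSums((evals - m)^2))
  den <- sqrt(rowSums(evals^2))
  fa <- ifelse(den > 0, sqrt(1.5) * num / den, 0)
  pmin(pmax(fa, 0), 1)
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf(
    "<tensor_field> %s grid, %d voxels fitted (b %s %g, %d directions), %d eigenvalue(s) clipped\n",
    paste(x$dims, collapse = "x"), length(x$voxel_index),
    if (x$shell_filter$include_max_b) "<=" else "<",
    x$shell_filter$max_b, x$shell_filter$n_directions, x$n_clipped
  ))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
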