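# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the TFCE oracle evaluates the defining
# discrete sum with igraph connected components; the tensor simulator
# evaluates exp(-b g' D g) directly.

# direct discrete-sum TFCE: for each threshold h = dh, 2dh, ..., label the
# connected components of {stat >= h} and add size^E * h^H * dh to every
# member voxel
tfce_oracle <- function(stat, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  d <- dim(stat)
  mx <- max(stat)
  if (mx <= 0) return(array(0, d))
  if (is.null(dh)) dh <- mx / 100
  nbr_ok <- function(da) {
    m <- sum(abs(da))
    m > 0 && ((connectivity == 26) || (connectivity == 18 && m <= 2) ||
                (connectivity == 6 && m <= 1))
  }
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[apply(offs, 1, nbr_ok), , drop = FALSE]
  out <- array(0, d)
  coords <- arrayInd(seq_len(prod(d)), d)
  for (k in seq_len(floor(mx / dh + 1e-12))) {
    h <- k * dh
    active <- which(stat >= h)
    if (!length(active)) break
    pos <- coords[active, , drop = FALSE]
    key <- (pos[, 1] - 1) + d[1] * (pos[, 2] - 1) + d[1] * d[2] * (pos[, 3] - 1)
    lookup <- integer(prod(d)); lookup[key + 1] <- seq_along(active)
    e_from <- integer(0); e_to <- integer(0)
    for (o in seq_len(nrow(offs))) {
      q <- sweep(pos, 2, as.numeric(offs[o, ]), "+")
      ok <- q[, 1] >= 1 & q[, 1] <= d[1] & q[, 2] >= 1 & q[, 2] <= d[2] &
        q[, 3] >= 1 & q[, 3] <= d[3]
      qk <- (q[ok, 1] - 1) + d[1] * (q[ok, 2] - 1) + d[1] * d[2] * (q[ok, 3] - 1)
      hit <- lookup[qk + 1]
      e_from <- c(e_from, which(ok)[hit > 0])
      e_to <- c(e_to, hit[hit > 0])
    }
    comp_sizes <- rep(1, length(active))
    if (length(e_from)) {
      g <- igraph::graph_from_edgelist(cbind(e_from, e_to), directed = FALSE)
      g <- igraph::add_vertices(g, max(0, length(active) - igraph::vcount(g)))
      cmp <- igraph::components(g)
      comp_sizes <- cmp$csize[cmp$membership[seq_along(active)]]
    }
    out[active] <- out[active] + comp_sizes^E * h^H * dh
  }
  out
}

# noiseless single-tensor DWI signal for a 3x3 tensor D (mm^2/s)
single_tensor_signal <- function(D, scheme, s0 = 1) {
  b <- scheme$bvals
  g <- scheme$bvecs
  s0 * exp(-b * rowSums((g %*% D) * g))
}

# wrap per-voxel signals (nvox x nvol) into a 4-D array + mask
as_dwi_array <- function(signals) {
  n <- nrow(signals)
  array(signals, c(n, 1, 1, ncol(signals)))
}

# straight tube of elevated FA along y, centered at (cx, cz), radius r
make_tube_fa <- function(dims = c(21L, 30L, 21L), cx = 11, cz = 11,
                         r = 3, inside = 0.6, outside = 0.05) {
  fa <- array(outside, dims)
  for (x in seq_len(dims[1])) {
    for (z in seq_len(dims[3])) {
      if ((x - cx)^2 + (z - cz)^2 <= r^2) fa[x, , z] <- inside
    }
  }
  fa
}

# minimal hand-built skeleton object (documented structure)
manual_skeleton <- function(voxels, perp, dims, voxel_size_mm = 2) {
  idx <- voxels[, 1] + dims[1] * (voxels[, 2] - 1) +
    dims[1] * dims[2] * (voxels[, 3] - 1)
  mask <- array(FALSE, dims); mask[idx] <- TRUE
  structure(list(mask = mask, idx = idx, perp = perp, dims = dims,
                 voxel_size_mm = voxel_size_mm),
            class = "skeleton_data")
}

# two planted blobs in 1-D giving a dissimilarity with known structure
blob_distance <- function(n1 = 5, n2 = 5, sep = 10, seed = 1) {
  set.seed(seed)
  x <- c(rnorm(n1, 0, 0.3), rnorm(n2, sep, 0.3))
  list(d = as.matrix(dist(x)), truth = rep(1:2, c(n1, n2)), x = x)
}

# one-step 6-neighborhood dilation of a logical 3-D mask
dilate1 <- function(mask) {
  d <- dim(mask)
  out <- mask
  sh <- function(m, axis, s) {
    idx <- seq_len(d[axis]) - s
    idx[idx < 1] <- 1; idx[idx > d[axis]] <- d[axis]
    if (axis == 1) m[idx, , , drop = FALSE]
    else if (axis == 2) m[, idx, , drop = FALSE]
    else m[, , idx, drop = FALSE]
  }
  for (axis in 1:3) for (s in c(-1, 1)) out <- out | sh(mask, axis, s)
  out
}
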