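test_that("a straight tube skeletonizes to its center line", {
  d <- c(21L, 30L, 21L)
  fa <- make_tube_fa(d)
  sk <- skeletonize(fa, 0.2, voxel_size_mm = 2)
  ai <- arrayInd(sk$idx, d)
  # the analytically known center line: (11, y, 11) for every y
  expect_setequal(
    paste(ai[, 1], ai[, 2], ai[, 3]),
    paste(11, 1:30, 11)
  )
  # no skeleton voxel on the tube surface
  expect_true(all((ai[, 1] - 11)^2 + (ai[, 3] - 11)^2 < 9))
  # perpendicular directions are unit vectors orthogonal to the tube axis
  expect_equal(rowSums(sk$perp^2), rep(1, nrow(sk$perp)), tolerance = 1e-8)
  expect_lt(max(abs(sk$perp[, 2])), 0.3)
})

test_that("sub-threshold maps raise the empty-skeleton error", {
  expect_error(skeletonize(array(0.1, c(10, 10, 10)), 0.2), "empty skeleton")
  expect_error(skeletonize(array(0.5, c(10, 10, 10)), 1.2), "fa_threshold")
})

test_that("mean_map is the voxelwise arithmetic mean with shape checks", {
  a <- array(runif(27), c(3, 3, 3))
  b <- array(runif(27), c(3, 3, 3))
  expect_identical(mean_map(list(a)), a)
  expect_identical(mean_map(list(a, a)), a)
  expect_equal(mean_map(list(a, b))[2, 2, 2], (a[2, 2, 2] + b[2, 2, 2]) / 2)
  expect_error(mean_map(list(a, array(0, c(3, 3, 4)))), "mismatched")
})

test_that("WM projection picks the perpendicular FA maximum", {
  d <- c(21L, 30L, 21L)
  fa <- make_tube_fa(d)
  sk <- skeletonize(fa, 0.2, voxel_size_mm = 2)
  # subject identical to mean: projects the skeleton voxel itself
  proj <- project_wm_metric(fa, fa, sk)
  expect_equal(proj, rep(0.6, length(sk$idx)))
  # constant metric: projection returns the constant regardless of search
  cmap <- array(7.5, d)
  expect_equal(project_wm_metric(fa, cmap, sk), rep(7.5, length(sk$idx)))
  expect_error(project_wm_metric(fa, fa, sk, search_mm = 1), "voxel size")
})

test_that("projection follows a one-voxel tract shift to the shifted center", {
  # planar ridge (sheet at x = 11): the perpendicular is unambiguously x
  d <- c(21L, 12L, 12L)
  mfa <- array(0.05, d); mfa[11, , ] <- 0.6
  sk <- skeletonize(mfa, 0.2, voxel_size_mm = 2)
  ai <- arrayInd(sk$idx, d)
  expect_true(all(ai[, 1] == 11))
  # subject sheet shifted one voxel in x, center marked by a distinct value
  sub_fa <- array(0.1, d); sub_fa[12, , ] <- 0.8
  metric <- array(0, d); metric[12, , ] <- 42
  proj <- project_wm_metric(sub_fa, metric, sk)
  expect_equal(proj, rep(42, length(sk$idx)))
})

test_that("projection equals the exhaustive perpendicular-search oracle", {
  set.seed(21)
  d <- c(18L, 18L, 18L)
  base <- gaussian_smooth_3d(array(runif(prod(d)), d), 1.5)
  base <- 0.15 + 0.5 * (base - min(base)) / diff(range(base))
  sk <- skeletonize(base, 0.3, voxel_size_mm = 2)
  sub_fa <- gaussian_smooth_3d(array(runif(prod(d)), d), 1)
  metric <- array(rnorm(prod(d)), d)
  proj <- project_wm_metric(sub_fa, metric, sk, search_mm = 6)
  K <- 3  # floor(6 mm / 2 mm)
  for (i in seq_along(sk$idx)) {
    v <- arrayInd(sk$idx[i], d)[1, ]
    cand <- unique(t(vapply(
      c(0, -1, 1, -2, 2, -3, 3),
      function(t) v + round(t * sk$perp[i, ]), numeric(3)
    )))
    keep <- apply(cand, 1, function(p) all(p >= 1 & p <= d))
    cand <- cand[keep, , drop = FALSE]
    vals <- sub_fa[cand]
    expect_equal(proj[i], metric[cand[which.max(vals), , drop = FALSE]])
  }
})

test_that("GBSS fill reproduces hand-computed Gaussian weights", {
  d <- c(9L, 5L, 5L)
  # three skeleton voxels on a line; 2 mm spacing -> neighbor distances 2, 4 mm
  sk <- manual_skeleton(
    voxels = rbind(c(3, 3, 3), c(4, 3, 3), c(6, 3, 3)),
    perp = rbind(c(0, 0, 1), c(0, 0, 1), c(0, 0, 1)),
    dims = d, voxel_size_mm = 2
  )
  ns <- 5
  gm <- rep(list(array(0.9, d)), ns)
  met <- rep(list(array(0, d)), ns)
  a <- 2; b <- 5
  for (s in 1:ns) {
    met[[s]][3, 3, ] <- a; met[[s]][6, 3, ] <- b; met[[s]][4, 3, ] <- 99
  }
  # subject 1 fails the GM threshold along the middle voxel's search line
  gm[[1]][4, 3, ] <- 0.5
  res <- project_gm_metric(gm, met, sk, gm_thresh = 0.65, subject_frac = 0.75,
                           sigma_mm = 2)
  expect_true(all(res$retained))  # middle voxel valid in 4/5 = 0.8 > 0.75
  w1 <- exp(-2^2 / (2 * 2^2)); w2 <- exp(-4^2 / (2 * 2^2))
  expect_equal(res$values[2, 1], (a * w1 + b * w2) / (w1 + w2))
  # subjects with no hole keep the argmax-GM-probability projection
  expect_equal(res$values[2, 2], 99)
  expect_false(res$validity[2, 1])
  expect_true(all(res$validity[, 2:5]))
})

test_that("GBSS thresholding and unfillable reporting behave at the edges", {
  d <- c(9L, 5L, 5L)
  sk <- manual_skeleton(rbind(c(3, 3, 3), c(6, 3, 3)),
                        rbind(c(0, 0, 1), c(0, 0, 1)), d, voxel_size_mm = 2)
  gm <- list(array(0.9, d), array(0.9, d))
  met <- list(array(1, d), array(2, d))
  # impossible threshold: zero retained voxels
  res <- project_gm_metric(gm, met, sk, gm_thresh = 1.01)
  expect_equal(sum(res$retained), 0)
  # isolated hole beyond 3 sigma of any donor: reported unfillable
  gm[[1]][3, 3, ] <- 0.5
  res <- project_gm_metric(gm, met, sk, gm_thresh = 0.65, subject_frac = 0.4,
                           sigma_mm = 1)
  expect_true(is.na(res$values[1, 1]))
  expect_equal(nrow(res$unfillable), 1)
  expect_equal(res$unfillable$subject, 1)
})

test_that("raising GM thresholds never grows the retained voxel set", {
  set.seed(5)
  d <- c(12L, 12L, 8L)
  sk_vox <- cbind(sample(2:11, 20, TRUE), sample(2:11, 20, TRUE),
                  sample(2:7, 20, TRUE))
  sk_vox <- sk_vox[!duplicated(sk_vox), , drop = FALSE]
  sk <- manual_skeleton(sk_vox,
                        matrix(rep(c(0, 0, 1), nrow(sk_vox)), ncol = 3,
                               byrow = TRUE), d, voxel_size_mm = 2)
  gm <- lapply(1:6, function(s) array(runif(prod(d), 0.3, 1), d))
  met <- lapply(1:6, function(s) array(rnorm(prod(d)), d))
  ret <- function(th, fr) {
    project_gm_metric(gm, met, sk, gm_thresh = th, subject_frac = fr)$retained
  }
  r0 <- ret(0.55, 0.5)
  expect_true(all(ret(0.75, 0.5) <= r0))
  expect_true(all(ret(0.55, 0.8) <= r0))
})
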