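#' Threshold-free cluster enhancement
#'
#' Integrates cluster support over all thresholds:
#' `enhanced(v) = sum_{h = dh, 2dh, ... <= stat(v)} e(h, v)^E * h^H * dh`,
#' where `e(h, v)` is the size of the connected component containing `v`
#' among voxels at or above `h`. Defaults follow the published TFCE
#' recommendation: `E = 0.5`, `H = 2`, `dh = max(stat)/100`,
#' 26-connectivity. Negative statistic values are handled by enhancing
#' the positive part and the negated map separately and recombining with
#' sign.
#'
#' @param stat_map 3-D array of finite statistic values.
#' @param E,H Extent and height exponents (> 0).
#' @param dh Integration step (> 0); default `max(abs(stat))/100`.
#' @param connectivity 6, 18 or 26 (default).
#' @return 3-D array of enhanced values (signed like the input).
#' @export
tfce <- function(stat_map, E = 0.5, H = 2, dh = NULL, connectivity = 26) {
  if (any(!is.finite(stat_map))) stop("stat_map contains non-finite values")
  stopifnot(E > 0, H > 0, connectivity %in% c(6, 18, 26))
  d <- dim(stat_map)
  stopifnot(length(d) == 3L)
  mx <- max(abs(stat_map))
  if (mx == 0) return(array(0, d))
  if (is.null(dh)) dh <- mx / 100
  stopifnot(dh > 0)
  pos <- pmax(stat_map, 0)
  neg <- pmax(-stat_map, 0)
  out <- tfce_cpp(as.numeric(pos), as.integer(d), E, H, dh, as.integer(connectivity))
  if (any(neg > 0)) {
    out <- out - tfce_cpp(as.numeric(neg), as.integer(d), E, H, dh,
                          as.integer(connectivity))
  }
  array(out, d)
}

#' Design specification for a two-group voxelwise comparison
#'
#' @param group Factor or vector with exactly two levels.
#' @param covariates Data frame or matrix of per-subject covariates
#'   (complete; no missing values), or `NULL`.
#' @param contrast Direction of the tested difference:
#'   `"group2_less"` tests level2 < level1, `"group2_greater"` the
#'   reverse.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(group, covariates = NULL,
                        contrast = c("group2_less", "group2_greater")) {
  contrast <- match.arg(contrast)
  group <- as.factor(group)
  if (nlevels(group) != 2L) stop("group must have exactly two levels")
  if (any(table(group) == 0)) stop("both groups must be non-empty")
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    if (any(!is.finite(covariates))) {
      stop("covariates must be complete (finite) for all subjects")
    }
    if (nrow(covariates) != length(group)) {
      stop("covariate rows must match the number of subjects")
    }
  }
  structure(list(group = group, covariates = covariates, contrast = contrast),
            class = "design_spec")
}

#' Permutation inference with TFCE (Freedman-Lane)
#'
#' Voxelwise two-group inference on skeleton-projected (or any masked)
#' data with nuisance covariates removed by the Freedman-Lane scheme: the
#' reduced (covariate-only) model is fitted once, its residuals are
#' permuted across subjects, refitted data are scored with the contrast
#' t-statistic, TFCE-enhanced, and the maximum enhanced statistic per
#' permutation forms the null distribution for family-wise-error
#' corrected p-values. When `n!` (the exact permutation count) does not
#' exceed `n_perm`, all permutations are enumerated instead of sampled.
#'
#' @param values Matrix (voxel x subject) of metric values.
#' @param voxel_idx Linear indices of the rows' voxels within `dims`.
#' @param dims Grid dimensions (for TFCE connectivity).
#' @param design A [design_spec()].
#' @param tfce_params List with `E`, `H`, `dh` (NULL = auto per map),
#'   `connectivity`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Integer seed; results are reproducible given the seed.
#' @return Object of class `permutation_result`: `t_map` and
#'   `enhanced` (vectors over voxels), FWER `p` per voxel, the null
#'   maximum distribution, and bookkeeping (`n_perm`, `exact`, `seed`).
#' @export
permutation_inference <- function(values, voxel_idx, dims, design,
                                  tfce_params = list(E = 0.5, H = 2,
                                                     dh = NULL,
                                                     connectivity = 26),
                                  n_perm = 5000, seed = 1L) {
  stopifnot(inherits(design, "design_spec"))
  if (n_perm < 100) stop("n_perm must be >= 100")
  n <- ncol(values)
  if (length(design$group) != n) stop("design does not match subject count")
  g <- as.numeric(design$group == levels(design$group)[2])
  if (design$contrast == "group2_less") g <- -g
  Z <- cbind(intercept = rep(1, n), design$covariates)

  # confounding check: group must not lie in the covariate span
  gz <- stats::lm.fit(Z, g)$residuals
  if (sqrt(sum(gz^2)) < 1e-10 * max(1, sqrt(sum(g^2)))) {
    stop("confounded design: group is contained in the covariate span")
  }

  qrZ <- qr(Z)
  fitted_red <- t(qr.fitted(qrZ, t(values)))   # voxel x subject
  resid_red <- values - fitted_red

  X <- cbind(g, Z)
  p_full <- qr(X)$rank
  df <- n - p_full
  if (df <= 0) stop("no residual degrees of freedom")
  gz_norm2 <- sum(gz^2)

  t_stat <- function(Y) {  # Y: voxel x subject
    bg <- as.numeric(Y %*% gz) / gz_norm2
    res <- t(qr.resid(qr(X), t(Y)))
    s2 <- rowSums(res^2) / df
    se <- sqrt(pmax(s2, 0) / gz_norm2)
    tv <- ifelse(se > 0, bg / se, 0)
    tv[abs(tv) < 1e-8] <- 0   # snap cancellation noise to an exact null
    tv
  }

  embed_enhance <- function(tv) {
    a <- array(0, dims)
    a[voxel_idx] <- tv
    e <- tfce(a, E = tfce_params$E, H = tfce_params$H,
              dh = tfce_params$dh,
              connectivity = tfce_params$connectivity %||% 26)
    e[voxel_idx]
  }

  t_obs <- t_stat(values)
  enh_obs <- embed_enhance(t_obs)

  exact <- factorial(n) <= n_perm
  set.seed(as.integer(seed))
  if (exact) {
    perms <- pracma::perms(seq_len(n))
    perms <- perms[-which(apply(perms, 1, identical, seq_len(n)))[1], ,
                   drop = FALSE]
  } else {
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  max_null <- numeric(nrow(perms))
  for (k in seq_len(nrow(perms))) {
    Yk <- fitted_red + resid_red[, perms[k, ], drop = FALSE]
    max_null[k] <- max(0, embed_enhance(t_stat(Yk)))
  }
  np <- length(max_null)
  p <- (1 + vapply(enh_obs, function(e) sum(max_null >= e), numeric(1))) /
    (np + 1)
  structure(
    list(t_map = t_obs, enhanced = enh_obs, p = p, voxel_idx = voxel_idx,
         dims = dims, max_null = max_null, n_perm = np, exact = exact,
         seed = seed, contrast = design$contrast),
    class = "permutation_result"
  )
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %d voxels, %d permutations%s; min FWER p = %.4g, %d voxel(s) with p < 0.05\n",
    length(x$p), x$n_perm, if (x$exact) " (exact)" else "",
    min(x$p), sum(x$p < 0.05)
  ))
  invisible(x)
}

#' Per-subject per-region means of projected metrics
#'
#' @param values Matrix (skeleton voxel x subject) of projected values.
#' @param region_labels Integer/character label per skeleton voxel;
#'   voxels with label 0 / NA are excluded and counted.
#' @param subjects Optional subject ids (defaults to `subj###`).
#' @return Tibble with columns `subject`, `region`, `mean`, `n_voxels`;
#'   regions with zero skeleton voxels are emitted as NA rows. The count
#'   of unlabeled voxels is attached as attribute `n_unlabeled`.
#' @export
roi_summary <- function(values, region_labels, subjects = NULL) {
  stopifnot(nrow(values) == length(region_labels))
  subjects <- subjects %||% sprintf("subj%03d", seq_len(ncol(values)))
  unlab <- is.na(region_labels) | region_labels == 0
  lab <- region_labels[!unlab]
  v <- values[!unlab, , drop = FALSE]
  out <- tidyr::expand_grid(subject = subjects,
                            region = sort(unique(as.character(lab))))
  means <- vapply(seq_len(nrow(out)), function(r) {
    sel <- as.character(lab) == out$region[r]
    s <- match(out$subject[r], subjects)
    mean(v[sel, s], na.rm = TRUE)
  }, numeric(1))
  nvox <- vapply(out$region, function(rg) sum(as.character(lab) == rg), 1L)
  out$mean <- means
  out$n_voxels <- nvox
  attr(out, "n_unlabeled") <- sum(unlab)
  out
}

#' Covariate-adjusted group comparison (ANOVA) with Bonferroni correction
#'
#' Linear-model F test of the group effect on a numeric outcome after
#' adjusting for covariates, with an explicit caller-supplied Bonferroni
#' family size (`adjusted p = min(1, p * bonferroni_m)`).
#'
#' @param data Data frame of per-subject records.
#' @param outcome,group Column names (strings).
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @param bonferroni_m Family size for the Bonferroni multiplier
#'   (default 1 = no correction).
#' @return One-row tibble: `outcome`, `F`, `df1`, `df2`, `p`, `p_bonferroni`.
#'   A constant outcome yields NA statistics with a note.
#' @export
adjusted_group_comparison <- function(data, outcome, group,
                                      covariates = character(),
                                      bonferroni_m = 1) {
  y <- data[[outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric")
  if (stats::sd(y, na.rm = TRUE) == 0 || all(is.na(y))) {
    return(tibble::tibble(outcome = outcome, F = NA_real_, df1 = NA_real_,
                          df2 = NA_real_, p = NA_real_,
                          p_bonferroni = NA_real_,
                          note = "constant outcome: F undefined"))
  }
  rhs_red <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste(outcome, "~",
                                    paste(c(group, covariates),
                                          collapse = " + ")))
  f_red <- stats::as.formula(paste(outcome, "~", rhs_red))
  full <- stats::lm(f_full, data = data)
  red <- stats::lm(f_red, data = data)
  a <- stats::anova(red, full)
  Fv <- a$F[2]; p <- a$`Pr(>F)`[2]
  if (is.na(Fv) && abs(a$`Sum of Sq`[2]) < 1e-12 * max(a$RSS[1], 1)) {
    Fv <- 0; p <- 1   # group adds no explained variance beyond rounding
  }
  tibble::tibble(outcome = outcome, F = Fv, df1 = a$Df[2],
                 df2 = a$Res.Df[2], p = p,
                 p_bonferroni = pmin(1, p * bonferroni_m),
                 note = NA_character_)
}

#' Partial Pearson correlation with covariate adjustment
#'
#' Pearson correlation of the residuals of `x` and `y` after linear
#' adjustment for the covariates; the p-value uses the t transform with
#' `n - k - 2` degrees of freedom (k = number of covariates).
#'
#' @param x,y Numeric vectors.
#' @param covariates Data frame / matrix of covariates, or `NULL`.
#' @return One-row tibble with `r`, `df`, `t`, `p` (two-sided). Residuals
#'   with zero variance yield NA with a note.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  k <- 0L
  if (!is.null(covariates)) {
    covariates <- as.matrix(as.data.frame(covariates))
    k <- ncol(covariates)
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  Z <- cbind(rep(1, n), covariates)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (stats::sd(rx) <= 1e-10 * max(stats::sd(x), .Machine$double.xmin) ||
      stats::sd(ry) <= 1e-10 * max(stats::sd(y), .Machine$double.xmin)) {
    return(tibble::tibble(r = NA_real_, df = NA_real_, t = NA_real_,
                          p = NA_real_,
                          note = "zero-variance residuals: undefined"))
  }
  r <- stats::cor(rx, ry)
  df <- n - k - 2
  tv <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tv), df)
  tibble::tibble(r = r, df = df, t = tv, p = p, note = NA_character_)
}
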