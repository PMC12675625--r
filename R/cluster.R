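#' Gower dissimilarity specification
#'
#' @param types Named character vector: `"continuous"`, `"binary"` or
#'   `"categorical"` per variable.
#' @param weights Named non-negative weights (default 1 each; not all
#'   zero).
#' @param ranges Optional named ranges for continuous variables; when
#'   absent they are computed from the observed sample.
#' @return Object of class `gower_spec`.
#' @export
gower_spec <- function(types, weights = NULL, ranges = NULL) {
  stopifnot(all(types %in% c("continuous", "binary", "categorical")))
  vars <- names(types)
  if (is.null(vars)) stop("types must be named by variable")
  w <- stats::setNames(rep(1, length(vars)), vars)
  if (!is.null(weights)) w[names(weights)] <- weights
  if (any(w < 0) || all(w == 0)) stop("weights must be >= 0 and not all zero")
  if (!is.null(ranges) && any(ranges <= 0)) stop("ranges must be positive")
  structure(list(types = types, weights = w, ranges = ranges),
            class = "gower_spec")
}

#' @rdname gower_spec
#' @param registry A variable registry (see
#'   [default_variable_registry()]); rows flagged `use_in_clustering`
#'   become the spec.
#' @export
gower_spec_from_registry <- function(registry) {
  r <- registry[registry$use_in_clustering, ]
  gower_spec(stats::setNames(r$type, r$variable))
}

#' Gower distance over mixed-type variables
#'
#' `d(i, j) = sum_v w_v d_v(i,j) s_v(i,j) / sum_v w_v d_v(i,j)` with
#' per-variable score `s_v = |x_i - x_j| / range_v` for continuous
#' variables and the mismatch indicator for binary / categorical ones;
#' the availability indicator `d_v` drops a variable from a pair when
#' either value is missing (pairwise deletion). Distances lie in [0, 1].
#'
#' @param table Data frame holding (at least) the registered variables.
#' @param spec A [gower_spec()]; every listed variable must be a column.
#' @return Symmetric n x n distance matrix with zero diagonal.
#' @export
gower_distance <- function(table, spec) {
  vars <- names(spec$types)
  missing_cols <- setdiff(vars, names(table))
  if (length(missing_cols)) {
    stop("columns not in table: ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(table)
  num <- matrix(0, n, n)
  den <- matrix(0, n, n)
  for (v in vars) {
    w <- spec$weights[[v]]
    if (w == 0) next
    x <- table[[v]]
    obs <- !is.na(x)
    dd <- outer(obs, obs, `&`)
    if (spec$types[[v]] == "continuous") {
      x <- as.numeric(x)
      rg <- if (!is.null(spec$ranges) && v %in% names(spec$ranges)) {
        spec$ranges[[v]]
      } else {
        diff(range(x, na.rm = TRUE))
      }
      s <- if (rg > 0) abs(outer(x, x, `-`)) / rg else matrix(0, n, n)
    } else {
      s <- outer(x, x, `!=`) * 1
    }
    s[!dd] <- 0
    num <- num + w * s * dd
    den <- den + w * dd
  }
  if (any(den[upper.tri(den)] == 0)) {
    bad <- which(den == 0 & upper.tri(den), arr.ind = TRUE)[1, ]
    stop(sprintf("subjects %d and %d share no jointly observed variable",
                 bad[1], bad[2]))
  }
  d <- num / den
  diag(d) <- 0
  d
}

#' Partitioning around medoids (k-medoids)
#'
#' Minimizes the total distance of points to their nearest medoid. When
#' the number of candidate medoid sets `choose(n, k)` is at most 3000
#' the search is exhaustive and returns the certified optimum (ties
#' toward the lexicographically smallest set) — this covers all
#' desk-scale two-cluster problems. Beyond that, BUILD greedily seeds
#' `k` medoids (first: the point minimizing total distance; then
#' maximal-gain additions) and SWAP repeatedly applies the best
#' medoid/non-medoid exchange until none reduces the objective. All
#' ties break toward the lowest index, so the result is deterministic;
#' the objective is asserted non-increasing across SWAP iterations.
#'
#' @param dist Symmetric dissimilarity matrix.
#' @param k Number of clusters, `2 <= k <= n` (k = n gives each point its
#'   own medoid with objective 0).
#' @return List with `medoids` (indices), `labels` (cluster = position
#'   of the assigned medoid in `medoids`), `objective`.
#' @export
pam_fit <- function(dist, k) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (k < 2 || k > n) stop("k must lie in [2, n]")
  if (choose(n, k) <= 3000) {
    sets <- utils::combn(n, k)
    objs <- apply(sets, 2, function(m) {
      sum(apply(d[, m, drop = FALSE], 1, min))
    })
    med <- sets[, which.min(objs)]   # first = lexicographically smallest
    labels <- apply(d[, med, drop = FALSE], 1, which.min)
    labels[med] <- seq_along(med)
    return(list(medoids = unname(med), labels = unname(labels),
                objective = min(objs)))
  }
  # BUILD
  med <- unname(which.min(rowSums(d)))
  while (length(med) < k) {
    cur <- apply(d[, med, drop = FALSE], 1, min)
    gain <- vapply(seq_len(n), function(c) {
      if (c %in% med) return(-Inf)
      sum(pmax(cur - d[, c], 0))
    }, numeric(1))
    med <- c(med, unname(which.max(gain)))  # which.max: lowest-index tie
  }
  objective_of <- function(meds) sum(apply(d[, meds, drop = FALSE], 1, min))
  obj <- objective_of(med)
  # SWAP
  repeat {
    best <- list(delta = 0)
    for (mi in seq_along(med)) {
      for (h in seq_len(n)) {
        if (h %in% med) next
        cand <- med; cand[mi] <- h
        delta <- objective_of(cand) - obj
        if (delta < best$delta - 1e-12) best <- list(delta = delta, meds = cand)
      }
    }
    if (best$delta >= 0) break
    new_obj <- obj + best$delta
    stopifnot(new_obj <= obj)  # objective never increases across SWAP
    med <- best$meds
    obj <- new_obj
  }
  med <- sort(med)
  labels <- apply(d[, med, drop = FALSE], 1, which.min)
  labels[med] <- seq_along(med)  # medoids belong to their own cluster
  list(medoids = med, labels = labels, objective = objective_of(med))
}

#' Silhouette widths
#'
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean
#' within-cluster distance (excluding self) and `b` the minimum over
#' other clusters of the mean distance to that cluster. Members of
#' singleton clusters get `s = 0` by convention.
#'
#' @param dist Symmetric dissimilarity matrix.
#' @param labels Integer cluster labels (>= 2 distinct).
#' @return List with per-subject `widths` and the `mean` width.
#' @export
silhouette_widths <- function(dist, labels) {
  d <- as.matrix(dist)
  n <- nrow(d)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette requires at least 2 clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, own & seq_len(n) != i])
    b <- min(vapply(ks[ks != labels[i]], function(kk) {
      mean(d[i, labels == kk])
    }, numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  list(widths = s, mean = mean(s))
}

#' Calinski-Harabasz index for a dissimilarity clustering
#'
#' Distance-based generalization using medoids in place of centroids
#' (Gower space has no coordinates): within-cluster dispersion
#' `W = sum_i d(i, medoid(cluster_i))^2`, between-cluster dispersion
#' `B = sum_c n_c d(medoid_c, global_medoid)^2`, index
#' `CH = (B / (k - 1)) / (W / (n - k))`. Doubling all distances leaves
#' the ranking over k unchanged (both terms scale by 4).
#'
#' @inheritParams silhouette_widths
#' @return The CH scalar (`Inf` when W = 0).
#' @export
calinski_harabasz <- function(dist, labels) {
  d <- as.matrix(dist)
  n <- nrow(d)
  ks <- sort(unique(labels))
  k <- length(ks)
  if (k < 2) stop("Calinski-Harabasz requires at least 2 clusters")
  gmed <- which.min(rowSums(d))
  W <- 0; B <- 0
  for (kk in ks) {
    m <- which(labels == kk)
    med <- m[which.min(rowSums(d[m, m, drop = FALSE]))]
    W <- W + sum(d[m, med]^2)
    B <- B + length(m) * d[med, gmed]^2
  }
  if (W == 0) return(Inf)
  (B / (k - 1)) / (W / (n - k))
}

#' Select the number of clusters by mean silhouette
#'
#' Runs [pam_fit()] for each candidate k, selects the k with the highest
#' mean silhouette width (ties toward smaller k), and reports the
#' Calinski-Harabasz index alongside.
#'
#' @param dist Symmetric dissimilarity matrix.
#' @param k_range Candidate cluster counts within `[2, n - 1]`.
#' @return Object of class `cluster_solution`: `k`, `medoids`, `labels`,
#'   per-subject silhouette `widths`, `mean_silhouette`,
#'   `calinski_harabasz`, `unassigned` (empty until
#'   [flag_unassigned()]), and the per-k selection table `by_k`.
#' @export
select_k <- function(dist, k_range = 2:6) {
  n <- nrow(as.matrix(dist))
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]")
  }
  fits <- lapply(k_range, function(k) pam_fit(dist, k))
  sil <- lapply(fits, function(f) silhouette_widths(dist, f$labels))
  ch <- vapply(fits, function(f) calinski_harabasz(dist, f$labels), numeric(1))
  means <- vapply(sil, `[[`, numeric(1), "mean")
  best <- which(means == max(means))[1]  # ties: smaller k first in order
  structure(
    list(
      k = k_range[best], medoids = fits[[best]]$medoids,
      labels = fits[[best]]$labels, widths = sil[[best]]$widths,
      mean_silhouette = means[best], calinski_harabasz = ch[best],
      objective = fits[[best]]$objective,
      unassigned = integer(0),
      by_k = tibble::tibble(k = k_range, mean_silhouette = means,
                            calinski_harabasz = ch)
    ),
    class = "cluster_solution"
  )
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf(
    "<cluster_solution> k = %d (mean silhouette %.3f, CH %.2f), sizes: %s%s\n",
    x$k, x$mean_silhouette, x$calinski_harabasz,
    paste(table(x$labels), collapse = "/"),
    if (length(x$unassigned)) sprintf(", %d unassigned", length(x$unassigned))
    else ""
  ))
  invisible(x)
}

#' @rdname select_k
#' @param x A `cluster_solution`.
#' @param ... Unused.
#' @method tidy cluster_solution
#' @export
tidy.cluster_solution <- function(x, ...) {
  tibble::tibble(
    subject = seq_along(x$labels),
    cluster = ifelse(seq_along(x$labels) %in% x$unassigned,
                     NA_integer_, x$labels),
    silhouette = x$widths,
    medoid = seq_along(x$labels) %in% x$medoids
  )
}

#' @rdname select_k
#' @method glance cluster_solution
#' @export
glance.cluster_solution <- function(x, ...) {
  tibble::tibble(k = x$k, mean_silhouette = x$mean_silhouette,
                 calinski_harabasz = x$calinski_harabasz,
                 objective = x$objective,
                 n_unassigned = length(x$unassigned))
}

#' @rdname select_k
#' @param object A `cluster_solution`.
#' @method autoplot cluster_solution
#' @export
autoplot.cluster_solution <- function(object, ...) {
  df <- tidy.cluster_solution(object)
  df <- df[order(df$cluster, -df$silhouette), ]
  df$pos <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$silhouette,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "subjects (sorted within cluster)",
                  y = "silhouette width", fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Flag unassigned subjects by silhouette width
#'
#' Subjects whose silhouette width is at or below `width_threshold`
#' (default 0: sitting on or across a cluster boundary) are moved to the
#' unassigned list. This is an explicit artifact convention — the
#' simplest internal criterion that can leave subjects in neither group.
#'
#' @param solution A `cluster_solution`.
#' @param width_threshold Threshold on the silhouette width, default 0.
#' @return The solution with `unassigned` filled in.
#' @export
flag_unassigned <- function(solution, width_threshold = 0) {
  stopifnot(inherits(solution, "cluster_solution"))
  solution$unassigned <- which(solution$widths <= width_threshold)
  solution
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement of two partitions of the same subjects,
#' from the contingency table under the permutation model: 1 for
#' identical partitions, expectation ~0 under independence.
#'
#' @param labels_a,labels_b Cluster labels of equal length.
#' @return The ARI scalar.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) == 0 || length(labels_a) != length(labels_b)) {
    stop("labelings must be non-empty and of equal length")
  }
  tab <- table(labels_a, labels_b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  a <- sum(ch2(rowSums(tab)))
  b <- sum(ch2(colSums(tab)))
  tot <- ch2(length(labels_a))
  expected <- a * b / tot
  mx <- (a + b) / 2
  if (mx == expected) return(ifelse(sum_ij == mx, 1, 0))
  (sum_ij - expected) / (mx - expected)
}

#' Bootstrap stability of a k-medoids solution
#'
#' For each of `n_boot` resamples (subjects drawn with replacement) the
#' Gower distance and k-medoids partition are recomputed and compared to
#' the full-data solution by the adjusted Rand index on the unique
#' subjects present in the resample (duplicates contribute once).
#' Resamples with fewer than `k + 1` unique subjects are redrawn (count
#' logged in `n_redrawn`).
#'
#' @param table Cohort data frame (e.g. the patient rows).
#' @param spec A [gower_spec()].
#' @param k Number of clusters.
#' @param n_boot Number of resamples (study setting: 1000).
#' @param seed Integer seed.
#' @return List with the `ari` vector, `mean`, `quantiles`
#'   (2.5/25/50/75/97.5%), `n_boot`, `n_redrawn`.
#' @export
bootstrap_stability <- function(table, spec, k = 2, n_boot = 1000, seed = 1L) {
  if (n_boot < 1) stop("n_boot must be >= 1")
  n <- nrow(table)
  full <- pam_fit(gower_distance(table, spec), k)
  set.seed(as.integer(seed))
  ari <- numeric(n_boot)
  n_redrawn <- 0L
  for (bb in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(idx)) >= k + 1) break
      n_redrawn <- n_redrawn + 1L
    }
    dres <- gower_distance(table[idx, , drop = FALSE], spec)
    fit <- pam_fit(dres, k)
    first <- !duplicated(idx)
    ari[bb] <- adjusted_rand_index(full$labels[idx[first]], fit$labels[first])
  }
  list(ari = ari, mean = mean(ari),
       quantiles = stats::quantile(ari, c(0.025, 0.25, 0.5, 0.75, 0.975)),
       n_boot = n_boot, n_redrawn = n_redrawn)
}
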