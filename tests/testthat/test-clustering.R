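test_that("Gower distance matches hand evaluation and stays in [0, 1]", {
  tab <- data.frame(
    a = c(1, 1, 5), b = c(0, 1, 1), c = c("x", "x", "y"),
    stringsAsFactors = FALSE
  )
  spec <- gower_spec(c(a = "continuous", b = "binary", c = "categorical"))
  d <- gower_distance(tab, spec)
  expect_equal(diag(d), rep(0, 3))
  expect_equal(d, t(d))
  # rows 1 and 2 differ only in one binary among m = 3 observed variables
  expect_equal(d[1, 2], 1 / 3)
  expect_true(all(d >= 0 & d <= 1))
  # identical rows at distance 0; all-different binary rows at 1
  tb <- data.frame(u = c(0, 1), v = c(1, 0))
  db <- gower_distance(tb, gower_spec(c(u = "binary", v = "binary")))
  expect_equal(db[1, 2], 1)
  expect_equal(gower_distance(tab[c(1, 1), ], spec)[1, 2], 0)
})

test_that("Gower handles missing values by pairwise deletion", {
  tab <- data.frame(a = c(1, NA, 3), b = c(0, 1, 1))
  spec <- gower_spec(c(a = "continuous", b = "binary"))
  d <- gower_distance(tab, spec)
  expect_equal(d[1, 2], 1)         # only b observed for the pair
  expect_equal(d[2, 3], 0)         # b agrees, a dropped
  none <- data.frame(a = c(1, NA), b = c(NA, 1))
  expect_error(gower_distance(none, gower_spec(c(a = "continuous",
                                                 b = "continuous"))),
               "jointly observed")
  expect_error(gower_distance(tab, gower_spec(c(zz = "binary"))),
               "not in table")
})

test_that("Gower agrees with cluster::daisy on complete mixed data", {
  set.seed(16)
  tab <- data.frame(x = rnorm(15), y = runif(15),
                    f = factor(sample(c("p", "q"), 15, TRUE)))
  spec <- gower_spec(c(x = "continuous", y = "continuous", f = "categorical"))
  ours <- gower_distance(tab, spec)
  ref <- as.matrix(cluster::daisy(tab, metric = "gower"))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("PAM equals exhaustive search over medoid pairs for n <= 8", {
  set.seed(17)
  for (r in 1:20) {
    n <- sample(5:8, 1)
    d <- as.matrix(dist(matrix(rnorm(n * 2), n, 2)))
    fit <- pam_fit(d, 2)
    pairs <- utils::combn(n, 2)
    objs <- apply(pairs, 2, function(p) {
      sum(pmin(d[, p[1]], d[, p[2]]))
    })
    expect_equal(fit$objective, min(objs), tolerance = 1e-12)
  }
})

test_that("PAM base cases: degenerate k, planted blobs, determinism", {
  bd <- blob_distance(5, 5, sep = 10, seed = 18)
  fit <- pam_fit(bd$d, 2)
  expect_equal(adjusted_rand_index(fit$labels, bd$truth), 1)
  # medoids are members of their own clusters
  expect_equal(fit$labels[fit$medoids], seq_along(fit$medoids))
  # k = n: every point its own medoid, objective 0
  fitn <- pam_fit(bd$d, nrow(bd$d))
  expect_equal(fitn$objective, 0)
  expect_equal(sort(fitn$medoids), 1:10)
  expect_error(pam_fit(bd$d, 1), "k must")
  # same input twice: identical output (deterministic tie-breaking)
  expect_identical(pam_fit(bd$d, 3), pam_fit(bd$d, 3))
})

test_that("PAM reaches the same objective as cluster::pam on random data", {
  set.seed(19)
  for (r in 1:5) {
    d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
    ours <- pam_fit(d, 3)$objective
    ref <- cluster::pam(stats::as.dist(d), 3, diss = TRUE)$objective[["swap"]] * 12
    expect_lte(ours, ref + 1e-9)
  }
})

test_that("silhouette widths match brute force and the package oracle", {
  set.seed(20)
  d <- as.matrix(dist(matrix(rnorm(24), 12, 2)))
  lab <- pam_fit(d, 3)$labels
  res <- silhouette_widths(d, lab)
  # direct evaluation of the defining formula (singletons: convention 0)
  for (i in 1:12) {
    if (sum(lab == lab[i]) == 1) {
      expect_equal(res$widths[i], 0)
      next
    }
    a <- mean(d[i, lab == lab[i] & seq_len(12) != i])
    b <- min(vapply(setdiff(unique(lab), lab[i]),
                    function(k) mean(d[i, lab == k]), numeric(1)))
    expect_equal(res$widths[i], (b - a) / max(a, b))
  }
  ref <- cluster::silhouette(lab, stats::as.dist(d))
  expect_equal(res$widths, unname(ref[, "sil_width"]), tolerance = 1e-12)
  # two tight far blobs: mean silhouette near 1
  bd <- blob_distance(6, 6, sep = 50, seed = 21)
  expect_gt(silhouette_widths(bd$d, bd$truth)$mean, 0.9)
  # a point equidistant to its own and the other cluster has width 0
  deq <- matrix(1, 3, 3); diag(deq) <- 0
  expect_equal(silhouette_widths(deq, c(1, 1, 2))$widths[3], 0)
  expect_error(silhouette_widths(d, rep(1, 12)), "2 clusters")
})

test_that("singleton clusters take silhouette width 0 by convention", {
  d <- as.matrix(dist(c(0, 0.1, 5)))
  expect_equal(silhouette_widths(d, c(1, 1, 2))$widths[3], 0)
})

test_that("Calinski-Harabasz prefers the true k and scales consistently", {
  # two equally spread, far-apart blobs (deterministic construction)
  x <- c(seq(0, 0.5, by = 0.1), seq(20, 20.5, by = 0.1))
  d <- as.matrix(dist(x))
  lab2 <- pam_fit(d, 2)$labels
  lab3 <- pam_fit(d, 3)$labels
  expect_gt(calinski_harabasz(d, lab2), calinski_harabasz(d, lab3))
  # doubling all distances leaves the ranking unchanged
  expect_gt(calinski_harabasz(2 * d, lab2), calinski_harabasz(2 * d, lab3))
  expect_error(calinski_harabasz(d, rep(1, 12)), "2 clusters")
})

test_that("select_k picks two planted blobs and breaks ties toward small k", {
  bd <- blob_distance(7, 7, sep = 15, seed = 23)
  sol <- select_k(bd$d, 2:6)
  expect_equal(sol$k, 2)
  expect_equal(adjusted_rand_index(sol$labels, bd$truth), 1)
  expect_equal(nrow(sol$by_k), 5)
  # flat all-equal distances: every k ties; the smallest k is returned
  flat <- matrix(1, 6, 6); diag(flat) <- 0
  expect_equal(select_k(flat, 2:4)$k, 2)
  # n = 3 with a single candidate k
  d3 <- as.matrix(dist(c(0, 1, 5)))
  expect_equal(select_k(d3, 2)$k, 2)
  expect_error(select_k(d3, 2:5), "k_range")
})

test_that("flag_unassigned moves boundary subjects out by silhouette", {
  bd <- blob_distance(6, 6, sep = 10, seed = 24)
  sol <- select_k(bd$d, 2:3)
  expect_length(flag_unassigned(sol)$unassigned, 0)   # all widths positive
  expect_length(flag_unassigned(sol, width_threshold = 1)$unassigned, 12)
  # a constructed boundary point with non-positive width is flagged alone
  x <- c(0, 0.2, 0.4, 10, 10.2, 10.4, 5.2)
  d <- as.matrix(dist(x))
  fit <- pam_fit(d, 2)
  sil <- silhouette_widths(d, fit$labels)
  sol2 <- structure(list(k = 2, medoids = fit$medoids, labels = fit$labels,
                         widths = sil$widths, mean_silhouette = sil$mean,
                         calinski_harabasz = 1, objective = fit$objective,
                         unassigned = integer(0)),
                    class = "cluster_solution")
  flagged <- flag_unassigned(sol2, width_threshold = 0.1)
  expect_equal(flagged$unassigned, 7L)
})

test_that("adjusted Rand index: identities, chance level, and brute force", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(rep(1, 8), rep(1:2, 4)), 0)
  set.seed(25)
  for (r in 1:10) {
    a <- sample(1:3, 10, TRUE); b <- sample(1:3, 10, TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(integer(0), integer(0)), "non-empty")
})

test_that("bootstrap stability separates stable from overlapping structure", {
  set.seed(26)
  sep <- data.frame(x = c(rnorm(10, 0, 0.2), rnorm(10, 20, 0.2)))
  ovl <- data.frame(x = c(rnorm(10, 0, 2), rnorm(10, 2, 2)))
  spec <- gower_spec(c(x = "continuous"))
  bs_sep <- bootstrap_stability(sep, spec, k = 2, n_boot = 60, seed = 5)
  bs_ovl <- bootstrap_stability(ovl, spec, k = 2, n_boot = 60, seed = 5)
  expect_true(all(bs_sep$ari == 1))   # trivially stable structure
  expect_lt(bs_ovl$mean, bs_sep$mean)
  expect_error(bootstrap_stability(sep, spec, k = 2, n_boot = 0), "n_boot")
})

test_that("planted two-subgroup cohorts are recovered end to end", {
  tab <- make_clinical_table(seed = 31)
  pts <- tab[tab$group == "patient", ]
  spec <- gower_spec_from_registry(attr(tab, "registry"))
  d <- gower_distance(pts, spec)
  sol <- select_k(d, 2:6)
  expect_equal(sol$k, 2)
  expect_gte(adjusted_rand_index(sol$labels, pts$truth_cluster), 0.9)
  td <- tidy(sol)
  expect_equal(nrow(td), 44)
  g <- glance(sol)
  expect_equal(g$k, 2)
})
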