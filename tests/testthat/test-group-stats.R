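test_that("TFCE base cases: zero map, constant cluster, monotonicity", {
  expect_true(all(tfce(array(0, c(5, 5, 5))) == 0))
  # one connected cluster of n voxels at constant height h0
  m <- array(0, c(8, 8, 8))
  m[2:3, 2:4, 2] <- 1.5             # n = 6, h0 = 1.5
  dh <- 0.01
  e <- tfce(m, E = 0.5, H = 2, dh = dh, connectivity = 26)
  ks <- seq_len(floor(1.5 / dh))
  oracle <- 6^0.5 * sum((ks * dh)^2 * dh)
  expect_equal(e[2, 2, 2], oracle, tolerance = 1e-10)
  expect_equal(e[3, 4, 2], oracle, tolerance = 1e-10)
  # raising any voxel never decreases any enhanced value
  m2 <- m; m2[3, 3, 2] <- 2.5
  e2 <- tfce(m2, E = 0.5, H = 2, dh = dh, connectivity = 26)
  expect_true(all(e2 >= e - 1e-12))
  expect_error(tfce(array(c(1, NA, rep(0, 25)), c(3, 3, 3))), "non-finite")
})

test_that("TFCE equals the discrete-sum oracle on random maps", {
  set.seed(33)
  for (r in 1:6) {
    d <- sample(5:10, 3, replace = TRUE)
    m <- array(0, d)
    m[sample(prod(d), round(prod(d) * 0.3))] <- runif(round(prod(d) * 0.3))
    for (conn in c(6, 26)) {
      e <- tfce(m, E = 0.5, H = 2, dh = max(m) / 40, connectivity = conn)
      o <- tfce_oracle(m, E = 0.5, H = 2, dh = max(m) / 40,
                       connectivity = conn)
      expect_lt(max(abs(e - o)), 1e-6)
    }
  }
})

test_that("TFCE handles signed maps by separate enhancement", {
  m <- array(0, c(6, 6, 6))
  m[2, 2, 2] <- 1; m[5, 5, 5] <- -1
  e <- tfce(m, dh = 0.05)
  expect_gt(e[2, 2, 2], 0)
  expect_lt(e[5, 5, 5], 0)
  expect_equal(e[2, 2, 2], -e[5, 5, 5], tolerance = 1e-12)
})

test_that("identical groups give a zero statistic map and p = 1 everywhere", {
  set.seed(2)
  Y <- matrix(rnorm(50 * 6), 50, 6)
  Y <- cbind(Y, Y)   # duplicate the cohort as both groups
  des <- design_spec(rep(c("a", "b"), each = 6))
  pr <- permutation_inference(Y, 1:50, c(5, 5, 2), des, n_perm = 120,
                              seed = 4)
  expect_lt(max(abs(pr$t_map)), 1e-10)
  expect_true(all(pr$p == 1))
})

test_that("permutation p-values are bounded, seeded, and power is real", {
  set.seed(6)
  n <- 20
  Y <- matrix(rnorm(64 * n), 64, n)
  eff <- 1:8   # planted effect region
  Y[eff, 11:20] <- Y[eff, 11:20] + 3
  des <- design_spec(rep(c("ctl", "pat"), each = 10),
                     covariates = data.frame(age = rnorm(n)),
                     contrast = "group2_greater")
  p1 <- permutation_inference(Y, 1:64, c(4, 4, 4), des, n_perm = 150, seed = 7)
  p2 <- permutation_inference(Y, 1:64, c(4, 4, 4), des, n_perm = 150, seed = 7)
  expect_identical(p1$p, p2$p)
  expect_true(all(p1$p >= 1 / (p1$n_perm + 1) & p1$p <= 1))
  expect_lt(min(p1$p[eff]), 0.05)
  expect_error(permutation_inference(Y, 1:64, c(4, 4, 4), des, n_perm = 50),
               ">= 100")
})

test_that("confounded designs are rejected", {
  g <- rep(c("a", "b"), each = 6)
  des <- design_spec(g, covariates = data.frame(dup = as.numeric(g == "b")))
  Y <- matrix(rnorm(10 * 12), 10, 12)
  expect_error(permutation_inference(Y, 1:10, c(10, 1, 1), des, n_perm = 100),
               "confounded")
})

test_that("exact enumeration replaces sampling for tiny cohorts", {
  Y <- matrix(rnorm(4 * 4), 4, 4)
  des <- design_spec(rep(c("a", "b"), each = 2))
  pr <- permutation_inference(Y, 1:4, c(4, 1, 1), des, n_perm = 100, seed = 1)
  expect_true(pr$exact)
  expect_equal(pr$n_perm, factorial(4) - 1)
})

test_that("roi_summary averages projected values per region", {
  vals <- matrix(c(1, 2, 3, 4, 5,
                   10, 20, 30, 40, 50), 5, 2)
  lab <- c("A", "A", "B", "B", "B")
  out <- roi_summary(vals, lab, subjects = c("s1", "s2"))
  expect_equal(out$mean[out$subject == "s1" & out$region == "A"], 1.5)
  expect_equal(out$mean[out$subject == "s2" & out$region == "B"], 40)
  # constant map: every region mean is the constant
  cm <- roi_summary(matrix(3, 5, 1), lab)
  expect_true(all(cm$mean == 3))
  # single region: mean over the whole skeleton
  one <- roi_summary(vals, rep("all", 5), subjects = c("s1", "s2"))
  expect_equal(one$mean, c(3, 30))
  # unlabeled voxels excluded and counted
  out2 <- roi_summary(vals, c("A", "A", NA, "B", "B"))
  expect_equal(attr(out2, "n_unlabeled"), 1)
  expect_equal(out2$mean[out2$region == "B" & out2$subject == "subj001"], 4.5)
})

test_that("adjusted group comparisons behave at the null and under effects", {
  set.seed(12)
  df <- data.frame(y = rep(c(1, 2, 3, 1.5, 2.5, 3.5), 2),
                   g = rep(c("a", "b"), each = 6),
                   age = rep(rnorm(6), 2))  # identical groups incl. covariate
  out <- adjusted_group_comparison(df, "y", "g", "age")
  expect_lt(out$F, 1e-20)
  expect_gt(out$p, 0.999)
  # Bonferroni with family size 1 leaves p unchanged; family m multiplies
  set.seed(3)
  df2 <- data.frame(y = rnorm(40), g = rep(c("a", "b"), each = 20))
  o1 <- adjusted_group_comparison(df2, "y", "g")
  expect_equal(o1$p_bonferroni, o1$p)
  o8 <- adjusted_group_comparison(df2, "y", "g", bonferroni_m = 8)
  expect_equal(o8$p_bonferroni, min(1, o1$p * 8))
  # planted 3 SD shift at n = 30/30: p < 0.001 in nearly all seeds
  hits <- sum(vapply(1:40, function(s) {
    set.seed(s)
    d <- data.frame(y = c(rnorm(30), rnorm(30, 3)),
                    g = rep(c("a", "b"), each = 30), age = rnorm(60))
    adjusted_group_comparison(d, "y", "g", "age")$p < 0.001
  }, TRUE))
  expect_gte(hits / 40, 0.95)
  # constant outcome: undefined F reported as such
  cst <- adjusted_group_comparison(data.frame(y = rep(1, 10),
                                              g = rep(c("a", "b"), 5)),
                                   "y", "g")
  expect_true(is.na(cst$F))
  expect_match(cst$note, "constant")
})

test_that("partial correlation matches residualization and a matrix oracle", {
  set.seed(9)
  n <- 60
  z <- rnorm(n)
  x <- 2 * z + rnorm(n)
  y <- -1.5 * z + rnorm(n)
  out <- partial_correlation(x, y, data.frame(z = z))
  # oracle: partial correlation from the inverse correlation matrix
  P <- solve(stats::cor(cbind(x, y, z)))
  r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_equal(out$r, r_oracle, tolerance = 1e-10)
  # symmetry in x and y
  expect_equal(partial_correlation(y, x, data.frame(z = z))$r, out$r)
  # no covariates: plain Pearson r and its t-test p
  o0 <- partial_correlation(x, y)
  expect_equal(o0$r, stats::cor(x, y), tolerance = 1e-12)
  expect_equal(o0$p, stats::cor.test(x, y)$p.value, tolerance = 1e-10)
  # y = x: r = 1 regardless of covariates
  expect_equal(partial_correlation(x, x, data.frame(z = z))$r, 1,
               tolerance = 1e-12)
  # degenerate residuals reported, tiny n rejected
  expect_true(is.na(partial_correlation(z * 2, y, data.frame(z = z))$r))
  expect_error(partial_correlation(1:3, 1:3, data.frame(z = 1:3)), "n >")
})
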