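test_that("KS normality gate: D matches direct ECDF enumeration", {
  set.seed(3)
  x <- rnorm(12, 5, 2)
  res <- ks_normality(x)
  # oracle: D = max over sorted points of the two one-sided ECDF gaps
  xs <- sort(x)
  Fz <- pnorm(xs, mean(x), sd(x))
  n <- length(x)
  D <- max(pmax(seq_len(n) / n - Fz, Fz - (seq_len(n) - 1) / n))
  expect_equal(res$statistic, D, tolerance = 1e-12)
  expect_error(ks_normality(rep(1, 10)), "degenerate")
  expect_error(ks_normality(c(1, 2, 3)), "at least 4")
})

test_that("KS normality rejects a uniform sample", {
  set.seed(99)
  u <- runif(500)
  expect_lt(ks_normality(u)$p_value, 0.05)
})

test_that("Kruskal-Wallis: degenerate and small-sample behaviour", {
  g <- rep(c("a", "b", "c"), each = 4)
  res0 <- kruskal_wallis(rep(2, 12), g)
  expect_equal(res0$statistic, 0, ignore_attr = TRUE)
  expect_equal(res0$p_value, 1)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("Kruskal-Wallis p agrees with a permutation oracle at small n", {
  set.seed(21)
  x <- c(2.1, 3.4, 1.2, 5.5, 4.4, 6.1, 3.9, 7.2, 8.0, 6.6, 5.9, 9.1)
  g <- factor(rep(c("a", "b", "c"), each = 4))
  res <- kruskal_wallis(x, g, p_method = "permutation", reps = 20000)
  H_obs <- oracle_kw_H(x, g)
  expect_equal(res$statistic, H_obs, ignore_attr = TRUE, tolerance = 1e-10)
  H_perm <- replicate(20000, oracle_kw_H(x, sample(g)))
  p_perm <- (1 + sum(H_perm >= H_obs - 1e-12)) / 20001
  expect_lt(abs(res$p_value - p_perm), 0.01)
})

test_that("two-group Kruskal-Wallis matches the squared rank-sum z", {
  set.seed(5)
  x <- rnorm(30)
  g <- factor(rep(c("a", "b"), c(14, 16)))
  res <- kruskal_wallis(x, g)
  # normal-approximation Wilcoxon z (no ties in this sample): chi2 = z^2
  r <- rank(x)
  n1 <- 14; n2 <- 16; N <- 30
  W <- sum(r[g == "a"])
  z <- (W - n1 * (N + 1) / 2) / sqrt(n1 * n2 * (N + 1) / 12)
  expect_equal(res$statistic, z^2, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("contingency test reproduces the printed group comparisons", {
  seizure <- rbind(c(34, 31), c(24, 30), c(77, 39))
  res <- contingency_test(seizure, method = "chi2")
  expect_equal(round(res$p_value, 3), 0.016)
  cognitive <- rbind(c(6, 59), c(14, 40), c(3, 113))
  expect_lt(contingency_test(cognitive, method = "chi2")$p_value, 0.001)
  flat <- rbind(c(10, 10), c(10, 10))
  res0 <- contingency_test(flat, method = "chi2")
  expect_equal(res0$statistic, 0, ignore_attr = TRUE)
  expect_equal(res0$p_value, 1)
})

test_that("Pearson chi-square equals the textbook sum over random tables", {
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 20) + 1, nrow = 3)
    res <- contingency_test(tab, method = "chi2")
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E),
                 ignore_attr = TRUE, tolerance = 1e-10)
    expect_equal(res$df, (nrow(tab) - 1) * (ncol(tab) - 1),
                 ignore_attr = TRUE)
  }
})

test_that("Fisher exact p equals hypergeometric tail enumeration on 2x2", {
  set.seed(9)
  for (i in 1:15) {
    tab <- matrix(rpois(4, 4), nrow = 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- contingency_test(tab, method = "fisher")
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    p_oracle <- sum(probs[probs <= dhyper(tab[1, 1], m, n, k) * (1 + 1e-7)])
    expect_equal(res$p_value, p_oracle, tolerance = 1e-7)
  }
})

test_that("auto method switches to Fisher when expected counts are small", {
  small <- rbind(c(1, 9), c(8, 2))
  expect_equal(contingency_test(small, method = "auto")$test, "Fisher exact")
  big <- rbind(c(30, 31), c(24, 30), c(77, 39))
  expect_equal(contingency_test(big, method = "auto")$test,
               "Pearson chi-square")
})

test_that("zero-margin rows are dropped with a warning", {
  tab <- rbind(c(10, 5), c(0, 0), c(8, 9))
  expect_warning(res <- contingency_test(tab, method = "chi2"), "zero-margin")
  expect_equal(res$df, 1, ignore_attr = TRUE)
  expect_error(suppressWarnings(contingency_test(rbind(c(3, 0), c(5, 0)))),
               "2 x 2")
})

test_that("Mood median test composes dichotomisation with chi-square", {
  # identical distributions, even split -> chi2 0, p 1
  x <- rep(c(1, 2, 3, 4), times = 3)
  g <- rep(c("a", "b", "c"), each = 4)
  res0 <- mood_median_test(x, g)
  expect_equal(res0$statistic, 0, ignore_attr = TRUE)
  expect_equal(res0$p_value, 1)
  # composition oracle on arbitrary data: equals contingency_test on the
  # dichotomised table (ties to the <= median side)
  set.seed(10)
  x <- c(rnorm(20), rnorm(25, 1), rnorm(18, 0.5))
  g <- rep(c("a", "b", "c"), c(20, 25, 18))
  res <- mood_median_test(x, g)
  med <- median(x)
  tab <- table(g, x <= med)
  oracle <- chisq.test(tab, correct = FALSE)
  expect_equal(res$statistic, oracle$statistic, ignore_attr = TRUE)
  expect_equal(res$p_value, oracle$p.value)
  expect_error(mood_median_test(rep(3, 10), rep(c("a", "b"), 5)),
               "degenerate")
})

test_that("Mood median test detects shifted medians", {
  set.seed(14)
  x <- c(rnorm(30, 0), rnorm(30, 1.2), rnorm(30, 2.4))
  g <- rep(c("a", "b", "c"), each = 30)
  expect_lt(mood_median_test(x, g)$p_value, 0.05)
})

test_that("BH adjustment matches direct step-up enumeration", {
  p <- c(0.001, 0.006, 0.05, 0.9)
  expect_equal(bh_fdr(p), c(0.004, 0.012, 0.05 * 4 / 3, 0.9))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  # property: step-up enumeration oracle, monotone, >= raw
  set.seed(4)
  for (i in 1:10) {
    p <- runif(sample(3:12, 1))
    adj <- bh_fdr(p)
    m <- length(p)
    o <- order(p)
    stepup <- rev(cummin(rev(p[o] * m / seq_len(m))))
    oracle <- pmin(1, stepup)[match(seq_len(m), o)]
    expect_equal(adj, oracle)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(diff(adj[o]) >= -1e-12))
  }
})

test_that("type-I error of each battery test is near nominal under H0", {
  set.seed(2025)
  reps <- 2000
  n <- 20
  g <- factor(rep(c("a", "b", "c"), each = n))
  rej <- matrix(FALSE, reps, 3,
                dimnames = list(NULL, c("kw", "chi2", "median")))
  for (r in seq_len(reps)) {
    x <- rnorm(3 * n)
    b <- rbinom(3 * n, 1, 0.5)
    rej[r, "kw"] <- kruskal_wallis(x, g)$p_value < 0.05
    tab <- table(g, factor(b, levels = 0:1))
    rej[r, "chi2"] <- contingency_test(unclass(tab),
                                       method = "chi2")$p_value < 0.05
    rej[r, "median"] <- mood_median_test(x, g)$p_value < 0.05
  }
  rates <- colMeans(rej)
  expect_true(all(rates >= 0.03 & rates <= 0.07),
              info = paste(names(rates), round(rates, 3), collapse = ", "))
})

test_that("the battery runs over a cohort and applies one FDR family", {
  sim <- simulate_covariates(seed = 31)
  tab <- group_comparison_table(sim)
  expect_true(all(c("variable", "test", "p", "fdr") %in% names(tab)))
  expect_equal(attr(tab, "m"), nrow(tab))
  expect_true(all(tab$fdr >= tab$p - 1e-12))
  expect_equal(tab$fdr, bh_fdr(tab$p))
  expect_true(all(c("age", "volume_ml", "bg_voxel_count", "seizure")
                  %in% tab$variable))
  expect_equal(tab$test[tab$variable == "bg_voxel_count"], "Mood median")
  expect_equal(tab$test[tab$variable == "age"], "Kruskal-Wallis")
  # normality gate reported for continuous variables only
  expect_false(is.na(tab$ks_p[tab$variable == "age"]))
  expect_true(is.na(tab$ks_p[tab$variable == "seizure"]))
})
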