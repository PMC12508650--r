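# 2x2 cohort builder: exposure x outcome counts
cohort_2x2 <- function(n11, n10, n01, n00) {
  data.frame(
    x = rep(c(1, 1, 0, 0), c(n11, n10, n01, n00)),
    y = rep(c(1, 0, 1, 0), c(n11, n10, n01, n00))
  )
}

test_that("logistic coefficient on a binary predictor is the log odds ratio", {
  d <- cohort_2x2(12, 8, 4, 16)  # exposed 12/20 events, unexposed 4/20
  res <- fit_binary_logistic(d, "y", "x")
  expect_equal(res$or, 6.0, tolerance = 1e-6)
  expect_equal(res$coef, log(6), tolerance = 1e-6)
  expect_equal(res$flag, "")
  # property over random non-separated tables
  set.seed(17)
  for (i in 1:10) {
    cnt <- rpois(4, 12) + 2
    d <- cohort_2x2(cnt[1], cnt[2], cnt[3], cnt[4])
    res <- fit_binary_logistic(d, "y", "x")
    expect_equal(res$coef, log(cnt[1] * cnt[4] / (cnt[2] * cnt[3])),
                 tolerance = 1e-6)
  }
})

test_that("an uninformative balanced predictor gives OR 1 and p near 1", {
  d <- cohort_2x2(10, 10, 10, 10)
  res <- fit_binary_logistic(d, "y", "x")
  expect_equal(res$or, 1.0, tolerance = 1e-8)
  expect_equal(res$p, 1.0, tolerance = 1e-6)
  expect_lte(res$ci_low, 1); expect_gte(res$ci_high, 1)
})

test_that("complete separation is flagged, not reported as a huge OR", {
  d <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                  y = c(rep(0, 20), rep(1, 20)))
  res <- suppressWarnings(fit_binary_logistic(d, "y", "x"))
  expect_equal(res$flag, "non_estimable")
})

test_that("constant predictors are dropped with a warning", {
  d <- cohort_2x2(12, 8, 4, 16)
  d$z <- 1
  expect_warning(res <- fit_binary_logistic(d, "y", c("x", "z")), "constant")
  expect_equal(res$term, "x")
  expect_error(suppressWarnings(fit_binary_logistic(d, "y", "z")),
               "no usable")
  d$y <- 0
  expect_error(fit_binary_logistic(d, "y", "x"), "both classes")
})

test_that("univariable mode fits each predictor in its own model", {
  set.seed(19)
  d <- data.frame(y = rbinom(80, 1, 0.4), a = rnorm(80), b = rnorm(80))
  uni <- fit_binary_logistic(d, "y", c("a", "b"), univariable = TRUE)
  expect_equal(nrow(uni), 2L)
  one <- fit_binary_logistic(d, "y", "b")
  expect_equal(uni$coef[uni$term == "b"], one$coef)
})

test_that("parameter recovery: OR per invasiveness voxel near ln(1.06)", {
  rec <- end_to_end_recovery(seed = 77, reps = 60)
  mc_half_width <- 3 * rec$se_or
  expect_lt(abs(rec$mean_or - 1.06), 0.01 + mc_half_width)
})

test_that("forward conditional selection finds signal and ignores noise", {
  set.seed(23)
  n <- 300
  d <- data.frame(signal = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  d$y <- rbinom(n, 1, plogis(-0.3 + 1.2 * d$signal))
  sel <- forward_conditional_select(d, "y", c("noise1", "signal", "noise2"))
  expect_true("signal" %in% sel$selected)
  expect_false(sel$intercept_only)
  # no associated predictor under a strict entry threshold -> intercept only
  d$y2 <- rbinom(n, 1, 0.5)
  sel0 <- forward_conditional_select(d, "y2", c("noise1", "noise2"),
                                     p_enter = 0.001, p_remove = 0.01)
  expect_true(sel0$intercept_only)
  expect_equal(sel0$selected, character(0))
  # duplicated predictor: exactly one of the pair enters (order tie-break)
  d$signal2 <- d$signal
  sel2 <- forward_conditional_select(d, "y", c("signal", "signal2"))
  expect_equal(sel2$selected, "signal")
})

test_that("variance inflation factors match the 1/(1-R^2) oracle", {
  set.seed(29)
  n <- 200
  a <- rnorm(n); b <- rnorm(n); cc <- rnorm(n)
  d <- data.frame(a = a, b = b, cc = cc)
  v <- check_collinearity(d, c("a", "b", "cc"))
  expect_true(all(v$vif < 1.15))
  expect_false(any(v$flagged))
  # correlated pair
  d$e <- 0.9 * scale(a)[, 1] + sqrt(1 - 0.81) * rnorm(n)
  v2 <- check_collinearity(d, c("a", "e"))
  r2 <- summary(lm(a ~ e, d))$r.squared
  expect_equal(v2$vif[v2$variable == "a"], 1 / (1 - r2), tolerance = 1e-8)
  # exact duplicate: infinite VIF, flagged, no crash
  d$dup <- d$a
  v3 <- check_collinearity(d, c("a", "dup", "b"))
  expect_true(all(v3$flagged[v3$variable %in% c("a", "dup")]))
  expect_true(all(is.infinite(v3$vif[v3$variable %in% c("a", "dup")])))
})

test_that("intercept-only multinomial returns the class shares", {
  d <- data.frame(group = rep(c("astro_IDHm", "astro_IDHwt", "oligo"),
                              c(65, 54, 116)))
  m <- fit_multinomial(d, "group")
  expect_equal(m$reference, "astro_IDHm")
  pr <- m$probabilities[1, ]
  expect_equal(unname(pr[m$classes]),
               c(65, 54, 116) / 235, tolerance = 1e-5)
  expect_true(all(abs(rowSums(m$probabilities) - 1) < 1e-9))
  d2 <- d[d$group != "oligo", , drop = FALSE]
  expect_error(fit_multinomial(d2, "group"), "3 classes")
})

test_that("saturated multinomial slopes equal closed-form log-odds shifts", {
  d <- data.frame(
    group = c(rep(c("c1", "c2", "c3"), c(10, 20, 30)),
              rep(c("c1", "c2", "c3"), c(20, 10, 10))),
    x = rep(c(1, 0), c(60, 40))
  )
  m <- fit_multinomial(d, "group", "x", reference = "c1")
  cf <- m$coefficients
  expect_equal(unname(cf["c2", "x"]), log(4), tolerance = 1e-3)
  expect_equal(unname(cf["c3", "x"]), log(6), tolerance = 1e-3)
})

test_that("ROC/AUC equals pairwise enumeration and rank statistic", {
  r <- roc_auc(c(0.9, 0.8, 0.4, 0.7, 0.3), c(1, 1, 1, 0, 0))
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(2, 8), rep(c(0, 1), 4))$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
  # rank (Mann-Whitney) agreement with ties, and monotone invariance
  set.seed(33)
  scores <- sample(seq(0, 1, 0.1), 60, replace = TRUE)
  truth <- rbinom(60, 1, 0.45)
  r2 <- roc_auc(scores, truth)
  pos <- scores[truth == 1]; neg <- scores[truth == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  expect_equal(r2$auc, mean(cmp), tolerance = 1e-12)
  expect_equal(roc_auc(qlogis(pmin(pmax(scores, 0.01), 0.99)), truth)$auc,
               r2$auc, tolerance = 1e-12)
  # ROC points are monotone in both axes
  expect_true(all(diff(r2$points$fpr) >= 0))
  expect_true(all(diff(r2$points$tpr) >= 0))
})

test_that("AUC matches an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(35)
  scores <- rnorm(100)
  truth <- rbinom(100, 1, 0.4)
  ours <- roc_auc(scores, truth)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(truth, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("predictive values follow the closed forms", {
  pv <- ppv_npv(0.43, 0.82, 0.277)
  expect_equal(round(100 * pv[["npv"]]), 79)
  expect_equal(unname(ppv_npv(1, 1, 0.3)), c(1, 1))
  pv2 <- ppv_npv(0.5, 0.5, 0.277)
  expect_equal(pv2[["ppv"]], 0.277, tolerance = 1e-12)
  expect_equal(pv2[["npv"]], 1 - 0.277, tolerance = 1e-12)
  expect_error(ppv_npv(0, 1, 0.5), "undefined")
  # property: agrees with direct confusion-matrix computation
  set.seed(37)
  for (i in 1:20) {
    tp <- rpois(1, 20) + 1; fn <- rpois(1, 10) + 1
    tn <- rpois(1, 25) + 1; fp <- rpois(1, 8) + 1
    se <- tp / (tp + fn); sp <- tn / (tn + fp)
    prev <- (tp + fn) / (tp + fn + tn + fp)
    pv <- ppv_npv(se, sp, prev)
    expect_equal(pv[["ppv"]], tp / (tp + fp), tolerance = 1e-12)
    expect_equal(pv[["npv"]], tn / (tn + fn), tolerance = 1e-12)
  }
})

test_that("per-class metrics match a confusion-matrix oracle", {
  set.seed(41)
  sim <- simulate_covariates(seed = 41)
  sim$age_over_40 <- as.integer(sim$age > 40)
  m <- fit_multinomial(sim, "group",
                       c("age_over_40", "seizure", "cognitive_deficit"))
  met <- classification_metrics(m)
  pred <- m$classes[max.col(m$probabilities, ties.method = "first")]
  for (cl in m$classes) {
    truth <- sim$group == cl
    tp <- sum(pred == cl & truth); fn <- sum(pred != cl & truth)
    tn <- sum(pred != cl & !truth); fp <- sum(pred == cl & !truth)
    row <- met[met$class == cl, ]
    expect_equal(row$sensitivity, tp / (tp + fn))
    expect_equal(row$specificity, tn / (tn + fp))
    expect_equal(row$prevalence, mean(truth))
  }
})

test_that("degenerate classifiers produce the expected metric patterns", {
  # perfectly separable classes
  d <- data.frame(group = rep(c("astro_IDHm", "astro_IDHwt", "oligo"),
                              each = 30),
                  x = rep(c(-8, 0, 8), each = 30))
  m <- suppressWarnings(fit_multinomial(d, "group", "x"))
  met <- classification_metrics(m)
  expect_true(all(met$sensitivity == 1))
  expect_true(all(met$specificity == 1))
  expect_true(all(met$auc == 1))
  # intercept-only: argmax is always the majority class
  d2 <- data.frame(group = rep(c("astro_IDHm", "astro_IDHwt", "oligo"),
                               c(65, 54, 116)))
  met2 <- classification_metrics(fit_multinomial(d2, "group"))
  expect_equal(met2$sensitivity[met2$class == "oligo"], 1)
  expect_equal(met2$sensitivity[met2$class != "oligo"], c(0, 0))
  expect_true(all(met2$flag[met2$class != "oligo"] == "never_predicted"))
})

test_that("the diagnosis wrapper returns collinearity, model and metrics", {
  sim <- simulate_covariates(seed = 43)
  dm <- diagnosis_model(sim)
  expect_s3_class(dm$model, "multinomial_model")
  expect_equal(nrow(dm$metrics), 3L)
  expect_true(all(dm$metrics$auc >= 0 & dm$metrics$auc <= 1))
  expect_false(any(dm$collinearity$flagged))
})
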