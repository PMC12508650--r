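#' @importFrom stats kruskal.test chisq.test fisher.test median glm binomial
#'   coef vcov pnorm pchisq as.formula add1 drop1 logLik plogis sd lm
#'   complete.cases uniroot rnorm rbinom runif rlnorm quantile predict setNames
NULL

test_result <- function(test, statistic, df, p_value) {
  structure(list(test = test, statistic = unname(statistic),
                 df = if (is.null(df)) NA_real_ else unname(df),
                 p_value = unname(p_value)),
            class = "bg_test")
}

#' @export
print.bg_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g%s, p = %.4g\n", x$test, x$statistic,
              if (is.na(x$df)) "" else sprintf(" (df %g)", x$df), x$p_value))
  invisible(x)
}

#' Kolmogorov-Smirnov normality test (Lilliefors correction)
#'
#' Normality gate applied to continuous variables before choosing the
#' non-parametric battery: the KS distance of the sample against a normal
#' with sample-estimated mean and SD, with the Lilliefors-corrected p-value
#' (the naive KS p would be anti-conservative when the parameters are
#' estimated from the same sample).
#'
#' @param values numeric sample, n >= 4, finite, non-constant.
#' @return a test result (statistic D, p-value).
#' @export
ks_normality <- function(values) {
  values <- as.numeric(values)
  if (any(!is.finite(values))) stop("values must be finite")
  if (length(values) < 4L) stop("need at least 4 observations")
  if (sd(values) == 0) stop("degenerate (constant) sample")
  lt <- nortest::lillie.test(values)
  test_result("Kolmogorov-Smirnov (Lilliefors)", lt$statistic, NULL, lt$p.value)
}

#' Kruskal-Wallis test across groups
#'
#' Rank-based k-sample location test with tie correction. The p-value comes
#' from the chi-square approximation with k - 1 degrees of freedom
#' (`p_method = "asymptotic"`, the battery default) or from a seeded
#' Monte-Carlo permutation of the group labels
#' (`p_method = "permutation"`), which is preferable for very small samples
#' where the chi-square approximation can be off by several hundredths.
#'
#' @param values numeric vector.
#' @param groups group labels, same length; at least 2 nonempty groups.
#' @param p_method `"asymptotic"` (default) or `"permutation"`.
#' @param reps permutation count for `p_method = "permutation"`.
#' @return a test result (H statistic, df, p-value).
#' @export
kruskal_wallis <- function(values, groups,
                           p_method = c("asymptotic", "permutation"),
                           reps = 10000) {
  p_method <- match.arg(p_method)
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(unique(values)) == 1L)  # all-tied sample: H is 0 by definition
    return(test_result("Kruskal-Wallis", 0, nlevels(groups) - 1, 1))
  kt <- kruskal.test(values, groups)
  p <- kt$p.value
  if (p_method == "permutation") {
    H_obs <- unname(kt$statistic)
    H_perm <- replicate(reps,
      kruskal.test(values, sample(groups))$statistic)
    p <- (1 + sum(H_perm >= H_obs - 1e-12)) / (reps + 1)
  }
  test_result("Kruskal-Wallis", kt$statistic, kt$parameter, p)
}

#' Chi-square or Fisher test on a contingency table
#'
#' Pearson chi-square (no continuity correction) or Fisher's exact test on
#' an r x c count table. `method = "auto"` switches to Fisher whenever any
#' expected count falls below 5, the usual small-sample rule. Zero-margin
#' rows/columns are dropped with a warning before testing.
#'
#' @param table r x c matrix of nonnegative integer counts (>= 2 x 2 after
#'   dropping empty margins).
#' @param method `"auto"`, `"chi2"` or `"fisher"`.
#' @return a test result; for Fisher the statistic is NA and df is NA.
#' @export
contingency_test <- function(table, method = c("auto", "chi2", "fisher")) {
  method <- match.arg(method)
  table <- as.matrix(table)
  if (any(table < 0) || any(table != round(table)))
    stop("table must contain nonnegative integer counts")
  if (sum(table) == 0) stop("empty table")
  keep_r <- rowSums(table) > 0
  keep_c <- colSums(table) > 0
  if (!all(keep_r) || !all(keep_c)) {
    warning("dropping zero-margin rows/columns before testing")
    table <- table[keep_r, keep_c, drop = FALSE]
  }
  if (nrow(table) < 2L || ncol(table) < 2L)
    stop("need at least a 2 x 2 table after dropping empty margins")
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (method == "auto")
    method <- if (any(expected < 5)) "fisher" else "chi2"
  if (method == "chi2") {
    ct <- suppressWarnings(chisq.test(table, correct = FALSE))
    test_result("Pearson chi-square", ct$statistic, ct$parameter, ct$p.value)
  } else {
    # exact network algorithm where feasible; Monte-Carlo fallback for
    # tables too large for the exact workspace
    ft <- tryCatch(fisher.test(table),
                   error = function(e)
                     fisher.test(table, simulate.p.value = TRUE, B = 1e5))
    test_result("Fisher exact", NA_real_, NULL, ft$p.value)
  }
}

#' Mood's median test across groups
#'
#' Dichotomises the pooled sample at its median (values equal to the median
#' counted on the "<= median" side) and applies a Pearson chi-square to the
#' resulting k x 2 table. Used for tumour volume and Brain-Grid voxel count,
#' whose distributions are heavy-tailed.
#'
#' @param values numeric vector; pooled sample must not be constant.
#' @param groups group labels, >= 2 groups.
#' @return a test result.
#' @export
mood_median_test <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  values <- as.numeric(values)
  if (sd(values) == 0) stop("degenerate (constant) pooled sample")
  med <- median(values)
  below <- values <= med
  tab <- table(groups, factor(below, levels = c(TRUE, FALSE),
                              labels = c("le_median", "gt_median")))
  res <- contingency_test(unclass(tab), method = "chi2")
  res$test <- "Mood median"
  res
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values with enforced monotonicity, capped at 1; the
#' input order is preserved. The adjustment is applied across all
#' between-group tests of a run (m = number of tests), always from raw
#' p-values.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
bh_fdr <- function(p) {
  p <- as.numeric(p)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# Battery variable plans: which column gets which test.
battery_plan <- function() {
  list(
    continuous_kw = c("age", "volume_ml"),
    continuous_median = c("bg_voxel_count"),
    categorical = c("sex", "border", "contrast", "laterality", "location",
                    "seizure", "cognitive_deficit", "motor_deficit",
                    "language_deficit", "visual_deficit", "headache",
                    "asymptomatic")
  )
}

#' Between-group statistical battery
#'
#' Runs the full between-group comparison over a cohort table: a
#' Kolmogorov-Smirnov (Lilliefors) normality gate on each continuous
#' variable, Kruskal-Wallis for continuous variables, Mood's median test
#' for the invasiveness count, Pearson chi-square / Fisher exact (auto
#' switch at expected count < 5) for categorical variables, and a single
#' Benjamini-Hochberg FDR adjustment across the whole battery. Two-sided
#' p-values throughout.
#'
#' @param cohort validated cohort data frame (see [read_cohort()]).
#' @param variables optional subset of variables to test; defaults to the
#'   standard demographic/radiological/clinical battery present in the
#'   table.
#' @return data frame: variable, test, statistic, df, p, ks_p (normality
#'   gate p for continuous variables), fdr; plus attribute `m` (family
#'   size).
#' @export
group_comparison_table <- function(cohort, variables = NULL) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  g <- droplevels(factor(cohort$group))
  plan <- battery_plan()
  all_vars <- c(plan$continuous_kw, plan$continuous_median, plan$categorical)
  vars <- intersect(if (is.null(variables)) all_vars else variables,
                    names(cohort))
  rows <- lapply(vars, function(v) {
    x <- cohort[[v]]
    ks_p <- NA_real_
    if (v %in% c(plan$continuous_kw, plan$continuous_median)) {
      ks_p <- tryCatch(ks_normality(x)$p_value, error = function(e) NA_real_)
      res <- if (v %in% plan$continuous_kw) kruskal_wallis(x, g)
             else mood_median_test(x, g)
    } else {
      res <- contingency_test(unclass(table(g, factor(x))), method = "auto")
    }
    data.frame(variable = v, test = res$test, statistic = res$statistic,
               df = res$df, p = res$p_value, ks_p = ks_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  attr(out, "m") <- nrow(out)
  out
}
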