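#' Binary logistic regression with Wald intervals and separation flagging
#'
#' Maximum-likelihood logistic fit of a binary outcome on one or more
#' predictors. In univariable mode each predictor is fitted in its own
#' model, mirroring the univariable columns of a clinical regression table;
#' otherwise one multivariable model is fitted. Odds ratios carry Wald 95%
#' intervals (exp(coef +/- 1.96 SE)). Fits showing signs of (quasi-)complete
#' separation - non-convergence or a coefficient beyond 15 on the
#' standardised scale - are flagged `non_estimable` rather than silently
#' reported as huge odds ratios. Constant predictors are dropped with a
#' warning.
#'
#' @param data data frame.
#' @param outcome name of the 0/1 (or logical) outcome column; both classes
#'   must be present.
#' @param predictors character vector of predictor column names.
#' @param univariable fit one model per predictor (default TRUE).
#' @return data frame: variable, term, coef, or, ci_low, ci_high, p, flag.
#'   Attribute `models` holds the underlying glm fits.
#' @export
fit_binary_logistic <- function(data, outcome, predictors,
                                univariable = TRUE) {
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (length(unique(y[!is.na(y)])) != 2L)
    stop("outcome must have both classes present")
  keep <- vapply(predictors, function(v) {
    x <- data[[v]]
    length(unique(x[!is.na(x)])) > 1L
  }, logical(1))
  if (any(!keep))
    warning("dropping constant predictor(s): ",
            paste(predictors[!keep], collapse = ", "))
  predictors <- predictors[keep]
  if (length(predictors) == 0L) stop("no usable predictors")

  fit_one <- function(vars) {
    f <- as.formula(paste("..y ~", paste(vars, collapse = " + ")))
    d <- data
    d$..y <- y
    fit <- suppressWarnings(glm(f, data = d, family = binomial()))
    rows <- summarise_logistic(fit, vars)
    list(fit = fit, rows = rows)
  }
  fits <- if (univariable) lapply(predictors, fit_one)
          else list(fit_one(predictors))
  out <- do.call(rbind, lapply(fits, `[[`, "rows"))
  rownames(out) <- NULL
  attr(out, "models") <- lapply(fits, `[[`, "fit")
  out
}

# Wald summary rows for the non-intercept terms of a logistic fit, with
# separation detection on the standardised scale.
summarise_logistic <- function(fit, vars) {
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  terms <- setdiff(names(cf), "(Intercept)")
  mm <- stats::model.matrix(fit)
  sds <- apply(mm, 2, sd)
  flag <- vapply(terms, function(t) {
    std <- abs(cf[t]) * if (sds[t] > 0) sds[t] else 1
    if (!fit$converged || !is.finite(cf[t]) || std > 15) "non_estimable" else ""
  }, character(1))
  z <- cf[terms] / se[terms]
  data.frame(
    variable = rep(paste(vars, collapse = " + "), length(terms)),
    term = terms,
    coef = unname(cf[terms]),
    or = unname(exp(cf[terms])),
    ci_low = unname(exp(cf[terms] - 1.96 * se[terms])),
    ci_high = unname(exp(cf[terms] + 1.96 * se[terms])),
    p = unname(2 * pnorm(-abs(z))),
    flag = unname(flag),
    stringsAsFactors = FALSE
  )
}

#' Forward-conditional stepwise logistic model
#'
#' Forward selection for a binary logistic model in the "forward
#' conditional" style of clinical statistics packages: at each step the
#' candidate with the smallest score (Rao) test p-value enters if it is
#' below `p_enter`; after each entry, variables whose conditional
#' likelihood-ratio p-value exceeds `p_remove` are removed. Ties break
#' deterministically by candidate order. If nothing passes entry the
#' intercept-only model is returned, flagged.
#'
#' @param data data frame.
#' @param outcome binary outcome column name.
#' @param candidates character vector of candidate predictors, in priority
#'   order for tie-breaks.
#' @param p_enter score-test entry threshold (default 0.05).
#' @param p_remove likelihood-ratio removal threshold (default 0.10);
#'   must exceed `p_enter`.
#' @return list: `selected` (character), `summary` (coefficient table as in
#'   [fit_binary_logistic()], NULL if intercept-only), `fit` (the final
#'   glm), `intercept_only` (logical), `steps` (log of entries/removals).
#' @export
forward_conditional_select <- function(data, outcome, candidates,
                                       p_enter = 0.05, p_remove = 0.10) {
  stopifnot(length(candidates) >= 1L, p_enter < p_remove)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.integer(y)
  d <- data
  d$..y <- y
  selected <- character(0)
  steps <- character(0)
  repeat {
    pool <- setdiff(candidates, selected)
    if (length(pool) == 0L) break
    base_f <- if (length(selected) == 0L) "..y ~ 1"
              else paste("..y ~", paste(selected, collapse = " + "))
    fit0 <- suppressWarnings(glm(as.formula(base_f), data = d,
                                 family = binomial()))
    scope <- as.formula(paste("~ . +", paste(pool, collapse = " + ")))
    a1 <- suppressWarnings(add1(fit0, scope = scope, test = "Rao"))
    pv <- a1[pool, "Pr(>Chi)"]
    if (!any(is.finite(pv))) break  # e.g. only exact duplicates remain
    best <- which.min(ifelse(is.finite(pv), pv, Inf))  # ties: candidate order
    if (pv[best] >= p_enter) break
    selected <- c(selected, pool[best])
    steps <- c(steps, paste0("+", pool[best]))
    # conditional removal by LR test
    repeat {
      if (length(selected) == 0L) break
      f <- as.formula(paste("..y ~", paste(selected, collapse = " + ")))
      fit <- suppressWarnings(glm(f, data = d, family = binomial()))
      d1 <- suppressWarnings(drop1(fit, test = "LRT"))
      pr <- d1[selected, "Pr(>Chi)"]
      worst <- which(pr == max(pr, na.rm = TRUE))[1]
      if (is.finite(pr[worst]) && pr[worst] > p_remove) {
        steps <- c(steps, paste0("-", selected[worst]))
        selected <- selected[-worst]
      } else break
    }
  }
  if (length(selected) == 0L) {
    fit <- suppressWarnings(glm(..y ~ 1, data = d, family = binomial()))
    return(list(selected = character(0), summary = NULL, fit = fit,
                intercept_only = TRUE, steps = steps))
  }
  smry <- fit_binary_logistic(d, "..y", selected, univariable = FALSE)
  list(selected = selected, summary = smry,
       fit = attr(smry, "models")[[1]], intercept_only = FALSE,
       steps = steps)
}

#' Variance inflation factors
#'
#' Collinearity check run before the multinomial diagnosis model: the VIF of
#' each predictor is 1 / (1 - R^2) from regressing it on the remaining
#' predictors. Exactly collinear columns yield infinite VIF and are flagged
#' rather than crashing.
#'
#' @param data data frame of numeric predictors (factors must be coded
#'   numerically first).
#' @param predictors column names; at least 2, with n > p.
#' @param threshold flag level (default 10).
#' @return data frame: variable, vif, flagged.
#' @export
check_collinearity <- function(data, predictors, threshold = 10) {
  stopifnot(length(predictors) >= 2L)
  X <- data[predictors]
  X <- as.data.frame(lapply(X, as.numeric))
  if (nrow(X) <= length(predictors)) stop("need n > number of predictors")
  vifs <- vapply(predictors, function(v) {
    others <- setdiff(predictors, v)
    fit <- lm(as.formula(paste(v, "~", paste(others, collapse = " + "))),
              data = X)
    r2 <- summary(fit)$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = predictors, vif = unname(vifs),
             flagged = unname(vifs > threshold), stringsAsFactors = FALSE)
}

#' Multinomial (baseline-category) logistic diagnosis model
#'
#' Fits a baseline-category logit model for the three molecular subgroups;
#' the reference class defaults to the IDH-mutated astrocytoma group so the
#' other classes' coefficients read as log-odds versus IDH-m. Per-patient
#' predicted probabilities sum to 1 by construction.
#'
#' @param data data frame; the outcome column must have all three classes.
#' @param outcome class label column name.
#' @param predictors character vector of predictor columns; empty for an
#'   intercept-only model.
#' @param reference reference class (default `"astro_IDHm"` when present,
#'   else the first level).
#' @return list of class `multinomial_model`: `fit` (nnet::multinom),
#'   `probabilities` (n x 3 matrix), `classes`, `reference`,
#'   `coefficients`.
#' @export
fit_multinomial <- function(data, outcome, predictors = character(0),
                            reference = NULL) {
  y <- factor(data[[outcome]])
  y <- droplevels(y)
  if (nlevels(y) < 3L) stop("all 3 classes must be present")
  if (is.null(reference))
    reference <- if ("astro_IDHm" %in% levels(y)) "astro_IDHm" else levels(y)[1]
  y <- stats::relevel(y, ref = reference)
  d <- data
  d$..y <- y
  f <- if (length(predictors) == 0L) ..y ~ 1
       else as.formula(paste("..y ~", paste(predictors, collapse = " + ")))
  fit <- nnet::multinom(f, data = d, trace = FALSE, maxit = 500)
  pr <- predict(fit, newdata = d, type = "probs")
  if (is.null(dim(pr))) pr <- matrix(pr, nrow = nrow(d))  # guard, 2-class
  structure(list(fit = fit, probabilities = pr, classes = levels(y),
                 reference = reference, coefficients = coef(fit),
                 truth = y),
            class = "multinomial_model")
}

#' @export
print.multinomial_model <- function(x, ...) {
  cat(sprintf("multinomial model: classes %s (reference %s)\n",
              paste(x$classes, collapse = "/"), x$reference))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Empirical ROC over all score thresholds with trapezoidal AUC. The AUC
#' equals the tie-corrected rank (Mann-Whitney) statistic
#' P(score_pos > score_neg) + 0.5 P(equal), and is invariant under strictly
#' monotone transformations of the scores.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param truth binary ground truth (0/1 or logical); both classes present.
#' @return list of class `roc_result`: `points` (data frame fpr, tpr,
#'   threshold) and `auc`.
#' @export
roc_auc <- function(scores, truth) {
  truth <- as.integer(as.logical(truth))
  if (length(unique(truth)) != 2L) stop("truth must contain both classes")
  stopifnot(length(scores) == length(truth))
  np <- sum(truth == 1)
  nn <- sum(truth == 0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1) / np, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0) / nn, 0)
  pts <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr),
                    threshold = c(Inf, thr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: %d points, AUC %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Positive and negative predictive value at a given prevalence
#'
#' Closed forms linking a test's sensitivity and specificity to its
#' predictive values at disease prevalence pi:
#' PPV = Se pi / (Se pi + (1 - Sp)(1 - pi)),
#' NPV = Sp (1 - pi) / (Sp (1 - pi) + (1 - Se) pi).
#'
#' @param sensitivity,specificity in \[0, 1\].
#' @param prevalence in (0, 1).
#' @return named numeric vector `c(ppv = , npv = )`.
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            prevalence > 0, prevalence < 1)
  dp <- sensitivity * prevalence + (1 - specificity) * (1 - prevalence)
  dn <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (dp == 0 || dn == 0) stop("undefined predictive value (zero denominator)")
  c(ppv = sensitivity * prevalence / dp,
    npv = specificity * (1 - prevalence) / dn)
}

#' Per-class prediction metrics of a multinomial model
#'
#' One-vs-rest sensitivity and specificity from the model's argmax class
#' assignment, AUC from the class's predicted probability, and PPV/NPV from
#' the closed forms at the observed class prevalence. A class the model
#' never predicts gets sensitivity 0 and is flagged.
#'
#' @param model a [fit_multinomial()] result.
#' @param truth optional class labels (defaults to the labels the model was
#'   fitted on).
#' @param assignment `"argmax"` (default) or `"youden"` (per-class
#'   probability threshold maximising Youden's J).
#' @return data frame: class, n, prevalence, sensitivity, specificity, auc,
#'   ppv, npv, flag.
#' @export
classification_metrics <- function(model, truth = NULL,
                                   assignment = c("argmax", "youden")) {
  stopifnot(inherits(model, "multinomial_model"))
  assignment <- match.arg(assignment)
  truth <- factor(if (is.null(truth)) model$truth else truth,
                  levels = model$classes)
  pr <- model$probabilities
  pred_argmax <- model$classes[max.col(pr, ties.method = "first")]
  rows <- lapply(model$classes, function(cl) {
    is_cl <- truth == cl
    prev <- mean(is_cl)
    p_cl <- pr[, cl]
    roc <- roc_auc(p_cl, is_cl)
    pred_pos <- if (assignment == "argmax") {
      pred_argmax == cl
    } else {
      j <- roc$points$tpr - roc$points$fpr
      p_cl >= roc$points$threshold[which.max(j)]
    }
    tp <- sum(pred_pos & is_cl); fn <- sum(!pred_pos & is_cl)
    tn <- sum(!pred_pos & !is_cl); fp <- sum(pred_pos & !is_cl)
    se <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    sp <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
    flag <- if (!any(pred_pos)) "never_predicted" else ""
    pv <- if (!is.na(se) && !is.na(sp) && prev > 0 && prev < 1 &&
              (se > 0 || sp < 1) && (sp > 0 || se < 1)) {
      tryCatch(ppv_npv(se, sp, prev),
               error = function(e) c(ppv = NA_real_, npv = NA_real_))
    } else c(ppv = NA_real_, npv = NA_real_)
    data.frame(class = cl, n = sum(is_cl), prevalence = prev,
               sensitivity = se, specificity = sp, auc = roc$auc,
               ppv = unname(pv["ppv"]), npv = unname(pv["npv"]),
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the diagnosis prediction model and report per-class metrics
#'
#' Convenience wrapper reproducing the diagnosis-prediction step: a
#' collinearity check over the candidate predictors (VIF > 10 flags), a
#' multinomial model with the IDH-m astrocytoma group as reference, and the
#' per-class sensitivity/specificity/AUC/PPV/NPV bundle.
#'
#' @param cohort cohort data frame.
#' @param predictors candidate predictor columns; defaults to the
#'   age-over-40 indicator, seizure, cognitive deficit and invasiveness
#'   count if present.
#' @param reference reference class.
#' @return list: `collinearity`, `model`, `metrics`.
#' @export
diagnosis_model <- function(cohort, predictors = NULL, reference = "astro_IDHm") {
  if (is.null(predictors)) {
    if (!"age_over_40" %in% names(cohort) && "age" %in% names(cohort))
      cohort$age_over_40 <- as.integer(cohort$age > 40)
    predictors <- intersect(
      c("age_over_40", "seizure", "cognitive_deficit", "bg_voxel_count"),
      names(cohort))
  }
  coll <- if (length(predictors) >= 2L)
    check_collinearity(cohort, predictors) else NULL
  model <- fit_multinomial(cohort, "group", predictors,
                           reference = reference)
  list(collinearity = coll, model = model,
       metrics = classification_metrics(model))
}
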