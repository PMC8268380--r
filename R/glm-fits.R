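# Regression layers: multivariable logistic models (complication ~ obesity +
# covariates; death ~ five complications) and OLS (LOS, charges ~ five
# complications), reporting publication-style statistics.

# Default adjustment covariates of the complication models (reference levels:
# White race, Q1 income, non-elective, rural, non-teaching).
DEFAULT_ADJUSTMENT <- c("race", "income_quartile", "elective", "urban",
                        "teaching")

# Put factor reference levels in place so coefficients are interpretable
# against the conventional baselines.
apply_reference_levels <- function(data) {
  refs <- list(race = "White", income_quartile = "Q1", bed_size = "small",
               age_group = "20-44", sex = "male")
  for (nm in intersect(names(refs), names(data))) {
    if (!is.factor(data[[nm]])) data[[nm]] <- factor(data[[nm]])
    if (refs[[nm]] %in% levels(data[[nm]])) {
      data[[nm]] <- stats::relevel(data[[nm]], ref = refs[[nm]])
    }
  }
  data
}

#' Fit a multivariable logistic regression with publication statistics
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares via [stats::glm()]) of a binary outcome on a term list, reporting
#' everything a discharge-data complication/mortality table prints: log-odds
#' coefficients, odds ratios with Wald 95% confidence intervals (computed on
#' the log-odds scale and exponentiated, so `OR = exp(beta)` holds exactly),
#' per-term p-values, the event count `N`, the dependent-variable mean
#' (events / rows used — the `P` at which marginal effects are evaluated),
#' `-2 log L`, the likelihood-ratio statistic against the intercept-only
#' model with its p-value, and the Pearson chi-square statistic of the fit.
#'
#' Rows with a missing outcome are dropped (complete-case per model) and
#' counted. Perfect separation and non-convergence are detected and reported.
#'
#' @param data `data.frame` of analytic rows.
#' @param outcome name of the binary (logical/0-1) outcome column.
#' @param predictors character vector of predictor column names.
#' @param tol IRLS convergence tolerance (relative deviance change).
#' @param maxit maximum IRLS iterations.
#' @param conf_level confidence level of the Wald intervals.
#' @return An object of class `margpath_logit`; see Details. The `terms`
#'   element is a `data.frame` with columns `term`, `beta`, `se`, `or`,
#'   `or_lo`, `or_hi`, `z`, `p_value`.
#' @seealso [fit_ols()], [select_significant_terms()], [marginal_effects()]
#' @export
fit_logistic <- function(data, outcome, predictors, tol = 1e-8, maxit = 100,
                         conf_level = 0.95) {
  data <- apply_reference_levels(data)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  use <- !is.na(y)
  df <- data[use, c(outcome, predictors), drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  y <- as.numeric(df[[outcome]])
  if (length(unique(y)) < 2L) stop("outcome '", outcome, "' is degenerate")

  fml <- stats::reformulate(if (length(predictors)) predictors else "1",
                            response = outcome)
  fit <- withCallingHandlers(
    stats::glm(fml, data = df, family = stats::binomial(),
               control = stats::glm.control(epsilon = tol, maxit = maxit)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  if (!fit$converged) {
    stop("logistic fit did not converge in ", maxit, " iterations (outcome '",
         outcome, "'); deviance trace: ",
         paste(signif(fit$deviance, 8), collapse = " -> "))
  }
  cf <- summary(fit)$coefficients
  separated <- any(abs(cf[, "Estimate"]) > 12) ||
    any(fit$fitted.values < 1e-10) || any(fit$fitted.values > 1 - 1e-10)
  if (separated) {
    warning("possible perfect separation in outcome '", outcome,
            "': extreme coefficients or fitted probabilities")
  }
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  terms <- data.frame(
    term = rownames(cf),
    beta = cf[, "Estimate"], se = cf[, "Std. Error"],
    or = exp(cf[, "Estimate"]),
    or_lo = exp(cf[, "Estimate"] - zq * cf[, "Std. Error"]),
    or_hi = exp(cf[, "Estimate"] + zq * cf[, "Std. Error"]),
    z = cf[, "z value"], p_value = cf[, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)

  lr <- unname(fit$null.deviance - fit$deviance)
  lr_df <- unname(fit$df.null - fit$df.residual)
  structure(list(
    outcome = outcome, predictors = predictors, terms = terms,
    n_used = nrow(df), n_events = as.integer(sum(y)),
    dependent_mean = mean(y),
    minus2_log_likelihood = unname(fit$deviance),
    likelihood_ratio = lr, lr_df = lr_df,
    lr_p = stats::pchisq(lr, lr_df, lower.tail = FALSE),
    pearson_chisq = sum(stats::residuals(fit, type = "pearson")^2),
    separated = separated, converged = fit$converged,
    n_dropped_missing = sum(!use) + sum(!cc)),
    class = "margpath_logit")
}

#' @export
print.margpath_logit <- function(x, digits = 3, ...) {
  cat("<margpath_logit> ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  tt <- x$terms
  tt$or_ci <- sprintf("(%.2f, %.2f)", tt$or_lo, tt$or_hi)
  print(format(tt[c("term", "beta", "or", "or_ci", "p_value")],
               digits = digits), row.names = FALSE)
  cat(sprintf("N events %d | dependent mean %.4g | -2logL %.6g | LR %.6g (df %d, p %.3g)\n",
              x$n_events, x$dependent_mean, x$minus2_log_likelihood,
              x$likelihood_ratio, x$lr_df, x$lr_p))
  invisible(x)
}

#' Fit ordinary least squares with Wald confidence intervals
#'
#' OLS of a continuous outcome (length of stay in days, or total charges in
#' US dollars) on a predictor list — typically the five complication flags —
#' reporting coefficients with 95% confidence intervals, R-squared, adjusted
#' R-squared, and the complete-case sample size. Rows missing the outcome are
#' excluded and counted. A rank-deficient design is an error.
#'
#' @inheritParams fit_logistic
#' @return An object of class `margpath_ols` with elements `terms`
#'   (`data.frame`: `term`, `beta`, `se`, `ci_lo`, `ci_hi`, `p_value`),
#'   `r_squared`, `adj_r_squared`, `n_used`, `n_dropped_missing`.
#' @export
fit_ols <- function(data, outcome, predictors, conf_level = 0.95) {
  data <- apply_reference_levels(data)
  y <- data[[outcome]]
  if (is.null(y)) stop("outcome column not found: ", outcome)
  use <- !is.na(y)
  df <- data[use, c(outcome, predictors), drop = FALSE]
  cc <- stats::complete.cases(df)
  df <- df[cc, , drop = FALSE]
  if (nrow(df) < length(predictors) + 2L) {
    stop("need at least p + 2 complete rows")
  }
  fml <- if (length(predictors)) {
    stats::reformulate(predictors, response = outcome)
  } else {
    stats::reformulate("1", response = outcome)   # intercept-only
  }
  fit <- stats::lm(fml, data = df)
  if (fit$rank < length(stats::coef(fit))) {
    stop("rank-deficient design for outcome '", outcome, "': aliased terms ",
         paste(names(which(is.na(stats::coef(fit)))), collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = conf_level)
  terms <- data.frame(
    term = rownames(cf), beta = cf[, "Estimate"], se = cf[, "Std. Error"],
    ci_lo = ci[, 1], ci_hi = ci[, 2], p_value = cf[, "Pr(>|t|)"],
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    outcome = outcome, predictors = predictors, terms = terms,
    r_squared = summary(fit)$r.squared,
    adj_r_squared = summary(fit)$adj.r.squared,
    n_used = nrow(df), n_dropped_missing = sum(!use) + sum(!cc),
    residual_dot_design = drop(crossprod(stats::model.matrix(fit),
                                         stats::residuals(fit)))),
    class = "margpath_ols")
}

#' @export
print.margpath_ols <- function(x, digits = 4, ...) {
  cat("<margpath_ols> ", x$outcome, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  tt <- x$terms
  tt$ci <- sprintf("(%.4g, %.4g)", tt$ci_lo, tt$ci_hi)
  print(format(tt[c("term", "beta", "ci", "p_value")], digits = digits),
        row.names = FALSE)
  cat(sprintf("N %d | R^2 %.4f | adjusted R^2 %.4f\n",
              x$n_used, x$r_squared, x$adj_r_squared))
  invisible(x)
}

#' Select model terms significant at a threshold
#'
#' Returns the terms of a fitted model with a two-sided p-value below `alpha`
#' (default 0.05); used to choose which complications enter the path analysis
#' as mediators.
#'
#' @param fit a `margpath_logit` or `margpath_ols`.
#' @param alpha two-sided significance threshold.
#' @param include_intercept keep the intercept if significant?
#' @return Character vector of term names.
#' @export
select_significant_terms <- function(fit, alpha = 0.05,
                                     include_intercept = FALSE) {
  tt <- fit$terms
  if (!include_intercept) tt <- tt[tt$term != "(Intercept)", , drop = FALSE]
  tt$term[tt$p_value < alpha]
}

#' Select mediator complications by the exposure term's significance
#'
#' Given one logistic fit per candidate complication (each of the form
#' complication ~ obesity + covariates), returns the names of the
#' complications whose exposure coefficient is significant at `alpha`.
#'
#' @param fits named list of `margpath_logit` objects, one per complication.
#' @param term name of the exposure term in each fit (default `obeseTRUE`,
#'   the coefficient name of a logical `obese` column).
#' @param alpha two-sided significance threshold.
#' @return Character vector of complication names.
#' @export
select_mediators <- function(fits, term = "obeseTRUE", alpha = 0.05) {
  keep <- vapply(fits, function(f) {
    p <- f$terms$p_value[f$terms$term == term]
    length(p) == 1L && p < alpha
  }, logical(1))
  names(fits)[keep]
}

#' Serialize a fitted model to JSON
#'
#' Writes every reported statistic of a [fit_logistic()] or [fit_ols()]
#' object (term table, sample sizes, fit statistics) as JSON.
#'
#' @param fit a `margpath_logit` or `margpath_ols`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  keep <- fit[!vapply(fit, is.function, logical(1))]
  jsonlite::write_json(keep, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
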