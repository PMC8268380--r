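# Regression layers: logistic and OLS fits and the significance-based
# mediator selection.

random_logit_data <- function(n, beta, seed) {
  set.seed(seed)
  x1 <- stats::rnorm(n)
  x2 <- stats::rbinom(n, 1, 0.4)
  lp <- beta[1] + beta[2] * x1 + beta[3] * x2
  data.frame(y = stats::runif(n) < stats::plogis(lp), x1 = x1, x2 = x2)
}

test_that("the intercept-only logistic model recovers the closed-form logit", {
  set.seed(5)
  d <- data.frame(y = stats::runif(300) < 0.23)
  fit <- fit_logistic(d, "y", character(0))
  expect_equal(fit$terms$beta[1], stats::qlogis(mean(d$y)), tolerance = 1e-8)
  expect_equal(fit$likelihood_ratio, 0, tolerance = 1e-10)
  expect_equal(fit$dependent_mean, mean(d$y))
  expect_identical(fit$n_events, sum(d$y))
})

test_that("logistic estimates match the numeric-likelihood oracle on small data", {
  for (seed in c(101, 202, 303)) {
    d <- random_logit_data(40, c(-0.5, 0.8, -0.6), seed)
    if (length(unique(d$y)) < 2) next
    fit <- fit_logistic(d, "y", c("x1", "x2"))
    oracle <- brute_logit(d$y, d[c("x1", "x2")])
    expect_equal(unname(fit$terms$beta), unname(oracle), tolerance = 1e-4)
  }
})

test_that("logistic fit statistics satisfy the likelihood identities", {
  d <- random_logit_data(2000, c(-1.5, 0.6, 0.4), 7)
  fit <- fit_logistic(d, "y", c("x1", "x2"))
  expect_true(fit$converged)
  expect_gte(fit$likelihood_ratio, 0)
  # -2logL of the full model cannot exceed that of the null model
  null_m2ll <- fit_logistic(d, "y", character(0))$minus2_log_likelihood
  expect_lte(fit$minus2_log_likelihood, null_m2ll)
  expect_equal(fit$likelihood_ratio, null_m2ll - fit$minus2_log_likelihood,
               tolerance = 1e-8)
  # OR columns are exact transforms of the log-odds scale
  expect_equal(fit$terms$or, exp(fit$terms$beta))
  expect_equal(fit$terms$or_lo,
               exp(fit$terms$beta - stats::qnorm(0.975) * fit$terms$se))
  expect_identical(round(fit$dependent_mean * fit$n_used), as.double(fit$n_events))
})

test_that("degenerate outcomes and perfect separation are reported", {
  d <- data.frame(y = rep(FALSE, 50), x1 = stats::rnorm(50))
  expect_error(fit_logistic(d, "y", "x1"), "degenerate")
  sep <- data.frame(y = rep(c(FALSE, TRUE), each = 25),
                    x1 = c(stats::rnorm(25, -3), stats::rnorm(25, 3)))
  expect_warning(fit_logistic(sep, "y", "x1"), "separation")
})

test_that("missing outcomes are dropped complete-case per model", {
  d <- random_logit_data(500, c(-1, 0.5, 0.2), 11)
  d$y[1:40] <- NA
  fit <- fit_logistic(d, "y", c("x1", "x2"))
  expect_identical(fit$n_used, 460L)
  expect_identical(fit$n_dropped_missing, 40L)
})

test_that("OLS is exact on noiseless data and reduces to the mean without predictors", {
  set.seed(9)
  d <- data.frame(a = stats::rbinom(200, 1, 0.3) == 1,
                  b = stats::rbinom(200, 1, 0.1) == 1)
  d$y <- 5 + 3 * d$a - 2 * d$b
  # base R flags the zero-residual fit as "essentially perfect"; that is the
  # point of this case
  fit <- suppressWarnings(fit_ols(d, "y", c("a", "b")))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(unname(fit$terms$beta), c(5, 3, -2), tolerance = 1e-10)
  expect_lte(fit$adj_r_squared, fit$r_squared)

  fit0 <- fit_ols(d, "y", character(0))
  expect_equal(fit0$terms$beta[1], mean(d$y), tolerance = 1e-12)

  # residuals orthogonal to the design at machine precision
  d$y <- d$y + stats::rnorm(200)
  fitn <- fit_ols(d, "y", c("a", "b"))
  expect_lt(max(abs(fitn$residual_dot_design)), 1e-8)
})

test_that("rank-deficient OLS designs are reported, not silently aliased", {
  d <- data.frame(y = stats::rnorm(50), a = rep(c(0, 1), 25))
  d$b <- d$a
  expect_error(fit_ols(d, "y", c("a", "b")), "rank-deficient")
})

test_that("term selection at alpha follows the Wald confidence-interval duality", {
  d <- random_logit_data(3000, c(-1.2, 0.5, 0), 13)
  fit <- fit_logistic(d, "y", c("x1", "x2"))
  sel <- select_significant_terms(fit, alpha = 0.05)
  tt <- fit$terms[fit$terms$term != "(Intercept)", ]
  by_ci <- tt$term[tt$or_lo > 1 | tt$or_hi < 1]
  expect_setequal(sel, by_ci)
})

test_that("mediator selection keys on the exposure term across complication fits", {
  cohort <- small_cohort(n = 60000, seed = 314)
  m <- match_1to4(cohort, seed = 314)
  mrows <- matched_rows(m, cohort)
  fits <- lapply(c("infection", "wound_disruption", "respiratory"),
                 function(nm) {
                   fit_logistic(mrows, paste0("c_", nm),
                                c("obese", "race", "income_quartile",
                                  "elective", "urban", "teaching"))
                 })
  names(fits) <- c("infection", "wound_disruption", "respiratory")
  sel <- select_mediators(fits)
  # strong generated effects are picked up; the complication generated with a
  # zero obesity coefficient is not
  expect_true(all(c("infection", "wound_disruption") %in% sel))
  expect_false("respiratory" %in% sel)
})

test_that("null synthetic exposure produces false selections near alpha", {
  set.seed(2024)
  nrep <- 200
  picked <- logical(nrep)
  for (i in seq_len(nrep)) {
    d <- data.frame(y = stats::runif(400) < 0.2,
                    x1 = stats::rnorm(400))
    if (length(unique(d$y)) < 2) next
    fit <- fit_logistic(d, "y", "x1")
    picked[i] <- "x1" %in% select_significant_terms(fit)
  }
  expect_lt(abs(mean(picked) - 0.05), 3 * sqrt(0.05 * 0.95 / nrep))
})
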