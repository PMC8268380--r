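# Absolute marginal effects and the path decomposition.

test_that("the marginal effect is exactly beta * P * (1 - P) with its invariants", {
  me <- marginal_effect(0.43, 0.046)
  expect_equal(me$value, 0.43 * 0.046 * 0.954)

  set.seed(64)
  for (i in 1:50) {
    beta <- stats::rnorm(1, sd = 2)
    p <- stats::runif(1, 0.001, 0.999)
    v <- marginal_effect(beta, p)$value
    expect_equal(v, beta * p * (1 - p))
    expect_lte(abs(v), abs(beta) / 4 + 1e-15)   # logistic derivative bound
    expect_identical(sign(v), sign(beta))
  }
  # the bound is attained at P = 1/2
  expect_equal(marginal_effect(0.8, 0.5)$value, 0.2)
})

test_that("prevalences outside (0,1) are rejected and values vanish at the boundary", {
  expect_error(marginal_effect(1, 0), "inside \\(0, 1\\)")
  expect_error(marginal_effect(1, 1), "inside \\(0, 1\\)")
  expect_error(marginal_effect(1, -0.2), "inside \\(0, 1\\)")
  expect_lt(marginal_effect(5, 1e-12)$value, 1e-10)
})

test_that("the formula agrees with the numerical derivative of the logistic mean", {
  for (case in list(c(0.43, 0.046), c(0.83, 0.0217), c(-1.2, 0.5),
                    c(2.45, 0.022))) {
    beta <- case[1]; p <- case[2]
    h <- 1e-6
    x0 <- stats::qlogis(p) / beta   # point where predicted probability is p
    num <- (stats::plogis(beta * (x0 + h)) - stats::plogis(beta * (x0 - h))) /
      (2 * h)
    expect_equal(marginal_effect(beta, p)$value, num,
                 tolerance = 1e-6 * abs(beta))
  }
})

test_that("marginal_effects evaluates every fit term at the dependent-variable mean", {
  set.seed(31)
  d <- data.frame(x = stats::rnorm(800))
  d$y <- stats::runif(800) < stats::plogis(-1 + 0.7 * d$x)
  fit <- fit_logistic(d, "y", "x")
  me <- marginal_effects(fit)
  expect_identical(me$term, fit$terms$term)
  expect_equal(me$dpdx,
               fit$terms$beta * fit$dependent_mean * (1 - fit$dependent_mean))
  expect_error(marginal_effects(fit, terms = "nope"), "not in fit")
})

published <- function() {
  list(a = c(infection = 0.0190, shock = 0.0025, bleeding = 0.0050,
             wound_disruption = 0.0060, digestive = 0.0135),
       b_mort = c(infection = 0.0176, shock = 0.0521, bleeding = 0.0121,
                  wound_disruption = 0.0132, digestive = 0.0046),
       b_los = c(infection = 8.42, shock = 8.68, bleeding = 3.15,
                 wound_disruption = 11.09, digestive = 3.94),
       b_chg = c(infection = 62169, shock = 85247, bleeding = 30770,
                 wound_disruption = 86760, digestive = 23378))
}

test_that("path products multiply exactly and totals add exactly", {
  pb <- published()
  ps <- build_paths(pb$a, pb$b_mort, pb$b_los, pb$b_chg)
  expect_equal(ps$paths$prod_mort, ps$paths$a * ps$paths$b_mort)
  expect_equal(unname(ps$totals["mortality"]), sum(ps$paths$prod_mort))
  expect_equal(unname(ps$totals["los"]), sum(ps$paths$prod_los))
  expect_equal(unname(ps$totals["charges"]), sum(ps$paths$prod_chg))
  expect_identical(unname(ps$dominant["mortality"]), "infection")

  # a mediator with a = 0 contributes nothing anywhere
  a0 <- pb$a; a0["shock"] <- 0
  ps0 <- build_paths(a0, pb$b_mort, pb$b_los, pb$b_chg)
  expect_equal(ps0$paths$prod_mort[ps0$paths$mediator == "shock"], 0)
  expect_equal(unname(ps0$totals["mortality"]),
               unname(ps$totals["mortality"]) - 0.0025 * 0.0521)
})

test_that("totals are invariant to mediator ordering and linear in each a", {
  pb <- published()
  ps <- build_paths(pb$a, pb$b_mort, pb$b_los, pb$b_chg)
  perm <- c("digestive", "shock", "infection", "wound_disruption", "bleeding")
  ps_perm <- build_paths(pb$a[perm], pb$b_mort, pb$b_los, pb$b_chg)
  expect_equal(ps_perm$totals, ps$totals)

  delta <- 0.01
  a2 <- pb$a; a2["bleeding"] <- a2["bleeding"] + delta
  ps2 <- build_paths(a2, pb$b_mort, pb$b_los, pb$b_chg)
  expect_equal(unname(ps2$totals - ps$totals),
               unname(delta * c(pb$b_mort["bleeding"], pb$b_los["bleeding"],
                                pb$b_chg["bleeding"])))
})

test_that("mismatched mediator sets across layers are rejected", {
  pb <- published()
  expect_error(build_paths(pb$a[-1], pb$b_mort, pb$b_los, pb$b_chg),
               "mediator name sets differ")
  expect_error(from_printed_tables(
    data.frame(mediator = "infection", dpdx = 0.019),
    data.frame(mediator = "shock", dpdx = 0.05),
    data.frame(mediator = "infection", beta_los = 8, beta_chg = 6e4)),
    "mediator name sets differ")
})

test_that("replay from beta/P pairs matches replay from precomputed dP/dX", {
  pb <- published()
  t3 <- data.frame(mediator = names(pb$a),
                   beta = c(0.43, 0.72, 0.24, 0.51, 0.13),
                   p = c(0.046, 0.003, 0.021, 0.012, 0.120))
  t4 <- data.frame(mediator = names(pb$b_mort),
                   beta = c(0.83, 2.45, 0.57, 0.62, 0.22),
                   p = 912 / 42046)
  t5 <- data.frame(mediator = names(pb$a), beta_los = pb$b_los,
                   beta_chg = pb$b_chg)
  ps_beta <- from_printed_tables(t3, t4, t5)
  ps_dpdx <- from_printed_tables(
    data.frame(mediator = names(pb$a), dpdx = pb$a),
    data.frame(mediator = names(pb$b_mort), dpdx = pb$b_mort), t5)
  # rounding of the printed dP/dX values is the only difference
  expect_equal(ps_beta$totals, ps_dpdx$totals, tolerance = 0.03)
  expect_equal(ps_beta$paths$a,
               t3$beta * t3$p * (1 - t3$p))
})

test_that("the bundled replay file reproduces the published decomposition end to end", {
  path <- system.file("extdata", "published_effects.csv", package = "margpath")
  tabs <- read_replay_coefficients(path)
  ps <- from_printed_tables(tabs$table3, tabs$table4, tabs$table5)
  expect_identical(nrow(ps$paths), 5L)
  expect_identical(unname(ps$dominant), rep("infection", 3))

  out <- withr::local_tempdir()
  ps2 <- replay_pipeline(path, outdir = out)
  expect_equal(ps2$totals, ps$totals)
  expect_true(file.exists(file.path(out, "path_summary.json")))
  parsed <- jsonlite::read_json(file.path(out, "path_summary.json"),
                                simplifyVector = TRUE)
  expect_equal(parsed$totals$mortality, unname(ps$totals["mortality"]))
})

test_that("the diagram serialization carries one edge per path segment", {
  pb <- published()
  ps <- build_paths(pb$a, pb$b_mort, pb$b_los, pb$b_chg)
  dg <- path_diagram(ps)
  expect_identical(nrow(dg$nodes), 1L + 5L + 3L)
  expect_identical(nrow(dg$edges), 5L + 3L * 5L)
  expect_equal(dg$edges$weight[dg$edges$kind == "exposure->mediator"],
               unname(pb$a))
})
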