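# Synthetic admission generator: config validation, determinism, calibration,
# agreement of realized rates with the analytic population averages, CSV
# round trip.

test_that("invalid configurations are rejected before any sampling", {
  expect_error(sim_config(n_patients = -5, calibrate = FALSE),
               "non-negative integer")
  expect_error(sim_config(obesity_prevalence = 1.2, calibrate = FALSE),
               "\\(0, 1\\)")
  ct <- default_covariate_tables()
  ct$race <- ct$race * 1.01
  expect_error(sim_config(covariate_tables = ct, calibrate = FALSE),
               "sums to")
  expect_error(sim_config(missingness = c(died = -0.1, los = 0, charges = 0),
                          calibrate = FALSE),
               "missingness")
  expect_error(calibrate_intercepts(sim_config(calibrate = FALSE),
                                    c(infection = 1.5)),
               "\\(0, 1\\)")
})

test_that("n_patients = 0 yields an empty record collection", {
  pop <- generate_population(sim_config(n_patients = 0, calibrate = FALSE))
  expect_identical(nrow(pop), 0L)
  expect_true(all(c("record_id", "dx_codes", "proc_codes", "died",
                    "los_days", "total_charges") %in% names(pop)))
})

test_that("the same (config, seed) pair reproduces records exactly", {
  cfg <- sim_config(n_patients = 3000, seed = 9, distractor_fraction = 0.1)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  c2 <- generate_population(cfg, seed = 10)
  expect_false(identical(a, c2))
})

# zero out every slope of a complication model, keep its shape
complication_model_zeroed <- function(m) {
  m$obesity <- 0
  m$race[] <- 0; m$income[] <- 0
  m$elective <- 0; m$urban <- 0; m$teaching <- 0
  m
}

test_that("intercept calibration matches the closed-form logit when all slopes are zero", {
  cfg <- sim_config(calibrate = FALSE)
  zero <- complication_model_zeroed(cfg$complication_models$infection)
  cfg$complication_models$infection <- zero
  # symmetric case: target one half
  out <- calibrate_intercepts(cfg, c(infection = 0.5))
  expect_equal(out$complication_models$infection$intercept, 0, tolerance = 1e-8)
  # closed-form logit for the observed infection rate
  out <- calibrate_intercepts(cfg, c(infection = 0.046))
  expect_equal(out$complication_models$infection$intercept,
               log(0.046 / 0.954), tolerance = 1e-8)
})

test_that("calibrated default intercepts reproduce the target prevalences analytically and in simulation", {
  cfg <- sim_config(n_patients = 500000, seed = 314159)
  targets <- c(infection = 0.046, shock = 0.003, bleeding = 0.021,
               wound_disruption = 0.012, digestive = 0.120, mortality = 0.022)
  ap <- analytic_prevalences(cfg)
  expect_equal(ap[names(targets)], targets, tolerance = 1e-8)

  cohort <- extract_cohort(generate_population(cfg))
  n <- nrow(cohort)
  realized <- c(colMeans(cohort[paste0("c_", names(targets)[1:5])]),
                mean(cohort$died, na.rm = TRUE))
  se <- sqrt(targets * (1 - targets) / n)
  expect_true(all(abs(realized - targets) < 3 * se))

  # every complication family, not just the mediators, matches its analytic
  # population-average probability within Monte-Carlo error
  all_ap <- ap[COMPLICATIONS]
  all_real <- colMeans(cohort[paste0("c_", COMPLICATIONS)])
  expect_true(all(abs(all_real - all_ap) <
                    3 * sqrt(all_ap * (1 - all_ap) / n)))
})

test_that("zero obesity coefficients leave obese/non-obese complication rates equal", {
  cfg <- sim_config(n_patients = 100000, seed = 2718, calibrate = FALSE)
  for (nm in COMPLICATIONS) cfg$complication_models[[nm]]$obesity <- 0
  cohort <- extract_cohort(generate_population(cfg))
  n1 <- sum(cohort$obese); n0 <- sum(!cohort$obese)
  for (nm in COMPLICATIONS) {
    p1 <- mean(cohort[[paste0("c_", nm)]][cohort$obese])
    p0 <- mean(cohort[[paste0("c_", nm)]][!cohort$obese])
    p <- mean(cohort[[paste0("c_", nm)]])
    se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n0))
    expect_lt(abs(p1 - p0), 3 * se)
  }
})

test_that("raising the obesity coefficient strictly widens the analytic exposure gap", {
  cfg <- sim_config(calibrate = FALSE)
  gap <- function(beta) {
    cfg$complication_models$infection$obesity <- beta
    analytic_prevalences(cfg, "obese")[["infection"]] -
      analytic_prevalences(cfg, "nonobese")[["infection"]]
  }
  gaps <- vapply(c(0, 0.2, 0.43, 0.8), gap, numeric(1))
  expect_true(all(diff(gaps) > 0))
})

test_that("records survive a CSV round trip, including missing-value flags", {
  cfg <- sim_config(n_patients = 400, seed = 5,
                    missingness = c(died = 0.05, los = 0.05, charges = 0.1))
  pop <- generate_population(cfg)
  path <- withr::local_tempfile(fileext = ".csv")
  write_records(pop, path)
  back <- read_records(path)
  expect_equal(back, pop)
  expect_true(any(is.na(back$total_charges)))   # missingness preserved
  expect_true(file.exists(paste0(path, ".dict.json")))
})

test_that("malformed rows are rejected with line numbers; blank outcomes are kept as missing", {
  pop <- generate_population(sim_config(n_patients = 10, seed = 1,
                                        calibrate = FALSE))
  path <- withr::local_tempfile(fileext = ".csv")

  bad <- pop; bad$los_days[3] <- -2
  write_records(bad, path)
  expect_error(read_records(path), "line 4: negative los_days")

  bad <- pop; bad$dx_codes[5] <- "15X.4;notacode"
  write_records(bad, path)
  expect_error(read_records(path), "line 6: malformed diagnosis code")

  ok <- pop; ok$los_days[2] <- NA
  write_records(ok, path)
  back <- read_records(path)
  expect_identical(nrow(back), nrow(pop))   # flagged missing, not dropped
  expect_true(is.na(back$los_days[2]))
})
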