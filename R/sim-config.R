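# Simulation configuration: covariate marginals, logistic complication and
# mortality models, linear LOS/charges models, missingness, seed.

#' Default generator parameter blocks
#'
#' `default_covariate_tables()` returns the covariate marginals of the
#' post-inclusion surgical CRC cohort (proportions of a 107,067-admission
#' national inpatient population); `default_complication_models()` the
#' generating logistic coefficient sets of the 13 complication families;
#' `default_prevalence_targets()` the prevalences the default configuration
#' is calibrated to.
#'
#' @return Named lists / numeric vectors consumed by [sim_config()].
#' @export
default_covariate_tables <- function() {
  n <- 107067
  list(
    sex = c(male = 53376, female = 53691) / n,
    age_group = c(`20-44` = 5238, `45-59` = 23527,
                  `60-74` = 38758, `75+` = 39544) / n,
    race = c(White = 83173, Black = 10673, Hispanic = 7061,
             `Asian or Pacific Islander` = 3106, Other = 3054) / n,
    income_quartile = c(Q1 = 26757, Q2 = 27058, Q3 = 26412, Q4 = 26840) / n,
    bed_size = c(small = 13080, medium = 26230, large = 67757) / n,
    elective = 70062 / n,
    metastasis = 37465 / n,
    alcohol_abuse = 2041 / n,
    liver_disease = 2058 / n,
    # diabetes is the one covariate deliberately tied to the exposure
    diabetes_given_obese = 0.4072,
    diabetes_given_nonobese = 0.1872,
    urban = 95133 / n,
    teaching = 47697 / n
  )
}

# Named logistic coefficient set for one complication model. Reference levels:
# White (race), Q1 (income), non-elective, rural, non-teaching.
complication_model <- function(intercept, obesity,
                               race = c(Black = 0, Hispanic = 0,
                                        `Asian or Pacific Islander` = 0,
                                        Other = 0),
                               income = c(Q2 = 0, Q3 = 0, Q4 = 0),
                               elective = 0, urban = 0, teaching = 0) {
  list(intercept = intercept, obesity = obesity, race = race, income = income,
       elective = elective, urban = urban, teaching = teaching)
}

# Background intercept-only rates cover the eight complication families whose
# occurrence the generator does not tie to obesity.
#' @rdname default_covariate_tables
#' @export
default_complication_models <- function() {
  race_names <- c("Black", "Hispanic", "Asian or Pacific Islander", "Other")
  rc <- function(black, hispanic, asian, other) {
    stats::setNames(c(black, hispanic, asian, other), race_names)
  }
  qc <- function(q2, q3, q4) c(Q2 = q2, Q3 = q3, Q4 = q4)
  bg <- function(p) complication_model(intercept = stats::qlogis(p), obesity = 0)
  list(
    infection = complication_model(
      intercept = -3.08, obesity = 0.43,
      race = rc(0.02, 0.004, 0.23, -0.02), income = qc(0.01, 0.05, 0.06),
      elective = -0.44, urban = 0.04, teaching = 0.33),
    shock = complication_model(
      intercept = -6.80, obesity = 0.72,
      race = rc(-0.12, 0.17, 0.64, 0.36), income = qc(0.30, 0.48, 0.59),
      elective = -0.65, urban = 1.06, teaching = -0.10),
    bleeding = complication_model(
      intercept = -3.89, obesity = 0.24,
      race = rc(-0.04, 0.02, -0.16, 0.15), income = qc(0.09, 0.11, -0.02),
      elective = -0.06, urban = -0.05, teaching = 0.08),
    wound_disruption = complication_model(
      intercept = -4.07, obesity = 0.51,
      race = rc(-0.10, 0.08, 0.003, -0.47), income = qc(-0.02, -0.07, -0.28),
      elective = -0.61, urban = -0.24, teaching = 0.46),
    digestive = complication_model(
      intercept = -1.98, obesity = 0.13,
      race = rc(0.10, -0.18, -0.10, -0.10), income = qc(-0.02, 0.01, -0.04),
      elective = -0.17, urban = 0.15, teaching = -0.09),
    nonhealing_wound = bg(0.004),
    nervous = bg(0.003),
    cardiac = bg(0.015),
    phlebitis = bg(0.004),
    respiratory = bg(0.040),
    urinary = bg(0.050),
    vascular = bg(0.003),
    unspecified = bg(0.020)
  )
}

#' @rdname default_covariate_tables
#' @export
default_prevalence_targets <- function() {
  c(infection = 0.046, shock = 0.003, bleeding = 0.021,
    wound_disruption = 0.012, digestive = 0.120, mortality = 0.022)
}

#' Simulation configuration for NIS-like admission records
#'
#' Assembles (and optionally calibrates) the full parameter set of the
#' synthetic-data generator. The defaults encode the study conditions of a
#' national surgical colorectal-cancer cohort: covariate marginals of a
#' 107,067-admission population, obesity prevalence 7.86%, five
#' obesity-related complication models (postoperative infection, shock,
#' bleeding, wound disruption, digestive complications) with published-scale
#' log-odds coefficients, a mortality model driven by those five
#' complications, and linear models for length of stay (days) and total
#' charges (US dollars) with right-skewed, mean-centred log-normal noise.
#'
#' With `calibrate = TRUE` (default) the logistic intercepts are adjusted by
#' 1-D root finding so the analytic population-average prevalences hit the
#' targets (infection 4.6%, shock 0.3%, bleeding 2.1%, wound disruption 1.2%,
#' digestive 12.0%, mortality 2.2%).
#'
#' @param n_patients number of admission records to generate.
#' @param obesity_prevalence probability that a record carries the obesity
#'   diagnosis code (278.0x).
#' @param covariate_tables named list of categorical marginals and Bernoulli
#'   probabilities; see `default_covariate_tables()`.
#' @param complication_models named list of 13 logistic coefficient sets.
#' @param mortality_model logistic coefficient set over the five mediators.
#' @param los_model,charges_model linear coefficient sets with noise scale.
#' @param missingness per-outcome missing-completely-at-random rates for the
#'   death flag, length of stay and total charges.
#' @param distractor_fraction fraction of *additional* records violating the
#'   cohort inclusion rules (other primary cancer, no qualifying surgery, or
#'   age below 20), to exercise cohort extraction.
#' @param seed RNG seed used by [generate_population()].
#' @param calibrate adjust logistic intercepts to the prevalence targets?
#' @param prevalence_targets named targets used when `calibrate = TRUE`.
#' @return A validated object of class `margpath_sim_config`.
#' @seealso [generate_population()], [calibrate_intercepts()]
#' @export
sim_config <- function(n_patients = 107067,
                       obesity_prevalence = 8412 / 107067,
                       covariate_tables = default_covariate_tables(),
                       complication_models = default_complication_models(),
                       mortality_model = list(
                         intercept = -3.97,
                         complications = c(infection = 0.83, shock = 2.45,
                                           bleeding = 0.57,
                                           wound_disruption = 0.62,
                                           digestive = 0.22)),
                       los_model = list(
                         intercept = 8.08,
                         complications = c(infection = 8.42, shock = 8.68,
                                           bleeding = 3.15,
                                           wound_disruption = 11.09,
                                           digestive = 3.94),
                         noise_mean = 8, noise_sd = 8),
                       charges_model = list(
                         intercept = 54795,
                         complications = c(infection = 62169, shock = 85247,
                                           bleeding = 30770,
                                           wound_disruption = 86760,
                                           digestive = 23378),
                         noise_mean = 50000, noise_sd = 78000),
                       missingness = c(died = 61 / 107067, los = 2 / 107067,
                                       charges = 3154 / 107067),
                       distractor_fraction = 0,
                       seed = 1L,
                       calibrate = TRUE,
                       prevalence_targets = default_prevalence_targets()) {
  cfg <- structure(
    list(n_patients = n_patients,
         obesity_prevalence = obesity_prevalence,
         covariate_tables = covariate_tables,
         complication_models = complication_models,
         mortality_model = mortality_model,
         los_model = los_model,
         charges_model = charges_model,
         missingness = missingness,
         distractor_fraction = distractor_fraction,
         seed = seed),
    class = "margpath_sim_config")
  validate_sim_config(cfg)
  if (calibrate) cfg <- calibrate_intercepts(cfg, prevalence_targets)
  cfg
}

#' Validate a simulation configuration
#'
#' Checks the non-stochastic invariants before any sampling: categorical
#' distributions sum to one (within 1e-9), all probabilities lie in the open
#' or closed unit interval as appropriate, and sizes are non-negative.
#'
#' @param cfg a `margpath_sim_config`.
#' @return `cfg`, invisibly; stops with a descriptive error otherwise.
#' @export
validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "margpath_sim_config"))
  if (length(cfg$n_patients) != 1L || is.na(cfg$n_patients) ||
      cfg$n_patients < 0 || cfg$n_patients != round(cfg$n_patients)) {
    stop("n_patients must be a single non-negative integer")
  }
  if (cfg$obesity_prevalence <= 0 || cfg$obesity_prevalence >= 1) {
    stop("obesity_prevalence must lie in (0, 1)")
  }
  ct <- cfg$covariate_tables
  for (nm in c("sex", "age_group", "race", "income_quartile", "bed_size")) {
    tab <- ct[[nm]]
    if (is.null(tab) || any(tab < 0)) stop("invalid distribution for ", nm)
    if (abs(sum(tab) - 1) > 1e-9) {
      stop("categorical distribution '", nm, "' sums to ", sum(tab),
           ", not 1 (tolerance 1e-9)")
    }
  }
  bern <- c("elective", "metastasis", "alcohol_abuse", "liver_disease",
            "diabetes_given_obese", "diabetes_given_nonobese", "urban",
            "teaching")
  for (nm in bern) {
    p <- ct[[nm]]
    if (is.null(p) || p < 0 || p > 1) stop("probability '", nm, "' invalid")
  }
  if (!setequal(names(cfg$complication_models), COMPLICATIONS)) {
    stop("complication_models must cover exactly the 13 complication families")
  }
  if (any(cfg$missingness < 0) || any(cfg$missingness > 1)) {
    stop("missingness rates must lie in [0, 1]")
  }
  if (cfg$distractor_fraction < 0) stop("distractor_fraction must be >= 0")
  invisible(cfg)
}

# --- analytic population-average probabilities ------------------------------

# Joint distribution of the covariate cells entering the complication models:
# obesity x race x income x elective x urban x teaching (320 cells), under the
# generator's independence structure.
covariate_cells <- function(cfg) {
  ct <- cfg$covariate_tables
  cells <- expand.grid(
    obese = c(FALSE, TRUE),
    race = names(ct$race),
    income_quartile = names(ct$income_quartile),
    elective = c(FALSE, TRUE),
    urban = c(FALSE, TRUE),
    teaching = c(FALSE, TRUE),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  p_ob <- ifelse(cells$obese, cfg$obesity_prevalence, 1 - cfg$obesity_prevalence)
  p_bin <- function(flag, p) ifelse(flag, p, 1 - p)
  cells$prob <- p_ob *
    ct$race[cells$race] *
    ct$income_quartile[cells$income_quartile] *
    p_bin(cells$elective, ct$elective) *
    p_bin(cells$urban, ct$urban) *
    p_bin(cells$teaching, ct$teaching)
  cells
}

# Linear predictor of one complication model on the covariate cells.
cell_linear_predictor <- function(model, cells) {
  race_beta <- c(model$race, White = 0)[cells$race]
  income_beta <- c(model$income, Q1 = 0)[cells$income_quartile]
  model$intercept +
    model$obesity * cells$obese +
    race_beta + income_beta +
    model$elective * cells$elective +
    model$urban * cells$urban +
    model$teaching * cells$teaching
}

#' Analytic population-average outcome probabilities
#'
#' Computes, by exact enumeration of the generator's covariate cells (and, for
#' mortality, of the 32 complication patterns conditionally independent given
#' covariates), the expected prevalence of each complication and of
#' in-hospital death under a configuration — no sampling involved. These are
#' the quantities the intercept calibration drives to their targets, and the
#' oracle against which realized simulation rates are tested.
#'
#' @param cfg a `margpath_sim_config`.
#' @param group `"all"`, `"obese"`, or `"nonobese"`: condition on exposure.
#' @return Named numeric vector: the 13 complication prevalences and
#'   `mortality`.
#' @export
analytic_prevalences <- function(cfg, group = c("all", "obese", "nonobese")) {
  group <- match.arg(group)
  cells <- covariate_cells(cfg)
  if (group != "all") {
    keep <- if (group == "obese") cells$obese else !cells$obese
    cells <- cells[keep, , drop = FALSE]
    cells$prob <- cells$prob / sum(cells$prob)
  }
  comp_p <- vapply(COMPLICATIONS, function(nm) {
    p <- stats::plogis(cell_linear_predictor(cfg$complication_models[[nm]], cells))
    sum(cells$prob * p)
  }, numeric(1))

  med <- names(cfg$mortality_model$complications)
  p_med <- lapply(med, function(nm) {
    stats::plogis(cell_linear_predictor(cfg$complication_models[[nm]], cells))
  })
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), length(med))))
  colnames(patterns) <- med
  mort <- 0
  for (k in seq_len(nrow(patterns))) {
    w <- cells$prob
    for (j in seq_along(med)) {
      w <- w * (if (patterns[k, j] == 1) p_med[[j]] else 1 - p_med[[j]])
    }
    lp <- cfg$mortality_model$intercept +
      sum(cfg$mortality_model$complications * patterns[k, ])
    mort <- mort + sum(w) * stats::plogis(lp)
  }
  c(comp_p, mortality = mort)
}

#' Calibrate logistic intercepts to target prevalences
#'
#' Adjusts the intercept of each named logistic model by monotone 1-D root
#' finding ([stats::uniroot()]) so that the analytic population-average
#' probability (see [analytic_prevalences()]) equals the target. The
#' population-average probability is strictly increasing in the intercept, so
#' the root is unique.
#'
#' @param cfg a `margpath_sim_config`.
#' @param targets named vector of proportions in (0,1); names are complication
#'   model names and/or `"mortality"`.
#' @param tol absolute tolerance on the achieved prevalence.
#' @return The configuration with intercepts replaced.
#' @export
calibrate_intercepts <- function(cfg, targets, tol = 1e-10) {
  validate_sim_config(cfg)
  if (any(targets <= 0) || any(targets >= 1)) {
    stop("calibration targets must lie in (0, 1)")
  }
  bad <- setdiff(names(targets), c(names(cfg$complication_models), "mortality"))
  if (length(bad)) stop("unknown calibration targets: ", paste(bad, collapse = ", "))

  cells <- covariate_cells(cfg)
  for (nm in setdiff(names(targets), "mortality")) {
    model <- cfg$complication_models[[nm]]
    lp0 <- cell_linear_predictor(model, cells) - model$intercept
    f <- function(b0) sum(cells$prob * stats::plogis(b0 + lp0)) - targets[[nm]]
    root <- tryCatch(
      stats::uniroot(f, c(-40, 20), tol = tol),
      error = function(e) stop("calibration target for '", nm,
                               "' unattainable: ", conditionMessage(e)))
    cfg$complication_models[[nm]]$intercept <- root$root
  }
  if ("mortality" %in% names(targets)) {
    f <- function(b0) {
      cfg$mortality_model$intercept <- b0
      unname(analytic_prevalences(cfg)["mortality"]) - targets[["mortality"]]
    }
    root <- tryCatch(
      stats::uniroot(f, c(-40, 20), tol = tol),
      error = function(e) stop("calibration target for 'mortality' ",
                               "unattainable: ", conditionMessage(e)))
    cfg$mortality_model$intercept <- root$root
  }
  cfg
}

#' @export
print.margpath_sim_config <- function(x, ...) {
  cat("<margpath_sim_config>\n")
  cat("  n_patients:        ", x$n_patients, "\n")
  cat("  obesity prevalence:", signif(x$obesity_prevalence, 4), "\n")
  cat("  distractors:       ", x$distractor_fraction, "\n")
  cat("  seed:              ", x$seed, "\n")
  ap <- analytic_prevalences(x)
  cat("  analytic prevalences (mediators + mortality):\n")
  show <- signif(ap[c(MEDIATORS, "mortality")], 3)
  for (nm in names(show)) cat(sprintf("    %-17s %s\n", nm, show[[nm]]))
  invisible(x)
}

#' Read or write a simulation configuration as YAML
#'
#' @param cfg a `margpath_sim_config`.
#' @param path file path.
#' @return `read_sim_config()` returns a validated configuration (intercepts
#'   are taken as stored; no re-calibration).
#' @export
write_sim_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "margpath_sim_config"))
  yaml::write_yaml(rapply(unclass(cfg), function(x) x, how = "replace"), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops names on scalars read back into lists; restore numeric vectors
  renum <- function(x) {
    if (is.list(x) && length(x) && all(vapply(x, is.numeric, logical(1))) &&
        all(vapply(x, length, integer(1)) == 1L) && !is.null(names(x))) {
      unlist(x)
    } else if (is.list(x)) {
      lapply(x, renum)
    } else x
  }
  cfg <- structure(renum(raw), class = "margpath_sim_config")
  validate_sim_config(cfg)
  cfg
}
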