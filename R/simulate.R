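# Synthetic NIS-like admission generator. Records are emitted as the
# post-inclusion surgical CRC population by default; distractor records
# violating the inclusion rules can be appended to exercise extraction.

# Draw n values from a categorical distribution given as a named probability
# vector.
sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Mean-centred shifted log-normal noise: a log-normal variate with the given
# mean and SD, minus its mean. Support is [-mean, Inf), so adding it to a
# linear predictor bounded below by `mean` keeps outcomes non-negative
# without truncation.
rlnorm_centred <- function(n, mean, sd) {
  if (sd == 0) return(rep(0, n))
  sdlog2 <- log(1 + (sd / mean)^2)
  meanlog <- log(mean) - sdlog2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sqrt(sdlog2)) - mean
}

# Paste optional code columns (NA = absent) into semicolon-delimited strings.
join_codes <- function(...) {
  cols <- list(...)
  cols <- lapply(cols, function(x) ifelse(is.na(x), "", x))
  joined <- do.call(paste, c(cols, sep = ";"))
  joined <- gsub(";{2,}", ";", joined)
  gsub("^;+|;+$", "", joined)
}

#' Generate a synthetic admission-level population
#'
#' Samples `n_patients` admission records under the configuration's causal
#' structure: covariates first, then each of the 13 postoperative
#' complications from its logistic model given covariates and obesity, then
#' in-hospital death from the mortality model given the realized five mediator
#' complications, then length of stay and total charges from the linear models
#' plus mean-centred log-normal noise. Clinical concepts are carried as
#' ICD-9-CM diagnosis codes (obesity 278.0x, CRC 153.x/154.x, metastasis
#' 196-199, comorbidities, complication codes) and ICD-9 procedure codes
#' (colorectal surgery), so the cohort module must recover every analytic flag
#' from the codes alone. Length of stay is reported in whole days and charges
#' in whole US dollars, as discharge abstracts do. A configurable fraction of
#' death/LOS/charge values is set missing completely at random.
#'
#' Identical `(config, seed)` pairs give identical output.
#'
#' @param config a [sim_config()] object.
#' @param seed optional override of `config$seed`.
#' @return A `data.frame` of admission records (one row per admission) with
#'   columns `record_id`, `dx_codes`, `proc_codes` (semicolon-delimited code
#'   strings), demographics, hospital attributes, and outcomes `died`
#'   (logical), `los_days`, `total_charges` (NA = missing).
#' @examples
#' cfg <- sim_config(n_patients = 500, calibrate = FALSE)
#' pop <- generate_population(cfg)
#' mean(codes_have_prefix(pop$dx_codes, "2780"))  # ~ obesity prevalence
#' @export
generate_population <- function(config, seed = NULL) {
  validate_sim_config(config)
  if (is.null(seed)) seed <- config$seed
  n <- as.integer(config$n_patients)
  n_extra <- as.integer(round(config$distractor_fraction * n))
  empty <- record_frame(0L)
  if (n + n_extra == 0L) return(empty)

  set.seed(seed)
  ct <- config$covariate_tables
  nn <- n + n_extra

  obese <- stats::runif(nn) < config$obesity_prevalence
  sex <- sample_cat(nn, ct$sex)
  age_group <- sample_cat(nn, ct$age_group)
  race <- sample_cat(nn, ct$race)
  income <- sample_cat(nn, ct$income_quartile)
  bed_size <- sample_cat(nn, ct$bed_size)
  elective <- stats::runif(nn) < ct$elective
  metastasis <- stats::runif(nn) < ct$metastasis
  alcohol <- stats::runif(nn) < ct$alcohol_abuse
  liver <- stats::runif(nn) < ct$liver_disease
  diabetes <- stats::runif(nn) <
    ifelse(obese, ct$diabetes_given_obese, ct$diabetes_given_nonobese)

  age_lo <- c(`20-44` = 20L, `45-59` = 45L, `60-74` = 60L, `75+` = 75L)
  age_hi <- c(`20-44` = 44L, `45-59` = 59L, `60-74` = 74L, `75+` = 100L)
  age <- age_lo[age_group] +
    floor(stats::runif(nn) * (age_hi[age_group] - age_lo[age_group] + 1L))

  covars <- data.frame(obese = obese, race = race, income_quartile = income,
                       elective = elective, urban = stats::runif(nn) < ct$urban,
                       teaching = stats::runif(nn) < ct$teaching,
                       stringsAsFactors = FALSE)

  comp <- matrix(FALSE, nn, length(COMPLICATIONS),
                 dimnames = list(NULL, COMPLICATIONS))
  for (nm in COMPLICATIONS) {
    lp <- cell_linear_predictor(config$complication_models[[nm]], covars)
    comp[, nm] <- stats::runif(nn) < stats::plogis(lp)
  }

  med <- names(config$mortality_model$complications)
  lp_mort <- config$mortality_model$intercept +
    comp[, med, drop = FALSE] %*% config$mortality_model$complications
  died <- stats::runif(nn) < stats::plogis(drop(lp_mort))

  mean_of <- function(model) {
    drop(model$intercept +
           comp[, names(model$complications), drop = FALSE] %*%
           model$complications)
  }
  los <- round(mean_of(config$los_model) +
                 rlnorm_centred(nn, config$los_model$noise_mean,
                                config$los_model$noise_sd))
  los <- pmax(los, 0)
  charges <- round(mean_of(config$charges_model) +
                     rlnorm_centred(nn, config$charges_model$noise_mean,
                                    config$charges_model$noise_sd))
  charges <- pmax(charges, 0)

  died[stats::runif(nn) < config$missingness[["died"]]] <- NA
  los[stats::runif(nn) < config$missingness[["los"]]] <- NA
  charges[stats::runif(nn) < config$missingness[["charges"]]] <- NA

  # diagnosis code assembly
  crc_code <- sample(c("153.4", "153.6", "153.9", "154.0", "154.1"),
                     nn, replace = TRUE)
  met_code <- ifelse(metastasis,
                     sample(c("197.7", "197.0", "198.5"), nn, replace = TRUE),
                     NA_character_)
  ob_code <- ifelse(obese,
                    sample(c("278.00", "278.01"), nn, replace = TRUE),
                    NA_character_)
  dm_code <- ifelse(diabetes, "250.00", NA_character_)
  liv_code <- ifelse(liver, "571.5", NA_character_)
  alc_code <- ifelse(alcohol, "303.90", NA_character_)
  # common chronic-condition codes, all outside every rule set
  benign <- sample(c("401.9", "272.4", "414.01", "530.81", "285.9", "311"),
                   nn, replace = TRUE)
  comp_codes <- list(
    infection = "998.59", shock = "998.0", bleeding = "998.11",
    wound_disruption = "998.32", nonhealing_wound = "998.83",
    nervous = "997.02", cardiac = "997.1", phlebitis = "997.2",
    respiratory = "997.3", digestive = "997.4", urinary = "997.5",
    vascular = "997.71", unspecified = "998.9")
  comp_cols <- lapply(COMPLICATIONS, function(nm) {
    ifelse(comp[, nm], comp_codes[[nm]], NA_character_)
  })
  dx <- do.call(join_codes, c(list(crc_code, met_code, ob_code, dm_code,
                                   liv_code, alc_code, benign), comp_cols))

  surgery <- sample(c("45.73", "45.74", "45.76", "45.79", "48.40", "48.41",
                      "48.43", "48.49", "48.50", "48.52", "48.59", "48.62",
                      "48.63", "48.69"), nn, replace = TRUE)
  other_proc <- ifelse(stats::runif(nn) < 0.3, "38.93", NA_character_)
  proc <- join_codes(surgery, other_proc)

  # distractor records violate exactly one inclusion rule each
  if (n_extra > 0L) {
    idx <- n + seq_len(n_extra)
    kind <- sample(c("other_cancer", "no_surgery", "underage"), n_extra,
                   replace = TRUE)
    oc <- idx[kind == "other_cancer"]
    dx[oc] <- paste(dx[oc],
                    sample(c("162.9", "174.9", "185", "151.9"), length(oc),
                           replace = TRUE), sep = ";")
    ns <- idx[kind == "no_surgery"]
    proc[ns] <- ifelse(is.na(other_proc[ns]), "89.52", "38.93")
    ua <- idx[kind == "underage"]
    age[ua] <- sample(1:19, length(ua), replace = TRUE)
  }

  out <- data.frame(
    record_id = sprintf("R%07d", seq_len(nn)),
    dx_codes = dx, proc_codes = proc,
    age_years = as.integer(age), sex = sex, race = race,
    income_quartile = income, elective = elective, bed_size = bed_size,
    urban = covars$urban, teaching = covars$teaching,
    died = died, los_days = as.numeric(los), total_charges = as.numeric(charges),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Zero-row record frame with the canonical column set.
record_frame <- function(n) {
  data.frame(record_id = character(n), dx_codes = character(n),
             proc_codes = character(n), age_years = integer(n),
             sex = character(n), race = character(n),
             income_quartile = character(n), elective = logical(n),
             bed_size = character(n), urban = logical(n),
             teaching = logical(n), died = logical(n),
             los_days = numeric(n), total_charges = numeric(n),
             stringsAsFactors = FALSE)
}

#' Test whether any code in a record matches a prefix set
#'
#' Convenience wrapper over the code book's prefix-matching convention, for
#' semicolon-delimited code strings.
#'
#' @param code_lists character vector of semicolon-delimited code strings.
#' @param prefixes character vector of (dotted or dot-free) code prefixes.
#' @return logical vector, one element per record.
#' @export
codes_have_prefix <- function(code_lists, prefixes) {
  codes_match(code_lists, prefixes)
}
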