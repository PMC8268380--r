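# Shared fixtures and independent oracles for the test suite.

# Independent maximum-likelihood logistic oracle: direct numerical
# minimization of the hand-coded negative log-likelihood (no IRLS, no glm).
brute_logit <- function(y, X) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  nll <- function(b) {
    lp <- drop(X %*% b)
    -sum(y * lp - log1p(exp(lp)))
  }
  gr <- function(b) {
    p <- stats::plogis(drop(X %*% b))
    -drop(crossprod(X, y - p))
  }
  fit <- stats::optim(rep(0, ncol(X)), nll, gr, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  stats::setNames(fit$par, colnames(X))
}

# Hand-computed Pearson chi-square: sum((O - E)^2 / E) over the table.
chisq_oracle <- function(tab) {
  tab <- as.matrix(tab)
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - e)^2 / e)
  list(statistic = stat,
       p_value = stats::pchisq(stat, ncol(tab) - 1L, lower.tail = FALSE))
}

# Minimal raw admission record; every field overridable.
make_record <- function(id = "R1", dx = "153.4;278.00", proc = "45.73",
                        age = 60, sex = "male", race = "White",
                        income = "Q1", elective = TRUE, bed = "large",
                        urban = TRUE, teaching = FALSE, died = FALSE,
                        los = 7, charges = 40000) {
  data.frame(record_id = id, dx_codes = dx, proc_codes = proc,
             age_years = as.integer(age), sex = sex, race = race,
             income_quartile = income, elective = elective, bed_size = bed,
             urban = urban, teaching = teaching, died = died,
             los_days = as.numeric(los), total_charges = as.numeric(charges),
             stringsAsFactors = FALSE)
}

records_of <- function(...) do.call(rbind, list(...))

# Brute-force re-statement of the cohort rules, record by record, used as the
# oracle for extract_cohort(). Deliberately loop-based and regex-free.
oracle_keep <- function(records) {
  cb <- default_codebook()
  excluded_roots <- setdiff(as.character(140:239), cb$other_cancer_carveout)
  vapply(seq_len(nrow(records)), function(i) {
    dx <- strsplit(gsub("\\.", "", records$dx_codes[i]), ";")[[1]]
    pr <- strsplit(gsub("\\.", "", records$proc_codes[i]), ";")[[1]]
    has_crc <- any(substr(dx, 1, 3) %in% c("153", "154"))
    has_surg <- any(substr(pr, 1, 3) == "457") ||
      any(pr %in% c("4840", "4841", "4843", "4849", "4850", "4852", "4859")) ||
      any(substr(pr, 1, 3) == "486")
    adult <- records$age_years[i] >= 20
    no_other <- !any(substr(dx, 1, 3) %in% excluded_roots)
    has_crc && has_surg && adult && no_other
  }, logical(1))
}

# Small generated cohort, cached per (n, seed) within a test file run.
small_cohort <- local({
  cache <- list()
  function(n = 20000, seed = 42, ...) {
    key <- paste(n, seed, sep = "_")
    if (is.null(cache[[key]])) {
      cfg <- sim_config(n_patients = n, seed = seed, ...)
      cache[[key]] <<- extract_cohort(generate_population(cfg))
    }
    cache[[key]]
  }
})
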