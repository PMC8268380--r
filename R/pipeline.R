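# Pipeline driver: simulate/ingest -> extract -> match -> descriptives ->
# regression layers -> path decomposition, with stage-boundary artifacts.

#' Pipeline configuration
#'
#' Validates and normalizes the configuration of [run_pipeline()]. Exactly
#' one input source must be given: a CSV of admission records (`input`) or a
#' simulation block (`simulate`, a [sim_config()]).
#'
#' @param input path to an admission-record CSV ([write_records()] layout).
#' @param simulate a `margpath_sim_config` to generate the input instead.
#' @param codebook a [default_codebook()] object or YAML path.
#' @param match_key matching variables.
#' @param match_ratio controls per case.
#' @param adjustment covariate terms of the complication models.
#' @param alpha mediator-selection significance threshold.
#' @param outdir output directory (`NULL` = no files written).
#' @param seed master seed: every random draw in the pipeline (simulation and
#'   matching) derives from it.
#' @param verbose print stage progress?
#' @return A validated list of class `margpath_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, simulate = NULL,
                            codebook = default_codebook(),
                            match_key = c("age_group", "sex", "metastasis"),
                            match_ratio = 4,
                            adjustment = DEFAULT_ADJUSTMENT,
                            alpha = 0.05, outdir = NULL, seed = 1L,
                            verbose = FALSE) {
  if (is.null(input) == is.null(simulate)) {
    stop("exactly one of 'input' (records CSV) or 'simulate' (sim config) ",
         "must be given")
  }
  if (is.character(codebook)) codebook <- read_codebook(codebook)
  validate_codebook(codebook)
  if (!is.null(simulate)) validate_sim_config(simulate)
  structure(list(input = input, simulate = simulate, codebook = codebook,
                 match_key = match_key, match_ratio = match_ratio,
                 adjustment = adjustment, alpha = alpha, outdir = outdir,
                 seed = as.integer(seed), verbose = verbose),
            class = "margpath_pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: simulate or ingest the admission records; extract the
#' surgical CRC cohort (attrition logged); match obese cases 1:k to non-obese
#' controls on the matching key; compute the covariate balance and outcome
#' comparison tables; fit one logistic model per complication
#' (complication ~ obesity + adjustment covariates) on the matched cohort and
#' select the mediators whose obesity term is significant at `alpha`; fit the
#' mortality logistic model (death ~ selected mediators) and the two OLS
#' models (LOS, charges ~ selected mediators), complete-case per outcome; and
#' assemble the marginal-effect path decomposition.
#'
#' With an `outdir`, every stage boundary is serialized (records CSV,
#' attrition JSON, matches CSV, comparison CSVs, fit JSONs, path summary
#' JSON, Figure-style text table, and a run log with the seed, stage row
#' counts and package version). The run is deterministic given the
#' configuration.
#'
#' @param config a [pipeline_config()].
#' @return A result bundle (list, class `margpath_result`): `records` count,
#'   `cohort`, `matched`, `balance`, `outcomes_table`, `complication_fits`,
#'   `mediators`, `mortality_fit`, `los_fit`, `charges_fit`, `effects`
#'   (exposure- and mortality-side marginal effect tables), `paths`
#'   (a `margpath_paths`), and `log`.
#' @examples
#' \donttest{
#' cfg <- pipeline_config(simulate = sim_config(n_patients = 20000), seed = 7)
#' res <- run_pipeline(cfg)
#' res$paths
#' }
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "margpath_pipeline_config"))
  say <- function(...) if (config$verbose) message("[margpath] ", ...)
  outdir <- config$outdir
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  emit <- function(fn, ...) if (!is.null(outdir)) fn(...)
  stage <- "ingest"
  log <- list(seed = config$seed,
              package_version = as.character(utils::packageVersion("margpath")),
              r_version = R.version.string, stages = list())
  res <- tryCatch({
    if (!is.null(config$simulate)) {
      stage <- "simulate"
      records <- generate_population(config$simulate, seed = config$seed)
      say("simulated ", nrow(records), " records")
    } else {
      records <- read_records(config$input)
      say("read ", nrow(records), " records from ", config$input)
    }
    log$stages$records <- nrow(records)
    emit(write_records, records, file.path(outdir, "records.csv"))

    stage <- "extract"
    cohort <- extract_cohort(records, config$codebook)
    log$stages$cohort <- nrow(cohort)
    say("cohort: ", nrow(cohort), " rows")
    emit(write_attrition, cohort, file.path(outdir, "attrition.json"))

    stage <- "match"
    matched <- match_1to4(cohort, key = config$match_key,
                          ratio = config$match_ratio, seed = config$seed)
    mrows <- matched_rows(matched, cohort)
    log$stages$matched_cases <- length(unique(matched$matches$case_id))
    log$stages$matched_rows <- nrow(mrows)
    log$stages$unmatched_cases <- length(matched$unmatched)
    say("matched ", log$stages$matched_cases, " cases (",
        log$stages$unmatched_cases, " unmatched)")
    emit(write_matches, matched, file.path(outdir, "matches.csv"))

    stage <- "describe"
    grp <- mrows$role == "case"
    balance <- balance_table(matched, cohort)
    outcome_vars <- c("died", paste0("c_", COMPLICATIONS), "los_days",
                      "total_charges")
    outcomes_table <- comparison_table(mrows, grp, outcome_vars,
                                       group_labels = c("non-obese", "obese"))
    emit(utils::write.csv, balance, file.path(outdir, "table1_balance.csv"),
         row.names = FALSE)
    emit(utils::write.csv, outcomes_table,
         file.path(outdir, "table2_outcomes.csv"), row.names = FALSE)

    stage <- "fit"
    comp_fits <- lapply(COMPLICATIONS, function(nm) {
      # complications with no (or universal) events in a small cohort cannot
      # be modelled; they are skipped and logged rather than aborting the run
      tryCatch(
        withCallingHandlers(
          fit_logistic(mrows, outcome = paste0("c_", nm),
                       predictors = c("obese", config$adjustment)),
          # quasi-separation in rare complications is recorded in the fit's
          # `separated` flag and the run log, not escalated per model
          warning = function(w) {
            if (grepl("separation", conditionMessage(w)))
              invokeRestart("muffleWarning")
          }),
        error = function(e) NULL)
    })
    names(comp_fits) <- COMPLICATIONS
    log$stages$complications_unmodelled <-
      names(comp_fits)[vapply(comp_fits, is.null, logical(1))]
    log$stages$separation_flagged <- names(which(vapply(
      comp_fits, function(f) !is.null(f) && f$separated, logical(1))))
    comp_fits <- comp_fits[!vapply(comp_fits, is.null, logical(1))]
    mediators <- select_mediators(comp_fits, alpha = config$alpha)
    if (length(mediators) == 0L) {
      stop("no complication is significantly related to the exposure at alpha = ",
           config$alpha)
    }
    say("selected mediators: ", paste(mediators, collapse = ", "))
    med_flags <- paste0("c_", mediators)
    mortality_fit <- fit_logistic(mrows, outcome = "died",
                                  predictors = med_flags)
    los_fit <- fit_ols(mrows, outcome = "los_days", predictors = med_flags)
    charges_fit <- fit_ols(mrows, outcome = "total_charges",
                           predictors = med_flags)
    if (!is.null(outdir)) {
      for (nm in names(comp_fits)) {
        write_fit_json(comp_fits[[nm]],
                       file.path(outdir, paste0("fit_", nm, ".json")))
      }
      write_fit_json(mortality_fit, file.path(outdir, "fit_mortality.json"))
      write_fit_json(los_fit, file.path(outdir, "fit_los.json"))
      write_fit_json(charges_fit, file.path(outdir, "fit_charges.json"))
    }

    stage <- "paths"
    a_tab <- do.call(rbind, lapply(mediators, function(nm) {
      me <- marginal_effects(comp_fits[[nm]], terms = "obeseTRUE")
      data.frame(mediator = nm, beta = me$beta, p = me$p, dpdx = me$dpdx,
                 stringsAsFactors = FALSE)
    }))
    b_tab <- marginal_effects(mortality_fit,
                              terms = paste0("c_", mediators, "TRUE"))
    b_tab$mediator <- mediators
    paths <- build_paths(
      a = stats::setNames(a_tab$dpdx, a_tab$mediator),
      b_mort = stats::setNames(b_tab$dpdx, b_tab$mediator),
      b_los = los_fit, b_chg = charges_fit)
    emit(path_summary_json, paths, file.path(outdir, "path_summary.json"))
    if (!is.null(outdir)) {
      writeLines(utils::capture.output(print(paths)),
                 file.path(outdir, "figure2_paths.txt"))
      jsonlite::write_json(path_diagram(paths),
                           file.path(outdir, "path_diagram.json"),
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }

    list(n_records = nrow(records), cohort = cohort, matched = matched,
         balance = balance, outcomes_table = outcomes_table,
         complication_fits = comp_fits, mediators = mediators,
         mortality_fit = mortality_fit, los_fit = los_fit,
         charges_fit = charges_fit,
         effects = list(exposure = a_tab, mortality = b_tab),
         paths = paths, log = log)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  res$log$stages <- log$stages
  if (!is.null(outdir)) {
    jsonlite::write_json(res$log, file.path(outdir, "run_log.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  class(res) <- "margpath_result"
  res
}

#' @export
print.margpath_result <- function(x, ...) {
  cat("<margpath_result>\n")
  cat("  records:", x$n_records, "| cohort:", nrow(x$cohort),
      "| matched cases:", length(unique(x$matched$matches$case_id)), "\n")
  cat("  mediators:", paste(x$mediators, collapse = ", "), "\n\n")
  print(x$paths)
  invisible(x)
}

#' Reproduce a path decomposition from a replay coefficient file
#'
#' Convenience wrapper: reads a per-mediator published-coefficient CSV
#' ([read_replay_coefficients()]) and rebuilds the path decomposition with
#' [from_printed_tables()], optionally writing the summary JSON and diagram.
#'
#' @param path replay CSV path.
#' @param outdir optional output directory.
#' @return A `margpath_paths` object.
#' @export
replay_pipeline <- function(path, outdir = NULL) {
  tabs <- read_replay_coefficients(path)
  paths <- from_printed_tables(tabs$table3, tabs$table4, tabs$table5)
  if (!is.null(outdir)) {
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    path_summary_json(paths, file.path(outdir, "path_summary.json"))
    writeLines(utils::capture.output(print(paths)),
               file.path(outdir, "figure2_paths.txt"))
  }
  paths
}
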