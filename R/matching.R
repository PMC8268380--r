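# 1:k exact case-control matching and post-match balance.

#' Exact 1:k case-control matching
#'
#' Matches each exposed case to `ratio` unexposed controls drawn uniformly at
#' random *without replacement* from the case's exact stratum of the matching
#' variables (default: age band, sex, metastasis). Within each stratum the
#' case order is shuffled by the seed; cases left in a stratum after its
#' control pool is exhausted are reported unmatched and excluded. No control
#' is ever reused, no caliper is applied, and matching never alters any row —
#' it only selects and pairs. Output is deterministic given the seed.
#'
#' @param rows analytic cohort (`data.frame` with a logical `obese` column).
#' @param key character vector of matching variable names.
#' @param ratio controls per case (>= 1).
#' @param seed RNG seed for the shuffles.
#' @return An object of class `margpath_matched`: a list with `matches`
#'   (`data.frame` of `case_id`, `control_id`, `stratum`; `ratio` rows per
#'   matched case), `unmatched` (case record ids), `key`, `ratio`, `seed`.
#' @examples
#' cohort <- extract_cohort(generate_population(sim_config(2000, calibrate = FALSE)))
#' m <- match_1to4(cohort, seed = 7)
#' length(m$unmatched)
#' @export
match_1to4 <- function(rows, key = c("age_group", "sex", "metastasis"),
                       ratio = 4, seed = 1L) {
  if (ratio < 1 || ratio != round(ratio)) stop("ratio must be an integer >= 1")
  missing_key <- setdiff(c(key, "obese", "record_id"), names(rows))
  if (length(missing_key)) {
    stop("rows lack columns: ", paste(missing_key, collapse = ", "))
  }
  if (!any(rows$obese) || all(rows$obese)) {
    stop("rows must contain both exposed and unexposed members")
  }
  stratum <- do.call(paste, c(rows[key], sep = "|"))
  case_idx <- which(rows$obese)
  ctrl_idx <- which(!rows$obese)

  set.seed(seed)
  matches <- vector("list", 0L)
  unmatched <- character(0)
  for (s in sort(unique(stratum[case_idx]))) {
    cases <- case_idx[stratum[case_idx] == s]
    ctrls <- ctrl_idx[stratum[ctrl_idx] == s]
    cases <- cases[sample.int(length(cases))]
    ctrls <- ctrls[sample.int(length(ctrls))]
    n_ok <- min(length(cases), length(ctrls) %/% ratio)
    if (n_ok > 0L) {
      used_cases <- cases[seq_len(n_ok)]
      used_ctrls <- ctrls[seq_len(n_ok * ratio)]
      matches[[length(matches) + 1L]] <- data.frame(
        case_id = rep(rows$record_id[used_cases], each = ratio),
        control_id = rows$record_id[used_ctrls],
        stratum = s, stringsAsFactors = FALSE)
    }
    if (n_ok < length(cases)) {
      unmatched <- c(unmatched, rows$record_id[cases[-seq_len(n_ok)]])
    }
  }
  matches <- if (length(matches)) {
    do.call(rbind, matches)
  } else {
    data.frame(case_id = character(0), control_id = character(0),
               stratum = character(0), stringsAsFactors = FALSE)
  }
  structure(list(matches = matches, unmatched = unmatched, key = key,
                 ratio = ratio, seed = seed),
            class = "margpath_matched")
}

#' @export
print.margpath_matched <- function(x, ...) {
  cat("<margpath_matched> 1:", x$ratio, " exact matching on ",
      paste(x$key, collapse = ", "), "\n", sep = "")
  cat("  matched cases:  ", length(unique(x$matches$case_id)), "\n")
  cat("  controls used:  ", nrow(x$matches), "\n")
  cat("  unmatched cases:", length(x$unmatched), "\n")
  invisible(x)
}

#' Assemble the matched cohort rows
#'
#' Returns the analytic rows of matched cases and their controls, with a
#' `role` column (`"case"`/`"control"`). Row fields are untouched.
#'
#' @param matched a `margpath_matched` object.
#' @param rows the analytic cohort the matching was computed on.
#' @return `data.frame` of matched rows.
#' @export
matched_rows <- function(matched, rows) {
  stopifnot(inherits(matched, "margpath_matched"))
  case_ids <- unique(matched$matches$case_id)
  out <- rbind(
    cbind(rows[match(case_ids, rows$record_id), , drop = FALSE],
          role = "case", stringsAsFactors = FALSE),
    cbind(rows[match(matched$matches$control_id, rows$record_id), ,
               drop = FALSE],
          role = "control", stringsAsFactors = FALSE))
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Write matched pairs as CSV
#'
#' @param matched a `margpath_matched` object.
#' @param path output path; columns `case_id`, `control_id`, `stratum`.
#' @return `path`, invisibly.
#' @export
write_matches <- function(matched, path) {
  utils::write.csv(matched$matches, path, row.names = FALSE)
  invisible(path)
}

#' Covariate balance between matched cases and controls
#'
#' Compares each requested variable between the matched exposed and unexposed
#' groups with the descriptives layer ([compare_categorical()] /
#' [compare_continuous()]). Matching variables show exact balance: their
#' chi-square statistic is 0 and p-value 1 by construction of exact 1:k
#' matching.
#'
#' @param matched a `margpath_matched` object.
#' @param rows the analytic cohort.
#' @param vars variables to compare; default covers the demographic,
#'   severity/comorbidity and hospital blocks.
#' @return A `data.frame` with one row per variable level plus the test
#'   statistic and p-value per variable (see [comparison_table()]).
#' @export
balance_table <- function(matched, rows,
                          vars = c("sex", "age_group", "race",
                                   "income_quartile", "elective",
                                   "metastasis", "alcohol_abuse", "diabetes",
                                   "liver_disease", "bed_size", "urban",
                                   "teaching")) {
  mr <- matched_rows(matched, rows)
  comparison_table(mr, group = mr$role == "case", vars = vars,
                   group_labels = c("control", "case"))
}
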