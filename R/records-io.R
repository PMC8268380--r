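# CSV persistence for admission records. One row per admission; dx/proc codes
# as semicolon-delimited lists; an empty cell in an outcome column means
# missing. A JSON data dictionary travels with the file.

RECORD_COLUMNS <- c("record_id", "dx_codes", "proc_codes", "age_years", "sex",
                    "race", "income_quartile", "elective", "bed_size",
                    "urban", "teaching", "died", "los_days", "total_charges")

record_dictionary <- function() {
  list(
    record_id = list(type = "string", description = "opaque admission identifier"),
    dx_codes = list(type = "string",
                    description = "ICD-9-CM diagnosis codes, semicolon-delimited"),
    proc_codes = list(type = "string",
                      description = "ICD-9 procedure codes, semicolon-delimited"),
    age_years = list(type = "integer", description = "age at admission, years"),
    sex = list(type = "category", levels = c("male", "female")),
    race = list(type = "category",
                levels = c("White", "Black", "Hispanic",
                           "Asian or Pacific Islander", "Other")),
    income_quartile = list(type = "category", levels = c("Q1", "Q2", "Q3", "Q4"),
                           description = "ZIP-level median household income quartile"),
    elective = list(type = "boolean", description = "elective admission"),
    bed_size = list(type = "category", levels = c("small", "medium", "large")),
    urban = list(type = "boolean", description = "urban hospital location"),
    teaching = list(type = "boolean", description = "teaching hospital"),
    died = list(type = "boolean", missing = "empty cell",
                description = "in-hospital death"),
    los_days = list(type = "number", missing = "empty cell", units = "days",
                    description = "length of stay, non-negative"),
    total_charges = list(type = "number", missing = "empty cell",
                         units = "US dollars",
                         description = "total hospital charges, non-negative")
  )
}

#' Write admission records to CSV (with data dictionary)
#'
#' Writes one row per admission; missing outcome values become empty cells.
#' A machine-readable JSON data dictionary is written next to the file
#' (`<path>.dict.json`) unless disabled.
#'
#' @param records a record `data.frame` as produced by [generate_population()].
#' @param path output CSV path.
#' @param dictionary also write the JSON data dictionary?
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, dictionary = TRUE) {
  missing_cols <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing_cols)) {
    stop("records are missing columns: ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(records[RECORD_COLUMNS], path, row.names = FALSE, na = "")
  if (dictionary) {
    jsonlite::write_json(record_dictionary(), paste0(path, ".dict.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' Read admission records from CSV
#'
#' Inverse of [write_records()]: the round trip is lossless, including
#' missing-value flags (empty outcome cells come back as `NA`; the record is
#' kept, not dropped). Rows violating the record invariants — malformed ICD-9
#' code syntax, negative length of stay or charges, unknown category levels —
#' are rejected with their line numbers (line 1 is the header).
#'
#' @param path CSV path written by [write_records()].
#' @return A record `data.frame`.
#' @export
read_records <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                         check.names = FALSE)
  missing_cols <- setdiff(RECORD_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("file lacks required columns: ", paste(missing_cols, collapse = ", "))
  }
  raw <- raw[RECORD_COLUMNS]
  lines <- seq_len(nrow(raw)) + 1L   # header occupies line 1

  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems,
                     paste0("line ", lines[bad], ": ", what))
    }
  }

  dx_ok <- validate_code_list(raw$dx_codes, "^[VE]?[0-9]{3}([0-9]{0,2})$")
  note(!dx_ok, "malformed diagnosis code")
  proc_ok <- validate_code_list(raw$proc_codes, "^[0-9]{2}([0-9]{0,2})$")
  note(!proc_ok, "malformed procedure code")

  age <- suppressWarnings(as.integer(raw$age_years))
  note(is.na(age), "age_years is not an integer")

  to_num <- function(x) suppressWarnings(as.numeric(x))
  los <- to_num(raw$los_days); los[raw$los_days == ""] <- NA
  note(!is.na(los) & los < 0, "negative los_days")
  note(raw$los_days != "" & is.na(to_num(raw$los_days)),
       "los_days is not a number")
  chg <- to_num(raw$total_charges); chg[raw$total_charges == ""] <- NA
  note(!is.na(chg) & chg < 0, "negative total_charges")
  note(raw$total_charges != "" & is.na(to_num(raw$total_charges)),
       "total_charges is not a number")

  to_bool <- function(x) {
    out <- rep(NA, length(x))
    out[x %in% c("TRUE", "true", "1")] <- TRUE
    out[x %in% c("FALSE", "false", "0")] <- FALSE
    out
  }
  died <- to_bool(raw$died)
  note(raw$died != "" & is.na(died), "died is not a boolean")
  for (col in c("elective", "urban", "teaching")) {
    v <- to_bool(raw[[col]])
    note(is.na(v), paste0(col, " is not a boolean"))
    raw[[col]] <- v
  }
  dict <- record_dictionary()
  for (col in c("sex", "race", "income_quartile", "bed_size")) {
    note(!(raw[[col]] %in% dict[[col]]$levels), paste0("unknown ", col))
  }

  if (length(problems)) {
    stop("malformed records:\n  ",
         paste(utils::head(problems, 20), collapse = "\n  "),
         if (length(problems) > 20) "\n  ...", call. = FALSE)
  }

  data.frame(record_id = raw$record_id, dx_codes = raw$dx_codes,
             proc_codes = raw$proc_codes, age_years = age, sex = raw$sex,
             race = raw$race, income_quartile = raw$income_quartile,
             elective = raw$elective, bed_size = raw$bed_size,
             urban = raw$urban, teaching = raw$teaching, died = died,
             los_days = los, total_charges = chg, stringsAsFactors = FALSE)
}

# TRUE when every code in a semicolon-delimited list matches `pattern` after
# normalization; empty lists are invalid for dx (a record always carries
# codes) but this is enforced by the regex on "".
validate_code_list <- function(code_lists, pattern) {
  vapply(split_codes(code_lists), function(cs) {
    length(cs) > 0L && all(grepl(pattern, cs))
  }, logical(1))
}
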