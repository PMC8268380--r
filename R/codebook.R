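#' @keywords internal
"_PACKAGE"

#' Complication and mediator name sets
#'
#' `COMPLICATIONS` lists the thirteen postoperative complication families, in
#' reporting order; `MEDIATORS` the five obesity-related complications that
#' mediate the exposure's effect on mortality, length of stay and charges.
#'
#' @format Character vectors.
#' @export
COMPLICATIONS <- c(
  "infection", "shock", "bleeding", "wound_disruption", "nonhealing_wound",
  "nervous", "cardiac", "phlebitis", "respiratory", "digestive",
  "urinary", "vascular", "unspecified"
)

#' @rdname COMPLICATIONS
#' @export
MEDIATORS <- c("infection", "shock", "bleeding", "wound_disruption", "digestive")

#' ICD-9-CM code book for cohort definition
#'
#' Builds the code book that maps raw ICD-9-CM diagnosis and ICD-9 procedure
#' codes onto the analytic concepts of the pipeline: colorectal cancer (CRC),
#' the other-primary-cancer exclusion range, metastasis (used as the CRC
#' severity marker), obesity, comorbidities, the qualifying surgical
#' procedures, and the thirteen postoperative complication families.
#'
#' Codes "match" a code-book entry by string prefix on the normalized
#' (dot-free) form, the usual claims-data convention: `"45.73"` normalizes to
#' `"4573"` and matches the colectomy root `"457"`.
#'
#' The other-cancer exclusion covers primary malignancy roots 140-239 with
#' three carve-outs: 153/154 (the CRC definition itself) and 196-199
#' (secondary malignant neoplasms, which encode metastatic spread of the CRC
#' and define the severity stratum rather than a second primary).
#'
#' @param overrides optional named list replacing individual entries, e.g.
#'   `list(obesity_dx = c("2780", "27801"))`.
#' @return An object of class `margpath_codebook`: a named list of character
#'   vectors of normalized code prefixes, plus the numeric exclusion range.
#' @examples
#' cb <- default_codebook()
#' cb$complication_dx$infection
#' @export
default_codebook <- function(overrides = NULL) {
  cb <- list(
    crc_dx = c("153", "154"),
    other_cancer_range = c(140L, 239L),
    other_cancer_carveout = c("153", "154", "196", "197", "198", "199"),
    metastasis_dx = c("196", "197", "198", "199"),
    obesity_dx = c("2780"),
    comorbidity_dx = list(
      diabetes = c("250"),
      liver_disease = c("571"),
      alcohol_abuse = c("303")
    ),
    surgery_proc = c(
      "457",                                  # open and subtotal colectomy
      "4840", "4841", "4843", "4849",         # pull-through rectal resection
      "4850", "4852", "4859",                 # abdominoperineal resection
      "486"                                   # other rectal resection
    ),
    complication_dx = list(
      infection        = c("9985"),
      shock            = c("9980"),
      bleeding         = c("9981"),
      wound_disruption = c("9983"),
      nonhealing_wound = c("99883"),
      nervous          = c("9970"),
      cardiac          = c("9971"),
      phlebitis        = c("9972"),
      respiratory      = c("9973"),
      digestive        = c("9974"),
      urinary          = c("9975"),
      vascular         = c("9977"),
      unspecified      = c("9989")
    )
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides), all(names(overrides) %in% names(cb)))
    cb[names(overrides)] <- overrides
  }
  class(cb) <- "margpath_codebook"
  validate_codebook(cb)
  cb
}

validate_codebook <- function(cb) {
  stopifnot(inherits(cb, "margpath_codebook"))
  excluded_roots <- setdiff(
    as.character(seq(cb$other_cancer_range[1], cb$other_cancer_range[2])),
    cb$other_cancer_carveout
  )
  comp_roots <- substr(unlist(cb$complication_dx), 1L, 3L)
  if (any(comp_roots %in% excluded_roots)) {
    stop("code book inconsistent: complication roots fall inside the ",
         "other-cancer exclusion range")
  }
  if (any(substr(cb$obesity_dx, 1L, 3L) %in% excluded_roots)) {
    stop("code book inconsistent: obesity codes fall inside the ",
         "other-cancer exclusion range")
  }
  invisible(cb)
}

#' Read or write a code book as YAML
#'
#' The YAML form is editable: any entry can be overridden and read back.
#'
#' @param cb a `margpath_codebook`.
#' @param path file path.
#' @return `read_codebook()` returns a validated `margpath_codebook`.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "margpath_codebook"))
  yaml::write_yaml(unclass(cb), path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$other_cancer_range <- as.integer(raw$other_cancer_range)
  cb <- default_codebook()
  cb[names(raw)] <- raw
  class(cb) <- "margpath_codebook"
  validate_codebook(cb)
  cb
}

# --- code matching helpers --------------------------------------------------

#' Normalize ICD-9 code strings
#'
#' Uppercases and strips dots and whitespace so codes can be compared by
#' prefix ("45.73" -> "4573").
#'
#' @param x character vector of codes.
#' @return normalized character vector.
#' @export
icd9_normalize <- function(x) {
  toupper(gsub("[.[:space:]]", "", as.character(x)))
}

# Regex matching any of the (normalized) prefixes at the start of a
# semicolon-delimited code list element.
prefix_pattern <- function(prefixes) {
  paste0("(^|;)(", paste(icd9_normalize(prefixes), collapse = "|"), ")")
}

# TRUE per element of `code_lists` (semicolon-delimited code strings) if any
# code starts with any prefix. Vectorized over records via a single regex.
codes_match <- function(code_lists, prefixes) {
  if (length(prefixes) == 0L) return(rep(FALSE, length(code_lists)))
  norm <- gsub("[.[:space:]]", "", toupper(code_lists))
  grepl(prefix_pattern(prefixes), norm)
}

# TRUE if any code has a 3-digit numeric root inside [range] excluding the
# carve-out roots.
codes_in_excluded_range <- function(code_lists, cb) {
  lo <- cb$other_cancer_range[1]
  hi <- cb$other_cancer_range[2]
  roots <- setdiff(as.character(seq(lo, hi)), cb$other_cancer_carveout)
  codes_match(code_lists, roots)
}

# Split semicolon-delimited code strings into a list of normalized codes.
split_codes <- function(code_lists) {
  strsplit(gsub("[.[:space:]]", "", toupper(code_lists)), ";", fixed = TRUE)
}
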