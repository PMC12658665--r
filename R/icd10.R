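# ICD-10 cause-category classification and encounter aggregation.

icd10_ranges <- function() {
  list(cardiovascular = c("I00", "I99"),
       injury = c("S00", "T88"),
       neuropsychiatric = c("F01", "F99"),
       respiratory = c("J00", "J99"))
}

#' Classify an ICD-10 code into cause categories
#'
#' Each valid code maps to `all_cause` plus every specific category whose
#' inclusive range contains the code's 3-character root (letter + two
#' digits), compared lexicographically so e.g. T50 falls inside the injury
#' range S00-T88. Subcodes after the period never change the category. The
#' specific ranges are cardiovascular I00-I99, injury S00-T88,
#' neuropsychiatric F01-F99 and respiratory J00-J99.
#'
#' @param codes Character vector of ICD-10 codes (`"J45.901"`, `"I21"`, ...).
#' @return A list (one element per code) of sorted category-name vectors.
#' @examples
#' classify_icd10(c("J45.901", "K35.80", "F01"))
#' @export
classify_icd10 <- function(codes) {
  ok <- grepl("^[A-Za-z][0-9]{2}(\\.[A-Za-z0-9]{1,4})?$", codes)
  if (any(!ok)) {
    stop("malformed ICD-10 code(s): ", paste(codes[!ok], collapse = ", "),
         call. = FALSE)
  }
  roots <- toupper(substr(codes, 1, 3))
  rng <- icd10_ranges()
  lapply(roots, function(r) {
    hits <- names(rng)[vapply(rng, function(b) r >= b[1] && r <= b[2], logical(1))]
    c("all_cause", sort(hits))
  })
}

#' Aggregate encounter records to the daily visit series
#'
#' Maps each encounter's tract to its exposure zone, classifies its ICD-10
#' codes, and counts encounters per date x zone x setting x cause over a
#' dense calendar grid with explicit zero rows, so downstream models see
#' every day. An encounter listing codes in several specific ranges
#' increments each matched cause once but `all_cause` exactly once.
#'
#' @param encounters Data frame with columns `date`, `tract_id`, `setting`
#'   (`"outpatient"`/`"virtual"`) and `icd10` (semicolon-separated codes).
#' @param zoning Output of [classify_tracts()]; every encounter tract must
#'   appear in it.
#' @param study_start,study_end Calendar bounds of the dense grid (defaults:
#'   encounter date range).
#' @return `VisitSeries` tibble (`date`, `zone`, `setting`, `cause`,
#'   `count`), complete over dates x zones x settings x the five causes.
#' @export
aggregate_encounters <- function(encounters, zoning,
                                 study_start = NULL, study_end = NULL) {
  encounters$date <- as.Date(encounters$date)
  unknown <- setdiff(unique(encounters$tract_id), zoning$tract_id)
  if (length(unknown) > 0) {
    stop("encounter tract(s) missing from zoning: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(encounters) > 0) {
    stopifnot(all(encounters$setting %in% setting_levels()))
  }
  study_start <- as.Date(study_start %||% min(encounters$date))
  study_end <- as.Date(study_end %||% max(encounters$date))
  zones <- sort(unique(zoning$zone))
  grid <- tidyr::expand_grid(date = seq(study_start, study_end, by = "day"),
                             zone = zones, setting = setting_levels(),
                             cause = cause_levels())
  if (nrow(encounters) == 0) {
    return(tibble::tibble(grid, count = 0L))
  }
  enc_zone <- zoning$zone[match(encounters$tract_id, zoning$tract_id)]
  cats <- lapply(strsplit(encounters$icd10, ";"), function(cs) {
    unique(unlist(classify_icd10(trimws(cs))))
  })
  long <- tibble::tibble(
    date = rep(encounters$date, lengths(cats)),
    zone = rep(enc_zone, lengths(cats)),
    setting = rep(encounters$setting, lengths(cats)),
    cause = unlist(cats)
  )
  counts <- dplyr::count(long, .data$date, .data$zone, .data$setting,
                         .data$cause, name = "count")
  out <- dplyr::left_join(grid, counts, by = c("date", "zone", "setting", "cause"))
  out$count <- as.integer(tidyr::replace_na(out$count, 0L))
  tibble::as_tibble(out)
}
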