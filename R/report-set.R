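#' The harmonized spontaneous-report model
#'
#' A `report_set` is a tibble with one row per (report, drug) pair plus a
#' provenance attribute recording lineage (source files, filters applied,
#' rows dropped). Columns:
#'
#' \describe{
#'   \item{report_id}{Opaque report identifier (unique per report within a
#'     database, but one report may span several drug rows before
#'     primary-suspect restriction).}
#'   \item{database}{One of [PV_DATABASES].}
#'   \item{age_years, weight_kg}{Numeric demographics; `NA` when missing.
#'     Ages are normalized to years at ingest.}
#'   \item{country}{ISO-like reporting-country string or `NA`.}
#'   \item{event_date}{`Date` or `NA`.}
#'   \item{drug_name}{Canonical drug name when the verbatim name matched
#'     the vocabulary, else the verbatim string.}
#'   \item{drug_verbatim, drug_mapped}{Verbatim name and whether it mapped.}
#'   \item{drug_role}{One of [PV_DRUG_ROLES].}
#'   \item{indication}{Free-text indication or `NA`.}
#'   \item{event_terms}{List-column of Preferred-Term character vectors,
#'     non-empty per row.}
#'   \item{serious}{Logical or `NA`.}
#'   \item{seriousness_criteria}{List-column, subsets of
#'     [PV_SERIOUSNESS_CRITERIA].}
#'   \item{outcome}{One of [PV_OUTCOMES] or `NA`.}
#'   \item{source_row}{Source row identifier used for deterministic
#'     tie-breaking during deduplication.}
#' }
#'
#' Cohort filtering ([apply_cohort_filters()]) adds a logical `ild_flag`
#' column.
#'
#' @param reports A data frame with the columns above.
#' @param provenance Character vector of lineage lines.
#' @param validate Run invariant checks (default `TRUE`).
#' @return An object of classes `report_set` and `tbl_df`.
#' @export
report_set <- function(reports, provenance = character(0), validate = TRUE) {
  reports <- tibble::as_tibble(reports)
  out <- structure(reports,
                   class = c("report_set", class(tibble::tibble())),
                   provenance = provenance)
  if (validate) validate_report_set(out)
  out
}

report_set_columns <- function() {
  c("report_id", "database", "age_years", "weight_kg", "country",
    "event_date", "drug_name", "drug_verbatim", "drug_mapped", "drug_role",
    "indication", "event_terms", "serious", "seriousness_criteria",
    "outcome", "source_row")
}

#' Validate report-set invariants
#'
#' Checks column presence, closed vocabularies, demographic ranges
#' (age in \[0, 130\] years, weight in (0, 500\] kg), non-empty event-term
#' sets, and that non-empty seriousness criteria imply `serious = TRUE`.
#'
#' @param x A [report_set()].
#' @return `x`, invisibly; errors on violation.
#' @export
validate_report_set <- function(x) {
  missing_cols <- setdiff(report_set_columns(), names(x))
  assert_that(length(missing_cols) == 0,
              paste0("report_set lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  if (nrow(x) == 0) return(invisible(x))
  assert_that(all(x$database %in% PV_DATABASES), "unknown database value")
  assert_that(all(x$drug_role %in% PV_DRUG_ROLES), "unknown drug_role value")
  assert_that(all(is.na(x$outcome) | x$outcome %in% PV_OUTCOMES),
              "unknown outcome value")
  age <- x$age_years[!is.na(x$age_years)]
  assert_that(all(age >= 0 & age <= 130), "age_years outside [0, 130]")
  wt <- x$weight_kg[!is.na(x$weight_kg)]
  assert_that(all(wt > 0 & wt <= 500), "weight_kg outside (0, 500]")
  assert_that(all(lengths(x$event_terms) > 0),
              "every report must carry at least one event term")
  crit_n <- lengths(x$seriousness_criteria)
  bad_crit <- unlist(x$seriousness_criteria, use.names = FALSE)
  assert_that(all(bad_crit %in% PV_SERIOUSNESS_CRITERIA),
              "unknown seriousness criterion")
  assert_that(all(crit_n == 0 | (!is.na(x$serious) & x$serious)),
              "non-empty seriousness_criteria require serious = TRUE")
  invisible(x)
}

#' @export
print.report_set <- function(x, ...) {
  cat("<report_set> ", nrow(x), " report rows across ",
      length(unique(x$database)), " database(s)\n", sep = "")
  if ("ild_flag" %in% names(x)) {
    cat("  event-of-interest flagged:", sum(x$ild_flag), "\n")
  }
  prov <- provenance(x)
  if (length(prov)) cat("  provenance:", length(prov), "line(s)\n")
  NextMethod()
}

#' Provenance lineage of a report set
#' @param x A [report_set()].
#' @return Character vector of lineage lines.
#' @export
provenance <- function(x) attr(x, "provenance") %||% character(0)

add_provenance <- function(x, ...) {
  attr(x, "provenance") <- c(provenance(x), paste0(...))
  x
}

# Keep report_set class + provenance through dplyr-style subsetting.
#' @export
`[.report_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    structure(out, class = c("report_set", class(tibble::tibble())),
              provenance = provenance(x))
  } else {
    out
  }
}

# Completeness score used by the deduplication rules: the count of
# non-missing fields among the seven demographic/clinical fields.
completeness_score <- function(x) {
  fields <- c("age_years", "weight_kg", "country", "event_date",
              "serious", "outcome", "indication")
  rowSums(!is.na(as.data.frame(x[fields])))
}
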