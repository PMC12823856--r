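#' Apply the cohort-construction filters
#'
#' Restricts a report set to primary-suspect drug rows whose indication
#' matches the cohort (case-insensitive substring match against
#' `indication_terms`), then flags each retained report with
#' `ild_flag = TRUE` when any of its event terms belongs to the supplied
#' SMQ. Reports with a missing or non-matching indication are excluded and
#' counted; reports left with more than one distinct primary-suspect drug
#' are excluded entirely (and counted) so each report contributes to
#' exactly one drug's contingency cell.
#'
#' Filters only select and annotate: no surviving field value is altered.
#'
#' @param reports A [report_set()].
#' @param indication_terms Non-empty character vector of substring
#'   patterns; see [default_indication_terms()].
#' @param smq An [smq_definition()] defining the event class of interest.
#' @return A [report_set()] with an added logical `ild_flag` column.
#' @export
apply_cohort_filters <- function(reports,
                                 indication_terms = default_indication_terms(),
                                 smq = default_ild_smq()) {
  assert_that(length(indication_terms) > 0, "indication_terms must be non-empty")
  assert_that(inherits(smq, "smq_definition") && length(smq$term_keys) > 0,
              "smq must be a non-empty smq_definition")
  n_in <- nrow(reports)
  x <- reports[reports$drug_role == "PRIMARY_SUSPECT", ]
  n_ps <- nrow(x)

  ind <- normalize_term(x$indication)
  pats <- normalize_term(indication_terms)
  hit <- rep(FALSE, nrow(x))
  for (p in pats) hit <- hit | grepl(p, ind, fixed = TRUE)
  hit[is.na(x$indication)] <- FALSE
  x <- x[hit, ]
  n_ind <- nrow(x)

  # attribute each report to one drug: drop reports spanning multiple
  # distinct primary-suspect drugs (avoids double-counting cell a)
  key <- paste(x$database, x$report_id, sep = "\r")
  multi <- character(0)
  if (anyDuplicated(key)) {
    ndrug <- tapply(x$drug_name, key, function(d) length(unique(d)))
    multi <- names(ndrug)[ndrug > 1]
    x <- x[!key %in% multi, ]
  }

  nt <- lengths(x$event_terms)
  if (all(nt == 1)) {
    # fast path: single-term reports (the generator default)
    x$ild_flag <- normalize_term(unlist(x$event_terms, use.names = FALSE)) %in%
      smq$term_keys
  } else {
    x$ild_flag <- vapply(x$event_terms,
                         function(tt) any(normalize_term(tt) %in% smq$term_keys),
                         logical(1))
  }
  x <- add_provenance(
    x,
    "apply_cohort_filters: ", n_in, " rows in; ",
    n_in - n_ps, " non-primary-suspect rows excluded; ",
    n_ps - n_ind, " missing/unmatched-indication rows excluded; ",
    length(multi), " report(s) with multiple primary-suspect drugs excluded; ",
    nrow(x), " rows retained (", sum(x$ild_flag), " event-of-interest flagged)")
  x
}

#' Deduplicate reports within or across databases
#'
#' `WITHIN_DATABASE`: rows sharing `(database, report_id)` are duplicate
#' submissions of one case; the most complete row survives, completeness
#' being the count of non-missing fields among age, weight, country,
#' event date, serious, outcome and indication. Ties go to the latest
#' event date, remaining ties to the lexicographically last `source_row`.
#'
#' `CROSS_DATABASE`: rows agreeing exactly on (age rounded to whole years,
#' canonical drug name, event date, country) — with all four fields
#' non-missing — are treated as the same case reported to several
#' databases. Only groups spanning more than one database are collapsed;
#' the FAERS-like record is retained (falling back to CVAR-like over
#' JADER-like, then the most complete row). Rows with any missing key
#' field are never merged.
#'
#' Output preserves the input order of survivors; removals are recorded in
#' the provenance. The operation is idempotent.
#'
#' @param reports A [report_set()].
#' @param scope `"WITHIN_DATABASE"` or `"CROSS_DATABASE"`.
#' @return A [report_set()] of surviving rows.
#' @export
deduplicate <- function(reports, scope = c("WITHIN_DATABASE", "CROSS_DATABASE")) {
  scope <- match.arg(scope)
  n_in <- nrow(reports)
  if (n_in == 0) {
    return(add_provenance(reports, "deduplicate[", scope, "]: empty input"))
  }
  x <- reports

  if (scope == "WITHIN_DATABASE") {
    key <- paste(x$database, x$report_id, sep = "\r")
    keep <- survivor_by_completeness(x, key)
  } else {
    complete_key <- !is.na(x$age_years) & !is.na(x$drug_name) &
      !is.na(x$event_date) & !is.na(x$country)
    key <- rep(NA_character_, nrow(x))
    key[complete_key] <- paste(round(x$age_years[complete_key]),
                               x$drug_name[complete_key],
                               format(x$event_date[complete_key], "%Y-%m-%d"),
                               x$country[complete_key], sep = "\r")
    keep <- rep(TRUE, nrow(x))
    spanning <- tapply(x$database, key, function(db) length(unique(db)) > 1)
    groups <- names(spanning)[spanning]
    if (length(groups)) {
      db_rank <- match(x$database, PV_DATABASES)  # FAERS < CVAR < JADER
      comp <- completeness_score(x)
      for (g in groups) {
        idx <- which(!is.na(key) & key == g)
        ord <- order(db_rank[idx], -comp[idx], x$source_row[idx])
        keep[idx[-ord[1]]] <- FALSE
      }
    }
  }

  out <- x[keep, ]
  add_provenance(out, "deduplicate[", scope, "]: ", n_in, " rows in, ",
                 sum(!keep), " duplicate row(s) removed, ", nrow(out),
                 " retained")
}

# Pick one survivor per key: most complete, then latest event_date (missing
# dates sort earliest), then lexicographically last source_row.
survivor_by_completeness <- function(x, key) {
  comp <- completeness_score(x)
  date_num <- as.numeric(x$event_date)
  date_num[is.na(date_num)] <- -Inf
  n <- nrow(x)
  keep <- rep(TRUE, n)
  dup_groups <- unique(key[duplicated(key)])
  for (g in dup_groups) {
    idx <- which(key == g)
    ord <- order(-comp[idx], -date_num[idx], -xtfrm(x$source_row[idx]))
    keep[idx[-ord[1]]] <- FALSE
  }
  keep
}
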