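#' 2x2 contingency table for one drug in one report universe
#'
#' Cell conventions follow the standard disproportionality layout:
#' `a` = reports of the drug of interest with the event of interest,
#' `b` = other drugs with the event, `c` = the drug with other events,
#' `d` = other drugs with other events.
#'
#' @param a,b,c,d Non-negative integer cell counts with `a+b+c+d > 0`.
#' @param drug Canonical drug name.
#' @param universe_label Label of the report universe (e.g. `"FAERS_LIKE"`,
#'   `"COMBINED"`, `"AGE_GE_65"`).
#' @return An object of class `contingency_table`.
#' @export
contingency_table <- function(a, b, c, d, drug = NA_character_,
                              universe_label = NA_character_) {
  # doubles, not integers: cell products in the chi-square denominator
  # overflow 32-bit integer range at realistic database sizes
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  cells <- c(a = a, b = b, c = c, d = d)
  assert_that(all(is.finite(cells)) && all(cells >= 0),
              "all cells must be finite and non-negative")
  assert_that(sum(cells) > 0, "table total must be positive")
  structure(list(a = a, b = b, c = c, d = d, n = a + b + c + d,
                 drug = drug, universe_label = universe_label),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table> ", x$drug, " in ", x$universe_label, "\n", sep = "")
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("drug", "other drugs"),
                              c("event", "other events")))
  print(m)
  invisible(x)
}

#' Build the 2x2 contingency table for one drug
#'
#' Counts are taken over a cohort-filtered, deduplicated report set in
#' which every row carries an `ild_flag` and one attributed drug. A drug
#' absent from every report yields `a = c = 0` (no error; downstream
#' statistics are flagged undefined).
#'
#' @param reports A [report_set()] with an `ild_flag` column.
#' @param drug Canonical drug name of interest.
#' @param universe_label Label recorded on the table (defaults to the
#'   database if unique, else `"COMBINED"`).
#' @return A [contingency_table()].
#' @export
build_contingency <- function(reports, drug, universe_label = NULL) {
  assert_that("ild_flag" %in% names(reports),
              "reports must be cohort-filtered first (missing ild_flag)")
  assert_that(nrow(reports) > 0, "cannot build a contingency table from an empty report set")
  if (is.null(universe_label)) {
    dbs <- unique(reports$database)
    universe_label <- if (length(dbs) == 1) dbs else "COMBINED"
  }
  is_drug <- reports$drug_name == drug
  ev <- reports$ild_flag
  contingency_table(a = sum(is_drug & ev), b = sum(!is_drug & ev),
                    c = sum(is_drug & !ev), d = sum(!is_drug & !ev),
                    drug = drug, universe_label = universe_label)
}

#' Disproportionality statistics for a 2x2 table
#'
#' Computes the proportional reporting ratio (PRR), reporting odds ratio
#' (ROR), Pearson and Yates-corrected chi-square, and the Bayesian
#' information component (IC) with its IC025 lower credibility bound:
#'
#' * `PRR = (a/(a+c)) / (b/(b+d))`, 95% CI
#'   `exp(ln PRR +/- 1.96 * sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d)))`
#' * `ROR = ad/bc`, 95% CI
#'   `exp(ln ROR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`
#' * `IC = log2((a + 0.5) / (a_exp + 0.5))` with
#'   `a_exp = (a+b)(a+c)/N`, and
#'   `IC025 = IC - 3.3 (a+0.5)^(-1/2) - 2 (a+0.5)^(-3/2)`
#'
#' Point estimates and CIs require all four cells to be at least 1; with
#' any zero cell they are returned as `NA` and the estimate is flagged
#' undefined (no pseudo-count correction is applied). The chi-square and
#' IC statistics, which are defined for zero cells, are always computed.
#' Values are kept at full precision; use [format_signal_table()] for the
#' conventional 2-decimal display.
#'
#' @param table A [contingency_table()].
#' @param continuity_correction If `TRUE`, `chi2` reports the
#'   Yates-corrected statistic; the default reports the Pearson statistic.
#'   Both are always available as `chi2_pearson` / `chi2_yates`.
#' @return An object of class `signal_estimates`: a list with elements
#'   `prr`, `prr_ci95`, `ror`, `ror_ci95`, `chi2`, `chi2_pearson`,
#'   `chi2_yates`, `ic`, `a_exp`, `ic025`, `n_cases` (= `a`), `defined`,
#'   `drug`, `universe_label`.
#' @export
compute_signal_estimates <- function(table, continuity_correction = FALSE) {
  stopifnot(inherits(table, "contingency_table"))
  a <- table$a; b <- table$b; cc <- table$c; d <- table$d
  n <- table$n
  defined <- all(c(a, b, cc, d) >= 1)
  z <- 1.96

  if (defined) {
    prr <- (a / (a + cc)) / (b / (b + d))
    se_prr <- sqrt(1 / a - 1 / (a + cc) + 1 / b - 1 / (b + d))
    prr_ci <- exp(log(prr) + c(-1, 1) * z * se_prr)
    ror <- (a * d) / (b * cc)
    se_ror <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
    ror_ci <- exp(log(ror) + c(-1, 1) * z * se_ror)
  } else {
    prr <- NA_real_; prr_ci <- c(NA_real_, NA_real_)
    ror <- NA_real_; ror_ci <- c(NA_real_, NA_real_)
  }

  denom <- (a + b) * (cc + d) * (a + cc) * (b + d)
  chi2_pearson <- n * (a * d - b * cc)^2 / denom
  chi2_yates <- n * max(abs(a * d - b * cc) - n / 2, 0)^2 / denom
  a_exp <- (a + b) * (a + cc) / n
  ic <- log2((a + 0.5) / (a_exp + 0.5))
  ic025 <- ic - 3.3 * (a + 0.5)^(-1 / 2) - 2 * (a + 0.5)^(-3 / 2)

  structure(
    list(prr = prr, prr_ci95 = prr_ci, ror = ror, ror_ci95 = ror_ci,
         chi2 = if (continuity_correction) chi2_yates else chi2_pearson,
         chi2_pearson = chi2_pearson, chi2_yates = chi2_yates,
         ic = ic, a_exp = a_exp, ic025 = ic025, n_cases = a,
         defined = defined, drug = table$drug,
         universe_label = table$universe_label),
    class = "signal_estimates")
}

#' @export
print.signal_estimates <- function(x, ...) {
  f <- function(v) formatC(round_half_up(v, 2), format = "f", digits = 2)
  cat("<signal_estimates> ", x$drug, " in ", x$universe_label,
      " (a = ", x$n_cases, ")\n", sep = "")
  if (x$defined) {
    cat("  PRR ", f(x$prr), " (", f(x$prr_ci95[1]), ", ", f(x$prr_ci95[2]),
        ")  ROR ", f(x$ror), " (", f(x$ror_ci95[1]), ", ", f(x$ror_ci95[2]),
        ")\n", sep = "")
  } else {
    cat("  PRR/ROR undefined (zero cell)\n")
  }
  cat("  chi2 ", f(x$chi2_pearson), " (Yates ", f(x$chi2_yates), ")  IC ",
      f(x$ic), "  IC025 ", f(x$ic025), "\n", sep = "")
  invisible(x)
}

#' Three-criterion disproportionality signal rule
#'
#' Criterion 1: at least 3 cases, PRR >= 2 and chi-square >= 4.
#' Criterion 2: lower 95% CI bound of the ROR above 1.
#' Criterion 3: IC025 above 0.
#' Undefined estimates make their criterion `FALSE`. Under `rule = "ANY"`
#' (the default signal definition) a signal is inferred when any criterion
#' holds; `"ALL"` requires all three.
#'
#' Criterion 1 uses the chi-square selected at estimation time
#' (`est$chi2`, Pearson unless the continuity correction was requested).
#'
#' @param est A [compute_signal_estimates()] result.
#' @param rule `"ANY"` or `"ALL"`.
#' @return An object of class `signal_verdict`: list with `criterion1`,
#'   `criterion2`, `criterion3`, `signal`, `rule`.
#' @export
evaluate_signal <- function(est, rule = c("ANY", "ALL")) {
  stopifnot(inherits(est, "signal_estimates"))
  rule <- match.arg(rule)
  c1 <- isTRUE(est$n_cases >= 3 && !is.na(est$prr) && est$prr >= 2 &&
                 est$chi2 >= 4)
  c2 <- isTRUE(!is.na(est$ror_ci95[1]) && est$ror_ci95[1] > 1)
  c3 <- isTRUE(!is.na(est$ic025) && est$n_cases > 0 && est$ic025 > 0)
  signal <- if (rule == "ANY") c1 || c2 || c3 else c1 && c2 && c3
  structure(list(criterion1 = c1, criterion2 = c2, criterion3 = c3,
                 signal = signal, rule = rule, drug = est$drug,
                 universe_label = est$universe_label),
            class = "signal_verdict")
}

#' @export
print.signal_verdict <- function(x, ...) {
  cat("<signal_verdict> ", x$drug, " in ", x$universe_label, ": ",
      if (x$signal) "SIGNAL" else "no signal", " (rule ", x$rule,
      "; c1=", x$criterion1, " c2=", x$criterion2, " c3=", x$criterion3,
      ")\n", sep = "")
  invisible(x)
}

#' Full signal table for one report universe
#'
#' Builds the contingency table and computes estimates plus verdict for
#' each drug, returning one tidy row per drug in the layout used for
#' per-universe signal exports.
#'
#' @param reports A cohort-filtered, deduplicated [report_set()] carrying
#'   `ild_flag`.
#' @param drugs Character vector of canonical drugs to tabulate; defaults
#'   to the built-in vocabulary.
#' @param universe_label Universe label (see [build_contingency()]).
#' @param rule Signal rule passed to [evaluate_signal()].
#' @param continuity_correction Passed to [compute_signal_estimates()].
#' @return A tibble with columns `universe`, `drug`, `a`, `b`, `c`, `d`,
#'   `prr`, `prr_ci_low`, `prr_ci_high`, `ror`, `ror_ci_low`,
#'   `ror_ci_high`, `chi2`, `chi2_yates`, `ic`, `ic025`, `criterion1`,
#'   `criterion2`, `criterion3`, `signal`.
#' @export
signal_table <- function(reports, drugs = vocabulary_drugs(default_drug_vocabulary()),
                         universe_label = NULL, rule = "ANY",
                         continuity_correction = FALSE) {
  if (nrow(reports) == 0) return(empty_signal_table())
  rows <- lapply(drugs, function(dr) {
    tab <- build_contingency(reports, dr, universe_label)
    est <- compute_signal_estimates(tab, continuity_correction)
    ver <- evaluate_signal(est, rule)
    tibble::tibble(
      universe = tab$universe_label, drug = dr,
      a = tab$a, b = tab$b, c = tab$c, d = tab$d,
      prr = est$prr, prr_ci_low = est$prr_ci95[1],
      prr_ci_high = est$prr_ci95[2],
      ror = est$ror, ror_ci_low = est$ror_ci95[1],
      ror_ci_high = est$ror_ci95[2],
      chi2 = est$chi2_pearson, chi2_yates = est$chi2_yates,
      ic = est$ic, ic025 = est$ic025,
      criterion1 = ver$criterion1, criterion2 = ver$criterion2,
      criterion3 = ver$criterion3, signal = ver$signal)
  })
  dplyr::bind_rows(rows)
}

empty_signal_table <- function() {
  tibble::tibble(universe = character(0), drug = character(0),
                 a = integer(0), b = integer(0), c = integer(0),
                 d = integer(0), prr = numeric(0), prr_ci_low = numeric(0),
                 prr_ci_high = numeric(0), ror = numeric(0),
                 ror_ci_low = numeric(0), ror_ci_high = numeric(0),
                 chi2 = numeric(0), chi2_yates = numeric(0), ic = numeric(0),
                 ic025 = numeric(0), criterion1 = logical(0),
                 criterion2 = logical(0), criterion3 = logical(0),
                 signal = logical(0))
}

#' Display-round a signal table
#'
#' Rounds all statistic columns to 2 decimals, half away from zero,
#' matching the conventional display of disproportionality tables.
#'
#' @param tab A [signal_table()] result.
#' @return The tibble with rounded statistic columns.
#' @export
format_signal_table <- function(tab) {
  stat_cols <- c("prr", "prr_ci_low", "prr_ci_high", "ror", "ror_ci_low",
                 "ror_ci_high", "chi2", "chi2_yates", "ic", "ic025")
  dplyr::mutate(tab, dplyr::across(dplyr::all_of(stat_cols),
                                   ~round_half_up(.x, 2)))
}

#' Age-stratified (or custom-stratified) signal tables
#'
#' Splits reports into strata, rebuilds every drug's contingency table
#' within each stratum's universe, and recomputes estimates and verdicts.
#' Reports for which the stratifier returns `NA` are excluded from all
#' strata and counted.
#'
#' @param reports A cohort-filtered, deduplicated [report_set()].
#' @param stratifier Function mapping the report tibble to a character
#'   vector of stratum labels (`NA` = excluded). Defaults to
#'   [age_stratifier()] at 65 years.
#' @param drugs,rule,continuity_correction Passed to [signal_table()].
#' @return A list with `strata` (named list of signal tibbles),
#'   `excluded` (count of reports without the stratifying field), and
#'   `labels`.
#' @export
stratified_signals <- function(reports, stratifier = age_stratifier(65),
                               drugs = vocabulary_drugs(default_drug_vocabulary()),
                               rule = "ANY", continuity_correction = FALSE) {
  labels <- stratifier(reports)
  assert_that(length(labels) == nrow(reports),
              "stratifier must return one label per report")
  excluded <- sum(is.na(labels))
  strata <- list()
  for (lv in sort(unique(labels[!is.na(labels)]))) {
    sub <- reports[!is.na(labels) & labels == lv, ]
    strata[[lv]] <- signal_table(sub, drugs, universe_label = lv,
                                 rule = rule,
                                 continuity_correction = continuity_correction)
  }
  list(strata = strata, excluded = excluded, labels = names(strata))
}

#' Age-threshold stratifier
#'
#' Returns a stratifier assigning reports with known age to
#' `AGE_GE_<t>` / `AGE_LT_<t>` (the boundary age goes to the upper
#' stratum) and `NA` where age is missing.
#'
#' @param threshold Age threshold in years (default 65).
#' @return A function usable as the `stratifier` of [stratified_signals()].
#' @export
age_stratifier <- function(threshold = 65) {
  force(threshold)
  function(reports) {
    ifelse(is.na(reports$age_years), NA_character_,
           ifelse(reports$age_years >= threshold,
                  paste0("AGE_GE_", threshold), paste0("AGE_LT_", threshold)))
  }
}
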