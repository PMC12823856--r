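#' Configuration for the synthetic multi-database report generator
#'
#' The generator emulates the statistical structure the disproportionality
#' analysis assumes: each report independently samples a primary-suspect
#' drug, an event-of-interest flag conditional on the drug, demographics,
#' an indication and an outcome, with configurable field missingness and
#' injected duplicate reports within and across databases.
#'
#' @param seed Integer seed; the generator is deterministic given it.
#' @param per_database Named list (names from [PV_DATABASES]) of
#'   per-database settings, each built by [synthetic_db_config()].
#' @return An object of class `synthetic_config` (validated).
#' @seealso [generate_reports()], [expected_ror()],
#'   [default_synthetic_config()]
#' @export
synthetic_config <- function(seed, per_database) {
  cfg <- structure(list(seed = as.integer(seed), per_database = per_database),
                   class = "synthetic_config")
  validate_synthetic_config(cfg)
  cfg
}

#' @param n_reports Number of base reports to emit.
#' @param drug_weights Named probability map over canonical study drugs;
#'   together with `background_weight` it must sum to 1.
#' @param ild_prob Named map drug -> probability that a report of that
#'   drug carries an event-of-interest term; drugs absent from the map
#'   fall back to `baseline_ild_prob`.
#' @param baseline_ild_prob Event probability for non-study (background)
#'   drugs and for unmapped study drugs.
#' @param background_weight Probability mass given to a pool of non-study
#'   drugs (reported verbatim, unmapped by the default vocabulary).
#' @param indication_mix Named probability map over indication strings
#'   (eligible and ineligible); must sum to 1.
#' @param missingness Named map field -> probability the field is blanked
#'   (fields: `age_years`, `weight_kg`, `country`, `event_date`,
#'   `serious`, `outcome`, `indication`).
#' @param dup_within_rate Fraction of base reports re-emitted as degraded
#'   same-`report_id` duplicate submissions.
#' @param dup_cross_rate Fraction of FAERS-like base reports re-emitted
#'   into another database under a fresh `report_id` (same age, drug,
#'   event date and country); only meaningful on the FAERS-like entry.
#' @param death_prob_given_ild Named map drug -> probability that an
#'   event-of-interest report has a fatal outcome (used when the drug has
#'   no severity shift; default is the `outcome_mix` death share).
#' @param outcome_mix Named probability map over [PV_OUTCOMES]; must sum
#'   to 1.
#' @param severity_shift Named map drug -> proportional-odds log-OR
#'   tilting the ordered outcome distribution of the drug's
#'   event-of-interest reports toward (positive) or away from (negative)
#'   severe categories.
#' @param role_primary_prob Probability a report row is PRIMARY_SUSPECT
#'   (else CONCOMITANT), exercising the role filter.
#' @param multi_pt_rate Fraction of reports carrying 1-2 extra non-query
#'   event terms (default 0: one term per report).
#' @rdname synthetic_config
#' @export
synthetic_db_config <- function(n_reports,
                                drug_weights,
                                ild_prob = NULL,
                                baseline_ild_prob = 0.02,
                                background_weight = 0,
                                indication_mix = default_indication_mix(),
                                missingness = default_missingness(),
                                dup_within_rate = 0,
                                dup_cross_rate = 0,
                                death_prob_given_ild = NULL,
                                outcome_mix = default_outcome_mix(),
                                severity_shift = NULL,
                                role_primary_prob = 0.9,
                                multi_pt_rate = 0) {
  list(n_reports = n_reports, drug_weights = drug_weights,
       ild_prob = ild_prob %||% setNames(numeric(0), character(0)),
       baseline_ild_prob = baseline_ild_prob,
       background_weight = background_weight,
       indication_mix = indication_mix, missingness = missingness,
       dup_within_rate = dup_within_rate, dup_cross_rate = dup_cross_rate,
       death_prob_given_ild = death_prob_given_ild %||% setNames(numeric(0), character(0)),
       outcome_mix = outcome_mix,
       severity_shift = severity_shift %||% setNames(numeric(0), character(0)),
       role_primary_prob = role_primary_prob, multi_pt_rate = multi_pt_rate)
}

#' @rdname synthetic_config
#' @export
default_indication_mix <- function() {
  c("Ovarian cancer" = 0.70, "Ovarian cancer recurrent" = 0.06,
    "Fallopian tube cancer" = 0.05, "Primary peritoneal cancer" = 0.05,
    "Breast cancer" = 0.09, "Prostate cancer" = 0.05)
}

#' @rdname synthetic_config
#' @export
default_outcome_mix <- function() {
  c(RECOVERED = 0.40, RECOVERING = 0.22, NOT_RECOVERED = 0.15,
    RECOVERED_WITH_SEQUELAE = 0.02, DEATH = 0.11, UNKNOWN = 0.10)
}

#' @rdname synthetic_config
#' @export
default_missingness <- function() {
  c(age_years = 0.35, weight_kg = 0.60, country = 0.05, event_date = 0.10,
    serious = 0.10, outcome = 0.25, indication = 0.03)
}

#' Default generator configuration
#'
#' Emulates the three-database study design at a workable scale: database
#' sizes proportional to the real extracts (FAERS-like largest, roughly
#' 15:2:1), drug-conditional event probabilities chosen so the implied
#' reporting odds ratios span the observed range (clear positive signals
#' for the ADC and one PARP inhibitor, null and protective associations
#' elsewhere), FAERS-like field missingness, and small duplicate-injection
#' rates.
#'
#' @param seed Integer seed.
#' @param scale Multiplier on the default database sizes
#'   (30,000 / 4,000 / 2,000 at `scale = 1`).
#' @return A [synthetic_config()].
#' @export
default_synthetic_config <- function(seed = 20260101, scale = 1) {
  drugs <- vocabulary_drugs(default_drug_vocabulary())
  w <- setNames(rep(1 / 13, 13), drugs)
  ild <- c("olaparib" = 0.060, "niraparib tosylate monohydrate" = 0.006,
           "rucaparib camsylate" = 0.005, "bevacizumab" = 0.020,
           "mirvetuximab soravtansine-gynx" = 0.070,
           "carboplatin" = 0.020, "cisplatin" = 0.035,
           "cyclophosphamide" = 0.030, "gemcitabine hydrochloride" = 0.045,
           "doxorubicin hydrochloride" = 0.060,
           "doxorubicin hydrochloride liposome" = 0.030,
           "topotecan hydrochloride" = 0.010, "paclitaxel" = 0.022)
  shift <- setNames(rep(0, 13), drugs)
  shift["mirvetuximab soravtansine-gynx"] <- 1.2
  db <- function(n, dup_w, dup_x) {
    synthetic_db_config(n_reports = n, drug_weights = w, ild_prob = ild,
                        baseline_ild_prob = 0.02,
                        dup_within_rate = dup_w, dup_cross_rate = dup_x,
                        severity_shift = shift)
  }
  synthetic_config(seed, list(
    FAERS_LIKE = db(round(30000 * scale), 0.01, 0.01),
    CVAR_LIKE  = db(round(4000 * scale), 0.01, 0),
    JADER_LIKE = db(round(2000 * scale), 0.01, 0)))
}

check_prob_map <- function(x, what, sum_to_one = FALSE) {
  assert_that(all(is.finite(x)) && all(x >= 0 & x <= 1),
              paste0(what, " must lie in [0, 1]"))
  if (sum_to_one) {
    assert_that(abs(sum(x) - 1) <= 1e-9, paste0(what, " must sum to 1"))
  }
}

#' @rdname synthetic_config
#' @param cfg A `synthetic_config`.
#' @export
validate_synthetic_config <- function(cfg) {
  assert_that(is.list(cfg$per_database) && length(cfg$per_database) > 0 &&
                all(names(cfg$per_database) %in% PV_DATABASES),
              "per_database must be named by database dialect")
  for (dbn in names(cfg$per_database)) {
    d <- cfg$per_database[[dbn]]
    assert_that(is.numeric(d$n_reports) && d$n_reports >= 0,
                paste0(dbn, ": n_reports must be non-negative"))
    check_prob_map(c(d$drug_weights, background = d$background_weight),
                   paste0(dbn, ": drug_weights + background_weight"),
                   sum_to_one = TRUE)
    check_prob_map(d$ild_prob, paste0(dbn, ": ild_prob"))
    check_prob_map(d$baseline_ild_prob, paste0(dbn, ": baseline_ild_prob"))
    check_prob_map(d$indication_mix, paste0(dbn, ": indication_mix"),
                   sum_to_one = TRUE)
    check_prob_map(d$outcome_mix, paste0(dbn, ": outcome_mix"),
                   sum_to_one = TRUE)
    assert_that(all(names(d$outcome_mix) %in% PV_OUTCOMES),
                paste0(dbn, ": unknown outcome in outcome_mix"))
    check_prob_map(d$missingness, paste0(dbn, ": missingness"))
    check_prob_map(d$dup_within_rate, paste0(dbn, ": dup_within_rate"))
    check_prob_map(d$dup_cross_rate, paste0(dbn, ": dup_cross_rate"))
    check_prob_map(d$death_prob_given_ild,
                   paste0(dbn, ": death_prob_given_ild"))
    check_prob_map(d$role_primary_prob, paste0(dbn, ": role_primary_prob"))
    assert_that(all(names(d$ild_prob) %in% names(d$drug_weights)),
                paste0(dbn, ": ild_prob names must be drugs in drug_weights"))
  }
  invisible(cfg)
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> seed ", x$seed, "\n", sep = "")
  for (dbn in names(x$per_database)) {
    d <- x$per_database[[dbn]]
    cat("  ", dbn, ": n = ", d$n_reports, ", ",
        length(d$drug_weights), " drugs, dup rates ",
        d$dup_within_rate, "/", d$dup_cross_rate, "\n", sep = "")
  }
  invisible(x)
}

background_drug_pool <- function() {
  c("letrozole", "anastrozole", "tamoxifen", "exemestane", "megestrol acetate")
}

background_pt_pool <- function() {
  c("Nausea", "Anaemia", "Fatigue", "Thrombocytopenia", "Neutropenia",
    "Vomiting", "Diarrhoea", "Abdominal pain", "Pyrexia", "Headache",
    "Decreased appetite", "Platelet count decreased")
}

# Proportional-odds exponential tilt of an ordered probability vector:
# logit F'_k = logit F_k - shift, so positive shifts move mass toward the
# severe (later) categories.
tilt_severity <- function(p, shift) {
  if (shift == 0) return(p)
  Fk <- cumsum(p)
  Fk <- Fk[-length(Fk)]
  Ft <- plogis(stats::qlogis(pmin(pmax(Fk, 1e-12), 1 - 1e-12)) - shift)
  diff(c(0, Ft, 1))
}

ild_prob_for <- function(d, drugs) {
  p <- d$ild_prob[drugs]
  p[is.na(p)] <- d$baseline_ild_prob
  unname(p)
}

#' Generate synthetic multi-database spontaneous reports
#'
#' Draws reports per database under the configured mixture (drug, then
#' event flag conditional on drug, then event term, demographics,
#' indication and outcome, then field missingness), injects within- and
#' cross-database duplicates, and returns the reports together with a
#' ground-truth ledger: expected contingency cells and true reporting
#' odds ratios per drug and universe, the injected duplicate pairs, and
#' the configured severity log-odds shifts. Deterministic given
#' `config$seed`; when `dir` is given the reports are also written as
#' dialect files readable by [read_reports()], with the seed recorded in
#' the provenance.
#'
#' @param config A [synthetic_config()].
#' @param dir Optional output directory for dialect files.
#' @param smq [smq_definition()] supplying event-of-interest terms.
#' @param indication_terms Eligible indication patterns (used only to
#'   compute ground-truth expectations; generation itself draws from the
#'   configured `indication_mix`).
#' @return List with `reports` (named list of [report_set()]s), `files`
#'   (named list of path vectors, or `NULL`), and `ground_truth` (list:
#'   `expected_cells`, `true_ror`, `duplicates_within`,
#'   `duplicates_cross`, `coincidental_cross`, `severity_log_or`,
#'   `emitted`, `seed`).
#' @export
generate_reports <- function(config, dir = NULL, smq = default_ild_smq(),
                             indication_terms = default_indication_terms()) {
  validate_synthetic_config(config)
  set.seed(config$seed)
  dbs <- names(config$per_database)

  reports <- list()
  dup_within <- list()
  for (dbn in dbs) {
    d <- config$per_database[[dbn]]
    base <- generate_db_base(dbn, d, smq)
    # within-database duplicate submissions: degraded copies sharing the
    # report_id, so the completeness rule retains the original
    n_dup <- round(d$dup_within_rate * nrow(base))
    if (n_dup > 0) {
      idx <- sample.int(nrow(base), n_dup)
      copy <- base[idx, ]
      for (f in c("weight_kg", "country", "outcome")) copy[[f]] <- NA
      copy$serious <- NA
      copy$seriousness_criteria <- rep(list(character(0)), nrow(copy))
      copy$source_row <- sub("^gen", "dup", copy$source_row)
      dup_within[[dbn]] <- tibble::tibble(database = dbn,
                                          report_id = copy$report_id,
                                          source_row = copy$source_row)
      base <- dplyr::bind_rows(base, copy)
    } else {
      dup_within[[dbn]] <- tibble::tibble(database = character(0),
                                          report_id = character(0),
                                          source_row = character(0))
    }
    reports[[dbn]] <- base
  }

  # cross-database duplicates: FAERS-like reports re-filed elsewhere under
  # a fresh report_id with identical dedup-key fields
  dup_cross <- tibble::tibble(db_from = character(0), db_to = character(0),
                              report_id_src = character(0),
                              report_id_copy = character(0))
  fa <- config$per_database[["FAERS_LIKE"]]
  if (!is.null(fa) && fa$dup_cross_rate > 0 && nrow(reports$FAERS_LIKE) > 0) {
    src <- reports$FAERS_LIKE
    eligible <- which(!is.na(src$age_years) & !is.na(src$event_date) &
                        !is.na(src$country) &
                        !startsWith(src$source_row, "dup"))
    n_cross <- min(round(fa$dup_cross_rate * fa$n_reports), length(eligible))
    if (n_cross > 0) {
      idx <- sample(eligible, n_cross)
      copy <- src[idx, ]
      to_jader <- copy$country == "JP" & "JADER_LIKE" %in% dbs
      copy$database <- ifelse(to_jader, "JADER_LIKE", "CVAR_LIKE")
      old_id <- copy$report_id
      copy$report_id <- sprintf("X%07d", seq_len(nrow(copy)))
      copy$source_row <- sprintf("xdup:%06d", seq_len(nrow(copy)))
      # JADER-like carries no seriousness fields
      jj <- copy$database == "JADER_LIKE"
      copy$serious[jj] <- NA
      copy$seriousness_criteria[jj] <- list(character(0))
      dup_cross <- tibble::tibble(db_from = "FAERS_LIKE",
                                  db_to = copy$database,
                                  report_id_src = old_id,
                                  report_id_copy = copy$report_id)
      for (dbn in unique(copy$database)) {
        if (is.null(reports[[dbn]])) next
        reports[[dbn]] <- dplyr::bind_rows(reports[[dbn]],
                                           copy[copy$database == dbn, ])
      }
    }
  }

  emitted <- tibble::tibble(
    database = dbs,
    n_rows = unname(vapply(reports[dbs], nrow, integer(1))),
    n_dup_within = unname(vapply(dup_within[dbs], nrow, integer(1))),
    n_dup_cross_in = unname(vapply(dbs, function(dbn) {
      sum(dup_cross$db_to == dbn)
    }, integer(1))))

  # coincidental cross-database key collisions among non-injected rows
  # (rare; recorded so dedup-exactness checks can account for them)
  all_rows <- dplyr::bind_rows(reports)
  noninj <- !all_rows$report_id %in% dup_cross$report_id_copy
  kk <- all_rows[noninj & !is.na(all_rows$age_years) &
                   !is.na(all_rows$event_date) & !is.na(all_rows$country), ]
  key <- paste(round(kk$age_years), kk$drug_name, kk$event_date, kk$country,
               sep = "\r")
  coincidental <- 0
  if (nrow(kk) > 0) {
    span <- tapply(kk$database, key, function(x) length(unique(x)))
    sizes <- table(key)
    spanning <- names(span)[span > 1]
    if (length(spanning)) {
      coincidental <- sum(pmax(as.integer(sizes[spanning]) - 1L, 0L))
    }
  }

  gt <- list(
    expected_cells = expected_cells_table(config, indication_terms),
    true_ror = true_ror_table(config, indication_terms),
    duplicates_within = dplyr::bind_rows(dup_within),
    duplicates_cross = dup_cross,
    coincidental_cross = as.integer(coincidental),
    severity_log_or = lapply(config$per_database, function(d) d$severity_shift),
    emitted = emitted,
    seed = config$seed)

  out <- lapply(dbs, function(dbn) {
    report_set(reports[[dbn]][report_set_columns()],
               provenance = c(
                 paste0("generate_reports[", dbn, "]: seed ", config$seed),
                 paste0("  rows emitted: ", nrow(reports[[dbn]]))))
  })
  names(out) <- dbs

  files <- NULL
  if (!is.null(dir)) {
    files <- lapply(dbs, function(dbn) {
      write_reports(out[[dbn]], dir, dbn,
                    prefix = tolower(sub("_LIKE", "", dbn)))
    })
    names(files) <- dbs
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(
      list(seed = config$seed,
           true_ror = gt$true_ror,
           expected_cells = gt$expected_cells,
           duplicates_within = gt$duplicates_within,
           duplicates_cross = gt$duplicates_cross,
           coincidental_cross = gt$coincidental_cross,
           emitted = gt$emitted),
      gt_path, auto_unbox = TRUE, digits = NA, na = "null")
    files$ground_truth <- gt_path
  }

  list(reports = out, files = files, ground_truth = gt)
}

generate_db_base <- function(dbn, d, smq) {
  n <- d$n_reports
  prefix <- c(FAERS_LIKE = "F", CVAR_LIKE = "C", JADER_LIKE = "J")[dbn]
  drugs <- c(names(d$drug_weights), background_drug_pool())
  nw <- length(d$drug_weights)
  probs <- c(unname(d$drug_weights),
             rep(d$background_weight / length(background_drug_pool()),
                 length(background_drug_pool())))
  p_ild_all <- c(ild_prob_for(d, names(d$drug_weights)),
                 rep(d$baseline_ild_prob, length(background_drug_pool())))
  if (n == 0) {
    return(empty_report_tbl())
  }

  di <- sample.int(length(drugs), n, replace = TRUE, prob = probs)
  drug <- drugs[di]
  ild <- runif(n) < p_ild_all[di]

  pt <- character(n)
  pt[ild] <- sample(smq$preferred_terms, sum(ild), replace = TRUE)
  pt[!ild] <- sample(background_pt_pool(), sum(!ild), replace = TRUE)
  event_terms <- as.list(pt)
  if (d$multi_pt_rate > 0) {
    extra <- which(runif(n) < d$multi_pt_rate)
    for (i in extra) {
      event_terms[[i]] <- unique(c(event_terms[[i]],
                                   sample(background_pt_pool(),
                                          sample(1:2, 1))))
    }
  }

  indication <- sample(names(d$indication_mix), n, replace = TRUE,
                       prob = d$indication_mix)
  role <- ifelse(runif(n) < d$role_primary_prob, "PRIMARY_SUSPECT",
                 "CONCOMITANT")
  age <- pmin(pmax(rnorm(n, 65, 10), 18), 95)
  weight <- round(pmin(pmax(rnorm(n, 60, 12), 30), 150), 1)
  country <- switch(dbn,
    FAERS_LIKE = sample(c("US", "JP", "FR", "IT", "DE", "CA"), n,
                        replace = TRUE,
                        prob = c(0.43, 0.25, 0.13, 0.05, 0.08, 0.06)),
    CVAR_LIKE = rep("CA", n),
    JADER_LIKE = rep("JP", n))
  event_date <- as.Date("2015-01-01") +
    sample.int(3652, n, replace = TRUE) - 1L

  outcome <- sample_outcomes(d, drug, ild)

  serious <- ifelse(ild, runif(n) < 0.95, runif(n) < 0.50)
  crit <- vector("list", n)
  crit[] <- list(character(0))
  death_i <- which(!is.na(outcome) & outcome == "DEATH" & serious)
  crit[death_i] <- list("DEATH")
  hosp_i <- which(serious & !(seq_len(n) %in% death_i) & runif(n) < 0.75)
  crit[hosp_i] <- list("HOSPITALIZATION")

  tbl <- tibble::tibble(
    report_id = sprintf("%s%07d", prefix, seq_len(n)),
    database = dbn, age_years = age, weight_kg = weight, country = country,
    event_date = event_date, drug_name = drug, drug_verbatim = drug,
    drug_mapped = di <= nw, drug_role = role, indication = indication,
    event_terms = event_terms, serious = serious,
    seriousness_criteria = crit, outcome = outcome,
    source_row = sprintf("gen:%s:%06d", prefix, seq_len(n)))

  # field missingness (seriousness criteria are cleared with `serious` to
  # keep the model invariant: criteria non-empty implies serious = TRUE)
  mis <- d$missingness
  for (f in names(mis)) {
    if (!f %in% names(tbl) || mis[[f]] <= 0) next
    if (dbn == "JADER_LIKE" && f %in% c("country", "serious")) next
    hit <- runif(n) < mis[[f]]
    tbl[[f]][hit] <- NA
    if (f == "serious") tbl$seriousness_criteria[hit] <- list(character(0))
  }
  if (dbn == "JADER_LIKE") {
    tbl$serious <- NA
    tbl$seriousness_criteria <- rep(list(character(0)), n)
    tbl$country <- "JP"
  }
  tbl
}

sample_outcomes <- function(d, drug, ild) {
  n <- length(drug)
  outcome <- rep(NA_character_, n)
  sev_order <- default_severity_ordering()
  mix <- d$outcome_mix
  base_sev <- mix[sev_order]
  base_sev[is.na(base_sev)] <- 0
  names(base_sev) <- sev_order
  base_sev <- base_sev / sum(base_sev)

  non_ild <- which(!ild)
  if (length(non_ild)) {
    outcome[non_ild] <- sample(names(mix), length(non_ild), replace = TRUE,
                               prob = mix)
  }
  for (g in unique(drug[ild])) {
    idx <- which(ild & drug == g)
    shift <- d$severity_shift[g]
    shift <- if (is.na(shift) || is.null(shift)) 0 else unname(shift)
    if (shift != 0) {
      p <- tilt_severity(base_sev, shift)
      outcome[idx] <- sample(sev_order, length(idx), replace = TRUE, prob = p)
    } else {
      p_death <- d$death_prob_given_ild[g]
      if (is.na(p_death) || is.null(p_death)) p_death <- base_sev["DEATH"]
      p <- base_sev[sev_order != "DEATH"]
      p <- p / sum(p) * (1 - unname(p_death))
      p <- c(p, DEATH = unname(p_death))
      outcome[idx] <- sample(names(p), length(idx), replace = TRUE, prob = p)
    }
  }
  outcome
}

empty_report_tbl <- function() {
  tibble::tibble(report_id = character(0), database = character(0),
                 age_years = numeric(0), weight_kg = numeric(0),
                 country = character(0), event_date = as.Date(character(0)),
                 drug_name = character(0), drug_verbatim = character(0),
                 drug_mapped = logical(0), drug_role = character(0),
                 indication = character(0), event_terms = list(),
                 serious = logical(0), seriousness_criteria = list(),
                 outcome = character(0), source_row = character(0))
}

# Fraction of reports whose indication string matches the eligible terms.
eligible_indication_mass <- function(d, indication_terms) {
  ind <- normalize_term(names(d$indication_mix))
  pats <- normalize_term(indication_terms)
  hit <- rep(FALSE, length(ind))
  for (p in pats) hit <- hit | grepl(p, ind, fixed = TRUE)
  sum(d$indication_mix[hit])
}

# Expected contingency cells per drug for the study-drug universe (primary
# suspect, eligible non-missing indication, vocabulary drugs only).
expected_cells_db <- function(d, indication_terms) {
  drugs <- names(d$drug_weights)
  miss_ind <- unname(d$missingness["indication"])
  if (is.na(miss_ind)) miss_ind <- 0
  keep <- d$role_primary_prob * (1 - miss_ind) *
    eligible_indication_mass(d, indication_terms)
  w <- unname(d$drug_weights)
  p <- ild_prob_for(d, drugs)
  ea <- d$n_reports * keep * w * p
  ec <- d$n_reports * keep * w * (1 - p)
  tibble::tibble(drug = drugs, ea = ea, eb = sum(ea) - ea,
                 ec = ec, ed = sum(ec) - ec)
}

expected_cells_table <- function(config, indication_terms) {
  per_db <- lapply(names(config$per_database), function(dbn) {
    dplyr::mutate(expected_cells_db(config$per_database[[dbn]],
                                    indication_terms),
                  universe = dbn, .before = 1)
  })
  combined <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(per_db), .data$drug),
    ea = sum(.data$ea), eb = sum(.data$eb), ec = sum(.data$ec),
    ed = sum(.data$ed), .groups = "drop")
  combined <- dplyr::mutate(combined, universe = "COMBINED", .before = 1)
  dplyr::bind_rows(c(per_db, list(combined)))
}

true_ror_table <- function(config, indication_terms) {
  cells <- expected_cells_table(config, indication_terms)
  odds_drug <- cells$ea / cells$ec
  odds_rest <- cells$eb / cells$ed
  ror <- odds_drug / odds_rest
  degenerate <- !is.finite(ror) | cells$ea == 0 | cells$ec == 0 |
    cells$eb == 0 | cells$ed == 0
  ror[degenerate] <- NA_real_
  tibble::tibble(universe = cells$universe, drug = cells$drug, ror = ror)
}

#' Closed-form true reporting odds ratio implied by a configuration
#'
#' The true ROR is the odds of the event of interest under the drug
#' divided by the event odds under the complement mixture of all other
#' drugs in the universe (combined universes pool databases weighted by
#' their expected cohort sizes). Degenerate configurations (event
#' probability 0 or 1 anywhere in the contrast) return `NA`.
#'
#' @param config A [synthetic_config()].
#' @param drug Canonical drug name present in the configuration.
#' @param universe A database name or `"COMBINED"`.
#' @param indication_terms Eligible indication patterns (cohort filter).
#' @return Positive number, or `NA` when undefined.
#' @export
expected_ror <- function(config, drug, universe = "COMBINED",
                         indication_terms = default_indication_terms()) {
  tr <- true_ror_table(config, indication_terms)
  row <- tr[tr$universe == universe & tr$drug == drug, ]
  assert_that(nrow(row) == 1,
              paste0("no such drug/universe in config: ", drug, " / ",
                     universe))
  row$ror
}
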