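# Shared fixture builders. Everything is generated in code; no binary data.

study_drugs <- function() vocabulary_drugs(default_drug_vocabulary())

uniform_weights <- function(drugs = study_drugs()) {
  setNames(rep(1 / length(drugs), length(drugs)), drugs)
}

# A fully-populated harmonized report tibble with per-argument recycling;
# used to exercise filters and dedup without going through files.
mk_reports <- function(n = 1,
                       report_id = sprintf("R%04d", seq_len(n)),
                       database = "FAERS_LIKE",
                       age_years = 60, weight_kg = 60, country = "US",
                       event_date = as.Date("2023-01-01"),
                       drug_name = "olaparib",
                       drug_verbatim = drug_name, drug_mapped = TRUE,
                       drug_role = "PRIMARY_SUSPECT",
                       indication = "Ovarian cancer",
                       event_terms = "Interstitial lung disease",
                       serious = TRUE,
                       seriousness_criteria = list(character(0)),
                       outcome = "RECOVERED",
                       source_row = sprintf("t:%04d", seq_len(n))) {
  if (!is.list(event_terms)) event_terms <- as.list(event_terms)
  tbl <- tibble::tibble(
    report_id = report_id, database = database, age_years = age_years,
    weight_kg = weight_kg, country = country, event_date = event_date,
    drug_name = drug_name, drug_verbatim = drug_verbatim,
    drug_mapped = drug_mapped, drug_role = drug_role,
    indication = indication, event_terms = event_terms, serious = serious,
    seriousness_criteria = seriousness_criteria, outcome = outcome,
    source_row = source_row)
  report_set(tbl)
}

# Minimal cohort encoding exact contingency cells for the signal module.
mk_cohort_cells <- function(a, b, c, d, drug = "olaparib",
                            other = "paclitaxel") {
  tibble::tibble(
    drug_name = c(rep(drug, a + c), rep(other, b + d)),
    ild_flag = c(rep(TRUE, a), rep(FALSE, c), rep(TRUE, b), rep(FALSE, d)),
    database = "FAERS_LIKE",
    age_years = NA_real_, outcome = NA_character_)
}

# Independent Fisher oracle: enumerates the conditional distribution from
# binomial coefficients directly (no dhyper), minimum-likelihood two-sided.
fisher_oracle <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c; N <- m1 + m2
  xs <- max(0, k - m2):min(k, m1)
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(N, k)
  p <- exp(logp)
  p_obs <- exp(lchoose(m1, a) + lchoose(m2, k - a) - lchoose(N, k))
  min(1, sum(p[p <= p_obs * (1 + 1e-7)]))
}

# Two-group proportional-odds log-likelihood for the grid-search oracle.
po_oracle_loglik <- function(theta, beta, counts) {
  ll <- 0
  for (gi in 1:2) {
    x <- gi - 1
    Fk <- c(0, plogis(theta - beta * x), 1)
    p <- pmax(diff(Fk), 1e-300)
    ll <- ll + sum(counts[gi, ] * log(p))
  }
  ll
}
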