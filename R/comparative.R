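#' Fatality constituent ratios and ILD-vs-non-ILD death risk
#'
#' Among event-of-interest (ILD-flagged) reports with a known outcome,
#' computes each drug's death constituent ratio (deaths / outcome-known
#' reports). The overall contrast compares death proportions between ILD
#' and non-ILD reports by a Pearson chi-square test (no continuity
#' correction) on the 2x2 death-by-ILD table; reports with missing or
#' `UNKNOWN` outcome are excluded from all denominators.
#'
#' @param reports A cohort-filtered [report_set()] carrying `ild_flag`.
#' @param by_drug Also compute per-drug summaries (default `TRUE`).
#' @return A list with `by_drug` (tibble: `drug`, `deaths`,
#'   `total_with_outcome`, `proportion` — `NA` proportion on a zero
#'   denominator) and `contrast` (tibble with one row per group ILD /
#'   NON_ILD plus attributes-free columns `chi2` and `p_value` repeated).
#' @export
fatality_analysis <- function(reports, by_drug = TRUE) {
  assert_that("ild_flag" %in% names(reports),
              "reports must be cohort-filtered first (missing ild_flag)")
  known <- !is.na(reports$outcome) & reports$outcome != "UNKNOWN"
  x <- reports[known, ]
  death <- x$outcome == "DEATH"

  by_drug_tbl <- NULL
  if (by_drug) {
    sub <- x[x$ild_flag, ]
    by_drug_tbl <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(drug = sub$drug_name,
                                     death = sub$outcome == "DEATH"),
                      .data$drug),
      deaths = sum(.data$death),
      total_with_outcome = dplyr::n(), .groups = "drop")
    by_drug_tbl$proportion <- ifelse(by_drug_tbl$total_with_outcome > 0,
                                     by_drug_tbl$deaths / by_drug_tbl$total_with_outcome,
                                     NA_real_)
    by_drug_tbl <- dplyr::arrange(by_drug_tbl, dplyr::desc(.data$proportion))
  }

  contrast <- tibble::tibble(
    group = c("ILD", "NON_ILD"),
    deaths = c(sum(death & x$ild_flag), sum(death & !x$ild_flag)),
    total_with_outcome = c(sum(x$ild_flag), sum(!x$ild_flag)))
  contrast$proportion <- ifelse(contrast$total_with_outcome > 0,
                                contrast$deaths / contrast$total_with_outcome,
                                NA_real_)
  chi2 <- NA_real_; p <- NA_real_
  if (all(contrast$total_with_outcome > 0)) {
    m <- rbind(contrast$deaths, contrast$total_with_outcome - contrast$deaths)
    ht <- suppressWarnings(chisq.test(m, correct = FALSE))
    chi2 <- unname(ht$statistic); p <- ht$p.value
  }
  contrast$chi2 <- chi2
  contrast$p_value <- p
  list(by_drug = by_drug_tbl, contrast = contrast)
}

# Coerce the tables argument of the pairwise/volcano operations: accepts a
# list of contingency_table objects or a signal_table tibble.
tables_to_cells <- function(tables) {
  if (is.data.frame(tables)) {
    assert_that(all(c("drug", "a", "b", "c", "d") %in% names(tables)),
                "tables tibble must carry drug, a, b, c, d columns")
    tibble::tibble(drug = tables$drug,
                   a = as.numeric(tables$a), b = as.numeric(tables$b),
                   c = as.numeric(tables$c), d = as.numeric(tables$d),
                   universe = tables$universe %||% NA_character_)
  } else {
    dplyr::bind_rows(lapply(tables, function(t) {
      tibble::tibble(drug = t$drug, a = t$a, b = t$b, c = t$c, d = t$d,
                     universe = t$universe_label)
    }))
  }
}

#' Pairwise odds-ratio matrix for event proportions across regimens
#'
#' Compares the proportion of event-of-interest reports between every pair
#' of drugs in one universe. With a single binary regressor the logistic
#' odds ratio equals the counts-based Wald odds ratio, so the entry at
#' (row i, column j) is `OR = (a_j * c_i) / (a_i * c_j)` — the odds of the
#' event under the column drug relative to the row drug — with 95% CI
#' `exp(ln OR +/- 1.96 * sqrt(1/a_i + 1/c_i + 1/a_j + 1/c_j))` and a
#' two-sided Wald-z p-value. Bonferroni adjustment uses the number of
#' off-diagonal pairs (upper triangle) as the family size. Entries with
#' any zero count are flagged undefined; the matrix is antisymmetric
#' (`OR[i,j] * OR[j,i] = 1`) with unit diagonal.
#'
#' @param tables List of [contingency_table()]s over one universe, or a
#'   [signal_table()] tibble.
#' @return An object of class `pairwise_matrix`: list with `comparisons`
#'   (long tibble: `drug_row`, `drug_col`, `odds_ratio`, `ci_low`,
#'   `ci_high`, `p_raw`, `p_adjusted`, `defined`), `or_matrix`,
#'   `family_size`, `universe`.
#' @export
pairwise_ild_odds_matrix <- function(tables) {
  cells <- tables_to_cells(tables)
  assert_that(!anyDuplicated(cells$drug), "duplicate drug in tables")
  k <- nrow(cells)
  assert_that(k >= 2, "need at least two drugs")
  m <- k * (k - 1) / 2
  z975 <- 1.96

  grid <- expand.grid(i = seq_len(k), j = seq_len(k))
  ai <- cells$a[grid$i]; ci <- cells$c[grid$i]
  aj <- cells$a[grid$j]; cj <- cells$c[grid$j]
  or <- (aj * ci) / (ai * cj)
  se <- sqrt(1 / ai + 1 / ci + 1 / aj + 1 / cj)
  lo <- exp(log(or) - z975 * se)
  hi <- exp(log(or) + z975 * se)
  zstat <- log(or) / se
  p_raw <- 2 * stats::pnorm(-abs(zstat))
  defined <- ai >= 1 & ci >= 1 & aj >= 1 & cj >= 1
  diag_idx <- grid$i == grid$j
  or[diag_idx] <- 1; lo[diag_idx] <- 1; hi[diag_idx] <- 1
  p_raw[diag_idx] <- 1
  or[!defined & !diag_idx] <- NA_real_
  lo[!defined & !diag_idx] <- NA_real_
  hi[!defined & !diag_idx] <- NA_real_
  p_raw[!defined & !diag_idx] <- NA_real_
  p_adj <- pmin(1, p_raw * m)
  p_adj[diag_idx] <- 1

  comparisons <- tibble::tibble(
    drug_row = cells$drug[grid$i], drug_col = cells$drug[grid$j],
    odds_ratio = or, ci_low = lo, ci_high = hi,
    p_raw = p_raw, p_adjusted = p_adj,
    defined = defined | diag_idx)
  or_matrix <- matrix(or, k, k, dimnames = list(cells$drug, cells$drug))
  structure(list(comparisons = comparisons, or_matrix = or_matrix,
                 family_size = m,
                 universe = cells$universe[1]),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("<pairwise_matrix> ", nrow(x$or_matrix), " drugs in ",
      x$universe %||% "?", "; Bonferroni family size ", x$family_size,
      "\n", sep = "")
  print(round_half_up(x$or_matrix, 2))
  invisible(x)
}

#' Two-sided Fisher exact p-value for a 2x2 table
#'
#' Conditional test with both margins fixed, using the minimum-likelihood
#' two-sided convention: the p-value sums the probabilities of all tables
#' with the observed margins whose point hypergeometric probability does
#' not exceed the observed one (within a 1e-7 relative tolerance guarding
#' floating-point ties).
#'
#' @param a,b,c,d Cell counts in the [contingency_table()] layout.
#' @return P-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  m1 <- a + b   # event margin
  m2 <- c + d   # non-event margin
  k <- a + c    # drug margin
  support <- max(0, k - m2):min(k, m1)
  probs <- dhyper(support, m1, m2, k)
  p_obs <- dhyper(a, m1, m2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Volcano coordinates: effect size vs adjusted Fisher significance
#'
#' For each drug's 2x2 table computes a two-sided conditional Fisher exact
#' p-value ([fisher_exact_2x2()]), Bonferroni-adjusts it over the number
#' of drugs tested in the universe, and emits plotting coordinates: the
#' natural log of the ROR on x and `-log10` of the adjusted p (floored at
#' 1e-300) on y. Drugs with an undefined ROR (any zero cell) are emitted
#' with `defined = FALSE` and no coordinates.
#'
#' @param tables List of [contingency_table()]s over one universe, or a
#'   [signal_table()] tibble.
#' @return Tibble with columns `drug`, `n_reports` (= `a`), `ror`,
#'   `log_ror`, `p_raw`, `p_adjusted`, `minus_log10_p_adjusted`,
#'   `defined`.
#' @export
volcano_statistics <- function(tables) {
  cells <- tables_to_cells(tables)
  m <- nrow(cells)
  p_raw <- mapply(fisher_exact_2x2, cells$a, cells$b, cells$c, cells$d)
  p_adj <- pmin(1, p_raw * m)
  defined <- cells$a >= 1 & cells$b >= 1 & cells$c >= 1 & cells$d >= 1
  ror <- ifelse(defined, (cells$a * cells$d) / (cells$b * cells$c), NA_real_)
  tibble::tibble(
    drug = cells$drug, n_reports = cells$a, ror = ror,
    log_ror = log(ror),
    p_raw = p_raw, p_adjusted = p_adj,
    minus_log10_p_adjusted = ifelse(defined, -log10(pmax(p_adj, 1e-300)),
                                    NA_real_),
    defined = defined)
}

#' Volcano plot of drug-event signal strength
#'
#' @param volcano A [volcano_statistics()] tibble.
#' @param alpha Significance threshold drawn as a horizontal line.
#' @return A ggplot object (points coloured by report count).
#' @export
plot_volcano <- function(volcano, alpha = 0.05) {
  v <- volcano[volcano$defined, ]
  ggplot2::ggplot(v, ggplot2::aes(x = .data$log_ror,
                                  y = .data$minus_log10_p_adjusted,
                                  colour = .data$n_reports)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::scale_colour_gradient(low = "steelblue", high = "firebrick") +
    ggplot2::labs(x = "ln(ROR)", y = "-log10 adjusted p",
                  colour = "reports") +
    ggplot2::theme_minimal()
}

# Severity ----------------------------------------------------------------

#' Ordered severity distribution of reaction outcomes for one drug
#'
#' @param drug Canonical drug name (or any group label).
#' @param counts Named numeric vector of outcome counts; names must be a
#'   subset of `ordering`.
#' @param ordering Outcome categories from least to most severe; the
#'   default places death at the severe end:
#'   RECOVERED < RECOVERING < RECOVERED_WITH_SEQUELAE < NOT_RECOVERED <
#'   DEATH.
#' @return An object of class `severity_distribution`.
#' @export
severity_distribution <- function(drug, counts,
                                  ordering = default_severity_ordering()) {
  assert_that(all(names(counts) %in% ordering),
              "counts names must be a subset of the ordering")
  assert_that(sum(counts) > 0, "severity distribution needs a positive total")
  full <- setNames(numeric(length(ordering)), ordering)
  full[names(counts)] <- counts
  structure(list(drug = drug, counts = full, ordering = ordering),
            class = "severity_distribution")
}

#' @rdname severity_distribution
#' @export
default_severity_ordering <- function() {
  c("RECOVERED", "RECOVERING", "RECOVERED_WITH_SEQUELAE", "NOT_RECOVERED",
    "DEATH")
}

#' Extract a drug's severity distribution from a report set
#'
#' Tallies known, non-`UNKNOWN` outcomes of the drug's event-of-interest
#' reports.
#'
#' @param reports Cohort-filtered [report_set()] with `ild_flag`.
#' @param drug Canonical drug name.
#' @param ordering See [severity_distribution()].
#' @param ild_only Restrict to flagged reports (default `TRUE`).
#' @return A [severity_distribution()], or `NULL` when the drug has no
#'   outcome-known reports.
#' @export
severity_from_reports <- function(reports, drug,
                                  ordering = default_severity_ordering(),
                                  ild_only = TRUE) {
  x <- reports[reports$drug_name == drug &
                 (!ild_only | reports$ild_flag) &
                 !is.na(reports$outcome) & reports$outcome != "UNKNOWN", ]
  if (nrow(x) == 0) return(NULL)
  severity_distribution(drug, table(factor(x$outcome, levels = ordering)),
                        ordering)
}

#' Two-group proportional-odds severity comparison
#'
#' Fits the cumulative-logit proportional-odds model
#' `logit P(Y <= k | x) = theta_k - beta * x` (x = 0 for group a, 1 for
#' group b) by maximum likelihood with Newton iterations (convergence at
#' gradient norm below `tol`, at most `max_iter` iterations, with step
#' halving). `exp(beta)` is the odds ratio for group b lying in a more
#' severe outcome category than group a; the Wald 95% CI comes from the
#' observed information. Categories empty in both groups are dropped
#' before fitting (the estimate is invariant to this merge). Data with a
#' single occupied category, or complete separation, are flagged
#' non-estimable.
#'
#' @param dist_a,dist_b [severity_distribution()]s sharing one ordering.
#' @param tol Gradient-norm convergence tolerance.
#' @param max_iter Maximum Newton iterations.
#' @return List with `odds_ratio`, `ci95`, `log_or`, `se`, `converged`,
#'   `estimable`, `iterations`, `loglik`.
#' @export
severity_proportional_odds <- function(dist_a, dist_b, tol = 1e-8,
                                       max_iter = 100) {
  stopifnot(inherits(dist_a, "severity_distribution"),
            inherits(dist_b, "severity_distribution"))
  assert_that(identical(dist_a$ordering, dist_b$ordering),
              "both distributions must share the same category ordering")
  counts <- rbind(a = dist_a$counts, b = dist_b$counts)
  occupied <- colSums(counts) > 0
  counts <- counts[, occupied, drop = FALSE]
  K <- ncol(counts)
  not_est <- list(odds_ratio = NA_real_, ci95 = c(NA_real_, NA_real_),
                  log_or = NA_real_, se = NA_real_, converged = FALSE,
                  estimable = FALSE, iterations = 0L, loglik = NA_real_)
  if (K < 2 || any(rowSums(counts) == 0)) return(not_est)
  # complete separation: the two groups occupy disjoint category ranges
  rng_a <- range(which(counts["a", ] > 0))
  rng_b <- range(which(counts["b", ] > 0))
  if (rng_a[2] < rng_b[1] || rng_b[2] < rng_a[1]) return(not_est)

  negll <- function(par) -po_loglik(par, counts)
  # start: pooled cumulative logits, no group effect
  pooled <- colSums(counts)
  cum <- cumsum(pooled)[-K] / sum(pooled)
  cum <- pmin(pmax(cum, 1e-6), 1 - 1e-6)
  par <- c(log(cum / (1 - cum)), 0)

  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    g <- po_gradient(par, counts)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    H <- po_hessian(par, counts)
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(not_est)
    # Newton ascent with step halving on likelihood decrease
    ll0 <- po_loglik(par, counts)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      if (is_increasing(cand[-length(cand)]) &&
          po_loglik(cand, counts) >= ll0 - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) return(not_est)
    }
    par <- cand
  }
  if (!converged) {
    g <- po_gradient(par, counts)
    converged <- sqrt(sum(g^2)) < tol
  }
  beta <- unname(par[length(par)])
  if (abs(beta) > 30) return(not_est)
  H <- po_hessian(par, counts)
  vc <- tryCatch(solve(-H), error = function(e) NULL)
  if (is.null(vc)) return(not_est)
  se <- sqrt(vc[length(par), length(par)])
  list(odds_ratio = exp(beta),
       ci95 = exp(beta + c(-1, 1) * 1.96 * se),
       log_or = beta, se = se, converged = converged, estimable = TRUE,
       iterations = it, loglik = po_loglik(par, counts))
}

is_increasing <- function(x) length(x) < 2 || all(diff(x) > 0)

# Cell probabilities of the two-group cumulative-logit model.
# par = (theta_1 < ... < theta_{K-1}, beta); rows of `counts` are groups
# a (x = 0) and b (x = 1).
po_cellprobs <- function(par, K) {
  theta <- par[-length(par)]
  beta <- par[length(par)]
  sapply(c(0, 1), function(x) {
    Fk <- c(plogis(theta - beta * x), 1)
    diff(c(0, Fk))
  })  # K x 2 matrix, columns = groups a, b
}

po_loglik <- function(par, counts) {
  p <- po_cellprobs(par, ncol(counts))
  p <- pmax(p, 1e-300)
  sum(counts["a", ] * log(p[, 1])) + sum(counts["b", ] * log(p[, 2]))
}

# Analytic gradient of the log-likelihood.
po_gradient <- function(par, counts) {
  K <- ncol(counts)
  theta <- par[-length(par)]
  beta <- par[length(par)]
  g <- numeric(length(par))
  for (gi in 1:2) {
    x <- gi - 1
    n <- counts[gi, ]
    Fk <- c(0, plogis(theta - beta * x), 1)       # F_0..F_K
    fk <- c(0, stats::dlogis(theta - beta * x), 0)  # f at the cutpoints
    p <- pmax(diff(Fk), 1e-300)
    w <- n / p
    # d p_k / d theta_j = f_j [j == k] - f_j [j == k - 1]
    for (j in seq_along(theta)) {
      g[j] <- g[j] + w[j] * fk[j + 1] - w[j + 1] * fk[j + 1]
    }
    # d p_k / d beta = -x f_k + x f_{k-1}
    g[length(par)] <- g[length(par)] +
      sum(w * (-x * fk[2:(K + 1)] + x * fk[1:K]))
  }
  g
}

# Observed-information Hessian via central differences of the analytic
# gradient (cutpoint count is small, so this is exact to O(h^2) and cheap).
po_hessian <- function(par, counts, h = 1e-5) {
  np <- length(par)
  H <- matrix(0, np, np)
  for (j in seq_len(np)) {
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    H[, j] <- (po_gradient(up, counts) - po_gradient(dn, counts)) / (2 * h)
  }
  (H + t(H)) / 2
}
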