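test_that("fatality constituent ratios are exact fractions of outcome-known reports", {
  rs <- report_set(dplyr::bind_rows(
    mk_reports(17, report_id = sprintf("A%02d", 1:17), drug_name = "mirvetuximab soravtansine-gynx",
               outcome = c(rep("DEATH", 5), rep("RECOVERED", 12)),
               seriousness_criteria = list(character(0))),
    mk_reports(40, report_id = sprintf("B%02d", 1:40), drug_name = "carboplatin",
               outcome = "RECOVERING"),
    mk_reports(6, report_id = sprintf("C%02d", 1:6), drug_name = "cisplatin",
               outcome = c(rep("DEATH", 2), rep("UNKNOWN", 3), NA))))
  rs$ild_flag <- TRUE
  fa <- fatality_analysis(rs)
  bd <- fa$by_drug
  expect_equal(bd$proportion[bd$drug == "mirvetuximab soravtansine-gynx"], 5 / 17)
  expect_equal(round_half_up(100 * bd$proportion[bd$drug == "mirvetuximab soravtansine-gynx"], 2),
               29.41)
  expect_equal(bd$proportion[bd$drug == "carboplatin"], 0)
  # UNKNOWN and missing outcomes leave the denominator
  expect_equal(bd$total_with_outcome[bd$drug == "cisplatin"], 2)
})

test_that("ILD vs non-ILD death contrast matches the chi-square oracle", {
  rs <- report_set(dplyr::bind_rows(
    mk_reports(60, report_id = sprintf("I%03d", 1:60),
               outcome = c(rep("DEATH", 12), rep("RECOVERED", 48)),
               seriousness_criteria = list(character(0))),
    mk_reports(200, report_id = sprintf("N%03d", 1:200),
               drug_name = "paclitaxel",
               outcome = c(rep("DEATH", 10), rep("RECOVERED", 190)))))
  rs$ild_flag <- startsWith(rs$report_id, "I")
  fa <- fatality_analysis(rs, by_drug = FALSE)
  ct <- fa$contrast
  expect_equal(ct$proportion[ct$group == "ILD"], 12 / 60)
  oracle <- chisq.test(matrix(c(12, 48, 10, 190), 2), correct = FALSE)
  expect_equal(ct$p_value[1], oracle$p.value, tolerance = 1e-12)
})

test_that("pairwise matrix reproduces the published olaparib/niraparib contrast", {
  tabs <- list(
    contingency_table(768, 3321, 22977, 352574, "olaparib", "COMBINED"),
    contingency_table(607, 3482, 147133, 228418,
                      "niraparib tosylate monohydrate", "COMBINED"))
  pm <- pairwise_ild_odds_matrix(tabs)
  cell <- pm$comparisons[pm$comparisons$drug_row == "olaparib" &
                           pm$comparisons$drug_col == "niraparib tosylate monohydrate", ]
  expect_equal(round_half_up(cell$odds_ratio, 2), 0.12)
  expect_equal(round_half_up(cell$ci_low, 2), 0.11)
  expect_equal(round_half_up(cell$ci_high, 2), 0.14)
  expect_lt(cell$p_adjusted, 0.05)
})

test_that("pairwise matrix is antisymmetric with unit diagonal and capped Bonferroni", {
  withr::local_seed(13)
  k <- 6
  tabs <- lapply(seq_len(k), function(i) {
    contingency_table(sample(3:80, 1), sample(50:300, 1),
                      sample(100:900, 1), sample(2000:9000, 1),
                      paste0("drug", i), "SYN")
  })
  pm <- pairwise_ild_odds_matrix(tabs)
  M <- pm$or_matrix
  expect_equal(unname(diag(M)), rep(1, k))
  expect_equal(M * t(M), matrix(1, k, k), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(pm$family_size, k * (k - 1) / 2)
  cmp <- pm$comparisons
  off <- cmp[cmp$drug_row != cmp$drug_col, ]
  expect_equal(off$p_adjusted, pmin(1, off$p_raw * pm$family_size))
  expect_true(all(off$p_adjusted >= off$p_raw))
})

test_that("Fisher exact p-values follow the minimum-likelihood convention", {
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  # enumeration oracle built from binomial coefficients
  expect_equal(fisher_exact_2x2(5, 1, 1, 5), fisher_oracle(5, 1, 1, 5),
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(5, 1, 1, 5),
               fisher.test(matrix(c(5, 1, 1, 5), 2))$p.value,
               tolerance = 1e-9)
  withr::local_seed(41)
  for (i in 1:30) {
    cells <- sample(0:25, 4, replace = TRUE)
    if (sum(cells) == 0) next
    p <- do.call(fisher_exact_2x2, as.list(cells))
    expect_gt(p, 0); expect_lte(p, 1)
    expect_equal(p, do.call(fisher_oracle, as.list(cells)),
                 tolerance = 1e-12)
    expect_equal(p, fisher.test(matrix(cells[c(1, 3, 2, 4)], 2))$p.value,
                 tolerance = 1e-7)
  }
})

test_that("volcano statistics carry Bonferroni-adjusted coordinates and flags", {
  tabs <- lapply(1:13, function(i) {
    contingency_table(3 + i, 40, 50, 600, paste0("d", i), "SYN")
  })
  tabs[[13]] <- contingency_table(0, 40, 50, 600, "d13", "SYN")
  v <- volcano_statistics(tabs)
  expect_equal(nrow(v), 13)
  expect_equal(v$p_adjusted, pmin(1, v$p_raw * 13))
  expect_false(v$defined[13])
  expect_true(is.na(v$log_ror[13]))  # undefined ROR emits no coordinate
  ok <- v$defined
  expect_equal(v$minus_log10_p_adjusted[ok], -log10(pmax(v$p_adjusted[ok], 1e-300)))
  expect_s3_class(plot_volcano(v), "ggplot")
})

test_that("identical severity distributions give an odds ratio of 1", {
  d <- severity_distribution("x", c(RECOVERED = 20, RECOVERING = 12,
                                    NOT_RECOVERED = 9, DEATH = 4))
  po <- severity_proportional_odds(d, d)
  expect_true(po$estimable && po$converged)
  expect_equal(po$odds_ratio, 1, tolerance = 1e-6)
})

test_that("with two categories the proportional-odds OR equals the 2x2 OR", {
  da <- severity_distribution("a", c(RECOVERED = 30, DEATH = 6))
  db <- severity_distribution("b", c(RECOVERED = 18, DEATH = 14))
  po <- severity_proportional_odds(da, db)
  closed_form <- (14 * 30) / (18 * 6)
  expect_equal(po$odds_ratio, closed_form, tolerance = 1e-6)
})

test_that("Newton estimate agrees with a brute-force likelihood grid", {
  da <- severity_distribution("a", c(RECOVERED = 14, RECOVERING = 9,
                                     NOT_RECOVERED = 5, DEATH = 3))
  db <- severity_distribution("b", c(RECOVERED = 6, RECOVERING = 8,
                                     NOT_RECOVERED = 9, DEATH = 8))
  po <- severity_proportional_odds(da, db)
  counts <- rbind(a = da$counts, b = db$counts)
  counts <- counts[, colSums(counts) > 0]
  # profile likelihood over a beta grid, thetas maximized numerically at
  # each grid point; coarse pass then a fine pass around the optimum
  profile_nll <- function(b) {
    start <- qlogis(pmin(pmax(cumsum(colSums(counts))[-ncol(counts)] /
                                sum(counts), 1e-6), 1 - 1e-6))
    optim(start, function(th) {
      if (is.unsorted(th, strictly = TRUE)) return(1e10)
      -po_oracle_loglik(th, b, counts)
    }, method = "Nelder-Mead",
    control = list(maxit = 5000, reltol = 1e-13))$value
  }
  coarse <- seq(-1, 2, by = 0.02)
  b0 <- coarse[which.min(vapply(coarse, profile_nll, numeric(1)))]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 5e-5)
  nll <- vapply(fine, profile_nll, numeric(1))
  expect_equal(fine[which.min(nll)], po$log_or, tolerance = 1e-4)
  expect_equal(-min(nll), po$loglik, tolerance = 1e-6)
})

test_that("the fit is invariant to dropping a category empty in both groups", {
  da <- severity_distribution("a", c(RECOVERED = 20, RECOVERING = 0,
                                     NOT_RECOVERED = 8, DEATH = 3))
  db <- severity_distribution("b", c(RECOVERED = 9, RECOVERING = 0,
                                     NOT_RECOVERED = 12, DEATH = 7))
  full <- severity_proportional_odds(da, db)
  da2 <- severity_distribution("a", c(RECOVERED = 20, NOT_RECOVERED = 8,
                                      DEATH = 3),
                               ordering = c("RECOVERED", "NOT_RECOVERED",
                                            "DEATH"))
  db2 <- severity_distribution("b", c(RECOVERED = 9, NOT_RECOVERED = 12,
                                      DEATH = 7),
                               ordering = c("RECOVERED", "NOT_RECOVERED",
                                            "DEATH"))
  merged <- severity_proportional_odds(da2, db2)
  expect_equal(full$odds_ratio, merged$odds_ratio, tolerance = 1e-8)
})

test_that("separated or single-category data are flagged non-estimable", {
  one_cat <- severity_distribution("a", c(RECOVERED = 10))
  expect_false(severity_proportional_odds(one_cat, one_cat)$estimable)
  sep_a <- severity_distribution("a", c(RECOVERED = 10, RECOVERING = 5))
  sep_b <- severity_distribution("b", c(NOT_RECOVERED = 4, DEATH = 6))
  expect_false(severity_proportional_odds(sep_a, sep_b)$estimable)
})

test_that("proportional-odds fit matches MASS::polr on expanded data", {
  da <- severity_distribution("a", c(RECOVERED = 25, RECOVERING = 15,
                                     NOT_RECOVERED = 9, DEATH = 6))
  db <- severity_distribution("b", c(RECOVERED = 10, RECOVERING = 12,
                                     NOT_RECOVERED = 14, DEATH = 12))
  po <- severity_proportional_odds(da, db)
  expand <- function(d, g) {
    data.frame(y = rep(names(d$counts), d$counts), g = g)
  }
  df <- rbind(expand(da, 0), expand(db, 1))
  df$y <- factor(df$y, levels = default_severity_ordering(), ordered = TRUE)
  fit <- MASS::polr(y ~ g, data = df, Hess = TRUE)
  expect_equal(po$log_or, unname(coef(fit)["g"]), tolerance = 1e-5)
  expect_equal(po$se, sqrt(vcov(fit)["g", "g"]), tolerance = 1e-4)
})
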