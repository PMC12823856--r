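test_that("contingency cells count drug-by-event membership exactly", {
  co <- mk_cohort_cells(7, 5, 11, 20)
  tab <- build_contingency(co, "olaparib", "TEST")
  expect_equal(c(tab$a, tab$b, tab$c, tab$d), c(7, 5, 11, 20))
  expect_equal(tab$n, nrow(co))

  single <- mk_cohort_cells(1, 0, 0, 0)
  t1 <- build_contingency(single, "olaparib")
  expect_equal(c(t1$a, t1$b, t1$c, t1$d), c(1, 0, 0, 0))

  absent <- build_contingency(co, "cisplatin", "TEST")
  expect_equal(c(absent$a, absent$c), c(0, 0))
  expect_false(compute_signal_estimates(absent)$defined)
})

test_that("a balanced table gives PRR = ROR = 1 and IC = 0 exactly", {
  e <- compute_signal_estimates(contingency_table(10, 10, 10, 10))
  expect_equal(e$prr, 1)
  expect_equal(e$ror, 1)
  expect_equal(e$a_exp, 10)
  expect_equal(e$ic, 0)
  expect_lt(e$ic025, 0)
})

test_that("published example rows reproduce at display rounding", {
  # FAERS olaparib
  e <- compute_signal_estimates(contingency_table(495, 2288, 18529, 293590))
  expect_equal(round_half_up(c(e$prr, e$prr_ci95), 2), c(3.36, 3.06, 3.70))
  expect_equal(round_half_up(c(e$ror, e$ror_ci95), 2), c(3.43, 3.11, 3.78))
  expect_equal(round_half_up(e$chi2_pearson, 2), 682.39)
  expect_equal(round_half_up(c(e$ic, e$ic025), 2), c(1.56, 1.41))
  # CVAR olaparib
  e2 <- compute_signal_estimates(contingency_table(15, 319, 581, 42411))
  expect_equal(round_half_up(c(e2$ror, e2$ror_ci95), 2), c(3.43, 2.03, 5.80))
  expect_equal(round_half_up(c(e2$ic, e2$ic025), 2), c(1.61, 0.73))
  # FAERS mirvetuximab soravtansine-gynx
  e3 <- compute_signal_estimates(contingency_table(33, 2750, 874, 311245))
  expect_equal(round_half_up(c(e3$ror, e3$ror_ci95), 2), c(4.27, 3.01, 6.06))
  expect_equal(round_half_up(c(e3$ic, e3$ic025), 2), c(1.98, 1.40))
})

test_that("zero cells yield undefined point estimates and no correction", {
  e <- compute_signal_estimates(contingency_table(0, 10, 5, 20))
  expect_false(e$defined)
  expect_true(is.na(e$prr) && is.na(e$ror))
  expect_true(all(is.na(e$prr_ci95)) && all(is.na(e$ror_ci95)))
  expect_true(is.finite(e$chi2_pearson))  # chi-square remains defined
  v <- evaluate_signal(e)
  expect_false(v$criterion1 || v$criterion2 || v$criterion3 || v$signal)
})

test_that("uncorrected chi-square matches independent implementations", {
  withr::local_seed(99)
  for (i in 1:25) {
    cells <- rmultinom(1, size = sample(50:5000, 1),
                       prob = runif(4, 0.05, 1))[, 1] + 1
    e <- compute_signal_estimates(do.call(contingency_table, as.list(cells)))
    m <- matrix(c(cells[1], cells[3], cells[2], cells[4]), 2)
    expect_equal(e$chi2_pearson,
                 unname(suppressWarnings(
                   chisq.test(m, correct = FALSE)$statistic)),
                 tolerance = 1e-9)
    expect_equal(e$chi2_yates,
                 unname(suppressWarnings(
                   chisq.test(m, correct = TRUE)$statistic)),
                 tolerance = 1e-9)
    # closed form on the drug/event margins
    a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
    n <- sum(cells)
    expect_equal(e$chi2_pearson,
                 n * (a * d - b * cc)^2 /
                   ((a + b) * (cc + d) * (a + cc) * (b + d)),
                 tolerance = 1e-12)
  }
})

test_that("estimate invariants hold across random tables", {
  withr::local_seed(7)
  for (i in 1:50) {
    cells <- sample(1:400, 4, replace = TRUE)
    e <- compute_signal_estimates(do.call(contingency_table, as.list(cells)))
    expect_true(e$prr_ci95[1] <= e$prr && e$prr <= e$prr_ci95[2])
    expect_true(e$ror_ci95[1] <= e$ror && e$ror <= e$ror_ci95[2])
    expect_lt(e$ic025, e$ic)
    expect_equal(e$ic > 0, e$n_cases + 0.5 > e$a_exp + 0.5)
    # PRR and ROR always deviate from 1 in the same direction
    expect_equal(sign(e$ror - 1), sign(e$prr - 1))
  }
})

test_that("ROR increases strictly in a with b, c, d fixed", {
  rors <- vapply(5:30, function(a) {
    compute_signal_estimates(contingency_table(a, 50, 70, 900))$ror
  }, numeric(1))
  expect_true(all(diff(rors) > 0))
})

test_that("signal rule criteria follow the published verdicts", {
  ola <- evaluate_signal(
    compute_signal_estimates(contingency_table(495, 2288, 18529, 293590)))
  expect_true(ola$criterion1 && ola$criterion2 && ola$criterion3)
  expect_true(ola$signal)
  expect_true(evaluate_signal(
    compute_signal_estimates(contingency_table(495, 2288, 18529, 293590)),
    rule = "ALL")$signal)

  nira <- evaluate_signal(
    compute_signal_estimates(contingency_table(607, 3482, 147133, 228418)))
  expect_false(nira$criterion1 || nira$criterion2 || nira$criterion3)
  expect_false(nira$signal)
})

test_that("stratified analysis partitions the age-known universe", {
  withr::local_seed(21)
  cfg <- synthetic_config(21, list(
    FAERS_LIKE = synthetic_db_config(4000, uniform_weights())))
  gen <- generate_reports(cfg)
  cohort <- deduplicate(apply_cohort_filters(gen$reports$FAERS_LIKE),
                        "WITHIN_DATABASE")
  res <- stratified_signals(cohort)
  expect_setequal(names(res$strata), c("AGE_GE_65", "AGE_LT_65"))
  expect_equal(res$excluded, sum(is.na(cohort$age_years)))

  known <- cohort[!is.na(cohort$age_years), ]
  whole <- signal_table(known, universe_label = "KNOWN")
  summed <- res$strata[[1]][, c("a", "b", "c", "d")] +
    res$strata[[2]][, c("a", "b", "c", "d")]
  expect_equal(as.data.frame(summed),
               as.data.frame(whole[, c("a", "b", "c", "d")]))

  # degenerate stratification: single stratum when all ages are on one side
  old <- cohort
  old$age_years <- 70
  res1 <- stratified_signals(old)
  expect_equal(names(res1$strata), "AGE_GE_65")
})

test_that("strata generated under identical rates give compatible RORs", {
  cfg <- synthetic_config(31, list(
    FAERS_LIKE = synthetic_db_config(
      12000, uniform_weights(),
      ild_prob = setNames(c(0.08, rep(0.02, 12)), study_drugs()),
      missingness = c(age_years = 0))))
  gen <- generate_reports(cfg)
  cohort <- deduplicate(apply_cohort_filters(gen$reports$FAERS_LIKE),
                        "WITHIN_DATABASE")
  res <- stratified_signals(cohort, drugs = "olaparib")
  t1 <- res$strata[[1]]; t2 <- res$strata[[2]]
  # each stratum's point estimate inside the other's 95% CI
  expect_gt(t1$ror, t2$ror_ci_low); expect_lt(t1$ror, t2$ror_ci_high)
  expect_gt(t2$ror, t1$ror_ci_low); expect_lt(t2$ror, t1$ror_ci_high)
})

test_that("the 95% ROR interval excludes 1 about 5% of the time under the null", {
  withr::local_seed(555)
  n_rep <- 2000
  excl <- logical(n_rep)
  p_drug <- 0.10; p_ev <- 0.06; n <- 4000
  probs <- c(p_drug * p_ev, (1 - p_drug) * p_ev,
             p_drug * (1 - p_ev), (1 - p_drug) * (1 - p_ev))
  draws <- rmultinom(n_rep, n, probs)
  for (i in seq_len(n_rep)) {
    e <- compute_signal_estimates(
      contingency_table(draws[1, i], draws[2, i], draws[3, i], draws[4, i]))
    excl[i] <- e$defined && (e$ror_ci95[1] > 1 || e$ror_ci95[2] < 1)
  }
  expect_gt(mean(excl), 0.03)
  expect_lt(mean(excl), 0.07)
})
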