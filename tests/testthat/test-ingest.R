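# Hand-written dialect fixtures (independent of write_reports) exercise
# the readers; generator round-trips exercise the writer/reader pair.

write_faers_fixture <- function(dir, delim = "\t") {
  j <- function(...) paste(..., sep = delim)
  writeLines(c(
    j("primaryid", "age", "age_cod", "wt", "occr_country", "event_dt",
      "serious", "outcome"),
    j("1001", "780", "MON", "62", "US", "2023-04-01", "Y", "RECOVERED"),
    j("1002", "58", "YR", "", "JP", "2022-11-30", "N", ""),
    j("1003", "7", "DEC", "55", "FR", "not-a-date", "Y", "DEATH")),
    file.path(dir, "demo.txt"))
  writeLines(c(
    j("primaryid", "drug_seq", "role_cod", "drugname"),
    j("1001", "1", "PS", "Lynparza"),
    j("1002", "1", "PS", "paclitaxel"),
    j("1002", "2", "C", "bevacizumab"),
    j("1003", "1", "PS", "unlisted compound")),
    file.path(dir, "drug.txt"))
  writeLines(c(
    j("primaryid", "pt"),
    j("1001", "Interstitial lung disease"),
    j("1002", "Nausea"),
    j("1002", "Pneumonitis"),
    j("1003", "Anaemia")),
    file.path(dir, "reac.txt"))
  writeLines(c(
    j("primaryid", "outc_cod"),
    j("1001", "HO"),
    j("1003", "DE")),
    file.path(dir, "outc.txt"))
  writeLines(c(
    j("primaryid", "indi_drug_seq", "indi_pt"),
    j("1001", "1", "Ovarian cancer"),
    j("1002", "1", "Breast cancer")),
    file.path(dir, "indi.txt"))
  c(demo = file.path(dir, "demo.txt"), drug = file.path(dir, "drug.txt"),
    reac = file.path(dir, "reac.txt"), outc = file.path(dir, "outc.txt"),
    indi = file.path(dir, "indi.txt"))
}

test_that("FAERS-like reader harmonizes ages, roles, synonyms and criteria", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir)
  rs <- read_reports(paths, "FAERS_LIKE")
  expect_s3_class(rs, "report_set")
  expect_equal(nrow(rs), 4)  # one row per drug-table row

  r1 <- rs[rs$report_id == "1001", ]
  expect_equal(r1$age_years, 65)            # 780 months
  expect_equal(r1$drug_name, "olaparib")    # trade synonym mapped
  expect_true(r1$drug_mapped)
  expect_equal(r1$drug_role, "PRIMARY_SUSPECT")
  expect_equal(r1$indication, "Ovarian cancer")
  expect_equal(r1$seriousness_criteria[[1]], "HOSPITALIZATION")

  r3 <- rs[rs$report_id == "1003", ]
  expect_equal(r3$age_years, 70)            # 7 decades
  expect_true(is.na(r3$event_date))         # unparseable date -> missing
  expect_false(r3$drug_mapped)              # unmapped retained verbatim
  expect_equal(r3$drug_name, "unlisted compound")
  expect_match(paste(provenance(rs), collapse = " "),
               "unparseable field values set missing: 1")

  # multi-drug report keeps per-row roles and shares report fields
  r2 <- rs[rs$report_id == "1002", ]
  expect_equal(nrow(r2), 2)
  expect_setequal(r2$drug_role, c("PRIMARY_SUSPECT", "CONCOMITANT"))
  expect_setequal(r2$event_terms[[1]], c("Nausea", "Pneumonitis"))
})

test_that("dollar-delimited FAERS-style files parse via the delimiter flag", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir, delim = "$")
  rs <- read_reports(paths, "FAERS_LIKE", delim = "$")
  expect_equal(nrow(rs), 4)
  expect_equal(rs$age_years[rs$report_id == "1001"], 65)
})

test_that("a missing mandatory column is a hard error naming it", {
  dir <- withr::local_tempdir()
  paths <- write_faers_fixture(dir)
  demo <- readLines(paths["demo"])
  writeLines(gsub("age_cod", "age_code", demo), paths["demo"])
  expect_error(read_reports(paths, "FAERS_LIKE"), "age_cod")
  expect_error(read_reports(paths, "FAERS_LIKE"), "FAERS_LIKE")
})

test_that("CVAR-like and JADER-like dialects harmonize to the same model", {
  dir <- withr::local_tempdir()
  writeLines(c(
    paste("report_id,age_y,weight_kg,country,event_date,drug_name,drug_role",
          "indication,reactions,serious,seriousness_criteria,outcome",
          sep = ","),
    "C1,66,70,CA,2023-04-01,Avastin,PRIMARY_SUSPECT,Ovarian cancer,Pneumonitis;Nausea,Y,HOSPITALIZATION,RECOVERING",
    "C2,59,,CA,,cisplatin,CONCOMITANT,Breast cancer,Anaemia,N,,"),
    file.path(dir, "cvar.csv"))
  rs <- read_reports(file.path(dir, "cvar.csv"), "CVAR_LIKE")
  expect_equal(nrow(rs), 2)
  expect_equal(rs$drug_name[1], "bevacizumab")
  expect_setequal(rs$event_terms[[1]], c("Pneumonitis", "Nausea"))
  expect_true(rs$serious[1])
  expect_true(is.na(rs$weight_kg[2]))

  writeLines(c("report_id\tage_years\tweight_kg\tevent_date\toutcome",
               "J1\t71\t48\t2022-06-15\tDEATH"),
             file.path(dir, "demo.tsv"))
  writeLines(c("report_id\tdrug_name\tdrug_role\tindication",
               "J1\tolaparib\tPRIMARY_SUSPECT\tOvarian cancer"),
             file.path(dir, "drug.tsv"))
  writeLines(c("report_id\tpt", "J1\tInterstitial lung disease"),
             file.path(dir, "reac.tsv"))
  rj <- read_reports(c(demo = file.path(dir, "demo.tsv"),
                       drug = file.path(dir, "drug.tsv"),
                       reac = file.path(dir, "reac.tsv")), "JADER_LIKE")
  expect_equal(rj$country, "JP")           # dialect carries no country
  expect_true(is.na(rj$serious))
  expect_equal(rj$outcome, "DEATH")
})

test_that("write_reports / read_reports round-trips every dialect", {
  cfg <- synthetic_config(301, list(
    FAERS_LIKE = synthetic_db_config(120, uniform_weights()),
    CVAR_LIKE = synthetic_db_config(60, uniform_weights()),
    JADER_LIKE = synthetic_db_config(60, uniform_weights())))
  dir <- withr::local_tempdir()
  gen <- generate_reports(cfg, dir = dir)
  cols <- setdiff(names(gen$reports$FAERS_LIKE),
                  "source_row")  # row ids are file positions after reread
  for (dbn in names(gen$reports)) {
    rr <- read_reports(gen$files[[dbn]], dbn)
    orig <- tibble::as_tibble(gen$reports[[dbn]])[cols]
    back <- tibble::as_tibble(rr)[cols]
    expect_equal(back, orig, ignore_attr = TRUE,
                 label = paste("reread", dbn))
  }
})

test_that("reader row count agrees with the generator's emitted count", {
  cfg <- synthetic_config(302, list(
    FAERS_LIKE = synthetic_db_config(1000, uniform_weights(),
                                     dup_within_rate = 0.05)))
  dir <- withr::local_tempdir()
  gen <- generate_reports(cfg, dir = dir)
  rs <- read_reports(gen$files$FAERS_LIKE, "FAERS_LIKE")
  expect_equal(nrow(rs), gen$ground_truth$emitted$n_rows[1])
  expect_equal(nrow(rs), 1050)
})
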