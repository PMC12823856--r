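#' Read spontaneous-report files in one of three database dialects
#'
#' Parses delimited text extracts into the harmonized [report_set()] model,
#' one row per (report, drug-table row). Drug names are mapped to canonical
#' vocabulary names (unmapped names are retained verbatim and flagged via
#' `drug_mapped = FALSE`); FAERS-like ages are normalized to years from
#' their unit codes. Unparseable numbers/dates become missing fields and
#' are counted in the provenance; a missing mandatory column is a hard
#' error naming the column and dialect.
#'
#' @section Dialect schemas:
#' All files are delimited text with a header row; dates are ISO 8601.
#'
#' * `FAERS_LIKE` — five tables joined on `primaryid`, `paths` named
#'   `demo`, `drug`, `reac` (mandatory) and `outc`, `indi` (optional).
#'   `demo`: `primaryid, age, age_cod, wt, occr_country, event_dt,
#'   serious, outcome` with `age_cod` in YR/DEC/MON/WK/DY and `serious`
#'   Y/N/blank. `drug`: `primaryid, drug_seq, role_cod, drugname` with
#'   `role_cod` in PS/SS/C/I. `reac`: `primaryid, pt`. `outc`:
#'   `primaryid, outc_cod` with codes DE/LT/HO/DS/OT. `indi`:
#'   `primaryid, indi_drug_seq, indi_pt`. Default delimiter is tab; the
#'   `"$"`-delimited variant is accepted via `delim = "$"`.
#' * `CVAR_LIKE` — a single wide table (default comma-delimited):
#'   `report_id, age_y, weight_kg, country, event_date, drug_name,
#'   drug_role, indication, reactions, serious, seriousness_criteria,
#'   outcome`, where `reactions` and `seriousness_criteria` are
#'   semicolon-separated and `drug_role` uses the harmonized role words.
#' * `JADER_LIKE` — three tab-delimited tables joined on `report_id`,
#'   `paths` named `demo`, `drug`, `reac`. `demo`: `report_id, age_years,
#'   weight_kg, event_date, outcome`. `drug`: `report_id, drug_name,
#'   drug_role, indication`. `reac`: `report_id, pt`. The dialect carries
#'   no country or seriousness fields: country is fixed to `"JP"`,
#'   `serious` is missing.
#'
#' @param paths Named character vector/list of file paths (see schemas);
#'   a single unnamed path for `CVAR_LIKE`.
#' @param dialect One of [PV_DATABASES].
#' @param vocabulary A [drug_vocabulary()] used for canonical mapping.
#' @param delim Field delimiter; defaults to tab (comma for `CVAR_LIKE`).
#' @return A [report_set()]; reports without any reaction row are dropped
#'   and counted in the provenance.
#' @export
read_reports <- function(paths, dialect, vocabulary = default_drug_vocabulary(),
                         delim = NULL) {
  dialect <- match.arg(dialect, PV_DATABASES)
  out <- switch(dialect,
    FAERS_LIKE = read_faers_like(paths, delim %||% "\t"),
    CVAR_LIKE  = read_cvar_like(paths, delim %||% ","),
    JADER_LIKE = read_jader_like(paths, delim %||% "\t"))
  tbl <- out$reports
  canon <- match_drug(tbl$drug_verbatim, vocabulary)
  tbl$drug_mapped <- !is.na(canon)
  tbl$drug_name <- ifelse(tbl$drug_mapped, canon, tbl$drug_verbatim)
  tbl <- tbl[report_set_columns()]
  report_set(tbl, provenance = out$provenance)
}

read_delim_chr <- function(path, delim, mandatory, dialect) {
  df <- readr::read_delim(path, delim = delim,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE, trim_ws = TRUE,
                          na = character(0))
  miss <- setdiff(mandatory, names(df))
  assert_that(length(miss) == 0,
              paste0("dialect ", dialect, ": file '", basename(path),
                     "' lacks mandatory column(s): ",
                     paste(miss, collapse = ", ")))
  df
}

blank_to_na <- function(x) ifelse(is.na(x) | !nzchar(trimws(x)), NA_character_, trimws(x))

# Lenient field parsers: unparseable values become NA and are tallied so
# read_reports can report a parse-warning count in the provenance.
parse_num_field <- function(x) {
  x <- blank_to_na(x)
  v <- suppressWarnings(as.numeric(x))
  list(values = v, n_bad = sum(!is.na(x) & is.na(v)))
}

parse_date_field <- function(x) {
  x <- blank_to_na(x)
  v <- as.Date(rep(NA_character_, length(x)))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  v[ok] <- as.Date(x[ok], format = "%Y-%m-%d")
  list(values = v, n_bad = sum(!is.na(x) & (is.na(v) | !ok)))
}

parse_outcome_field <- function(x) {
  x <- toupper(blank_to_na(x))
  bad <- !is.na(x) & !(x %in% PV_OUTCOMES)
  x[bad] <- NA_character_
  list(values = x, n_bad = sum(bad))
}

# FAERS-like age-unit normalization: ages arrive with a unit code and are
# converted to years; unknown units yield a missing age.
convert_age_years <- function(age, age_cod) {
  unit <- toupper(blank_to_na(age_cod))
  factor <- rep(NA_real_, length(age))
  factor[unit == "YR"] <- 1
  factor[unit == "DEC"] <- 10
  factor[unit == "MON"] <- 1 / 12
  factor[unit == "WK"] <- 7 / 365.25
  factor[unit == "DY"] <- 1 / 365.25
  factor[is.na(unit)] <- 1  # unitless ages are taken as years
  age * factor
}

faers_role_map <- c(PS = "PRIMARY_SUSPECT", SS = "SECONDARY_SUSPECT",
                    C = "CONCOMITANT", I = "INTERACTING")
faers_outc_map <- c(DE = "DEATH", LT = "LIFE_THREATENING",
                    HO = "HOSPITALIZATION", DS = "DISABILITY", OT = "OTHER")

read_faers_like <- function(paths, delim) {
  paths <- as.list(paths)
  for (p in c("demo", "drug", "reac")) {
    assert_that(!is.null(paths[[p]]),
                paste0("dialect FAERS_LIKE: paths must name a '", p, "' file"))
  }
  demo <- read_delim_chr(paths$demo, delim,
                         c("primaryid", "age", "age_cod", "wt",
                           "occr_country", "event_dt", "serious", "outcome"),
                         "FAERS_LIKE")
  drug <- read_delim_chr(paths$drug, delim,
                         c("primaryid", "drug_seq", "role_cod", "drugname"),
                         "FAERS_LIKE")
  reac <- read_delim_chr(paths$reac, delim, c("primaryid", "pt"), "FAERS_LIKE")

  n_bad <- 0L
  age_raw <- parse_num_field(demo$age); n_bad <- n_bad + age_raw$n_bad
  wt <- parse_num_field(demo$wt); n_bad <- n_bad + wt$n_bad
  dt <- parse_date_field(demo$event_dt); n_bad <- n_bad + dt$n_bad
  outc_field <- parse_outcome_field(demo$outcome); n_bad <- n_bad + outc_field$n_bad

  demo_h <- tibble::tibble(
    report_id = demo$primaryid,
    age_years = convert_age_years(age_raw$values, demo$age_cod),
    weight_kg = wt$values,
    country = blank_to_na(demo$occr_country),
    event_date = dt$values,
    serious = c("N" = FALSE, "Y" = TRUE)[toupper(blank_to_na(demo$serious))],
    outcome = outc_field$values)

  terms <- split(reac$pt, reac$primaryid)

  crit <- list()
  if (!is.null(paths$outc)) {
    outc <- read_delim_chr(paths$outc, delim, c("primaryid", "outc_cod"),
                           "FAERS_LIKE")
    codes <- unname(faers_outc_map[toupper(blank_to_na(outc$outc_cod))])
    keep <- !is.na(codes)
    crit <- lapply(split(codes[keep], outc$primaryid[keep]), unique)
  }

  indi_key <- character(0); indi_val <- character(0)
  if (!is.null(paths$indi)) {
    indi <- read_delim_chr(paths$indi, delim,
                           c("primaryid", "indi_drug_seq", "indi_pt"),
                           "FAERS_LIKE")
    indi_key <- paste(indi$primaryid, indi$indi_drug_seq, sep = "\r")
    indi_val <- blank_to_na(indi$indi_pt)
  }

  i <- match(drug$primaryid, demo_h$report_id)
  tbl <- demo_h[i, ]
  tbl$report_id <- drug$primaryid
  tbl$drug_verbatim <- trimws(drug$drugname)
  role <- unname(faers_role_map[toupper(blank_to_na(drug$role_cod))])
  role[is.na(role)] <- "CONCOMITANT"
  tbl$drug_role <- role
  tbl$indication <- indi_val[match(paste(drug$primaryid, drug$drug_seq, sep = "\r"),
                                   indi_key)]
  tbl$event_terms <- unname(terms[drug$primaryid])
  tbl$event_terms[vapply(tbl$event_terms, is.null, logical(1))] <- list(character(0))
  cr <- unname(crit[drug$primaryid])
  cr[vapply(cr, is.null, logical(1))] <- list(character(0))
  tbl$seriousness_criteria <- cr
  tbl$serious <- tbl$serious | lengths(cr) > 0
  tbl$database <- "FAERS_LIKE"
  tbl$source_row <- sprintf("%s:%06d", basename(paths$drug), seq_len(nrow(drug)))

  finalize_read(tbl, n_bad,
                files = vapply(paths, basename, character(1)),
                dialect = "FAERS_LIKE")
}

read_cvar_like <- function(paths, delim) {
  path <- if (is.list(paths) || length(paths) > 1) paths[[1]] else paths
  df <- read_delim_chr(path, delim,
                       c("report_id", "age_y", "weight_kg", "country",
                         "event_date", "drug_name", "drug_role", "indication",
                         "reactions", "serious", "seriousness_criteria",
                         "outcome"),
                       "CVAR_LIKE")
  n_bad <- 0L
  age <- parse_num_field(df$age_y); n_bad <- n_bad + age$n_bad
  wt <- parse_num_field(df$weight_kg); n_bad <- n_bad + wt$n_bad
  dt <- parse_date_field(df$event_date); n_bad <- n_bad + dt$n_bad
  outc <- parse_outcome_field(df$outcome); n_bad <- n_bad + outc$n_bad
  role <- toupper(blank_to_na(df$drug_role))
  role[!role %in% PV_DRUG_ROLES] <- "CONCOMITANT"
  crit <- lapply(df$seriousness_criteria, function(s) {
    v <- toupper(split_multi(if (is.na(s)) "" else s))
    intersect(v, PV_SERIOUSNESS_CRITERIA)
  })
  tbl <- tibble::tibble(
    report_id = df$report_id,
    database = "CVAR_LIKE",
    age_years = age$values,
    weight_kg = wt$values,
    country = blank_to_na(df$country),
    event_date = dt$values,
    drug_verbatim = trimws(df$drug_name),
    drug_role = role,
    indication = blank_to_na(df$indication),
    event_terms = lapply(df$reactions, function(s) split_multi(if (is.na(s)) "" else s)),
    serious = c("N" = FALSE, "Y" = TRUE)[toupper(blank_to_na(df$serious))],
    seriousness_criteria = crit,
    outcome = outc$values,
    source_row = sprintf("%s:%06d", basename(path), seq_len(nrow(df))))
  tbl$serious <- tbl$serious | lengths(crit) > 0
  finalize_read(tbl, n_bad, files = basename(path), dialect = "CVAR_LIKE")
}

read_jader_like <- function(paths, delim) {
  paths <- as.list(paths)
  for (p in c("demo", "drug", "reac")) {
    assert_that(!is.null(paths[[p]]),
                paste0("dialect JADER_LIKE: paths must name a '", p, "' file"))
  }
  demo <- read_delim_chr(paths$demo, delim,
                         c("report_id", "age_years", "weight_kg",
                           "event_date", "outcome"), "JADER_LIKE")
  drug <- read_delim_chr(paths$drug, delim,
                         c("report_id", "drug_name", "drug_role", "indication"),
                         "JADER_LIKE")
  reac <- read_delim_chr(paths$reac, delim, c("report_id", "pt"), "JADER_LIKE")

  n_bad <- 0L
  age <- parse_num_field(demo$age_years); n_bad <- n_bad + age$n_bad
  wt <- parse_num_field(demo$weight_kg); n_bad <- n_bad + wt$n_bad
  dt <- parse_date_field(demo$event_date); n_bad <- n_bad + dt$n_bad
  outc <- parse_outcome_field(demo$outcome); n_bad <- n_bad + outc$n_bad

  demo_h <- tibble::tibble(
    report_id = demo$report_id, age_years = age$values,
    weight_kg = wt$values, event_date = dt$values, outcome = outc$values)
  terms <- split(reac$pt, reac$report_id)

  i <- match(drug$report_id, demo_h$report_id)
  tbl <- demo_h[i, ]
  tbl$report_id <- drug$report_id
  tbl$database <- "JADER_LIKE"
  tbl$country <- "JP"
  tbl$drug_verbatim <- trimws(drug$drug_name)
  role <- toupper(blank_to_na(drug$drug_role))
  role[!role %in% PV_DRUG_ROLES] <- "CONCOMITANT"
  tbl$drug_role <- role
  tbl$indication <- blank_to_na(drug$indication)
  tbl$event_terms <- unname(terms[drug$report_id])
  tbl$event_terms[vapply(tbl$event_terms, is.null, logical(1))] <- list(character(0))
  tbl$serious <- NA
  tbl$seriousness_criteria <- rep(list(character(0)), nrow(tbl))
  tbl$source_row <- sprintf("%s:%06d", basename(paths$drug), seq_len(nrow(drug)))
  finalize_read(tbl, n_bad,
                files = vapply(paths, basename, character(1)),
                dialect = "JADER_LIKE")
}

finalize_read <- function(tbl, n_bad, files, dialect) {
  no_event <- lengths(tbl$event_terms) == 0
  tbl <- tbl[!no_event, ]
  prov <- c(
    paste0("read_reports[", dialect, "]: files ", paste(files, collapse = ", ")),
    paste0("  drug rows read: ", nrow(tbl) + sum(no_event),
           "; dropped (no reaction rows): ", sum(no_event),
           "; unparseable field values set missing: ", n_bad))
  list(reports = tbl, provenance = prov)
}

#' Write a report set as dialect files
#'
#' Inverse of [read_reports()]: serializes a harmonized [report_set()]
#' into the file layout of one dialect (see the schema section of
#' [read_reports()]). Fields the dialect does not carry (e.g. country and
#' seriousness for `JADER_LIKE`) are not preserved. Used by the synthetic
#' generator and for round-trip checks.
#'
#' @param reports A [report_set()] whose rows all belong to `dialect`.
#' @param dir Output directory (created if needed).
#' @param dialect One of [PV_DATABASES].
#' @param delim Field delimiter; defaults as in [read_reports()].
#' @param prefix File-name prefix.
#' @return Named character vector of written file paths, suitable as the
#'   `paths` argument of [read_reports()].
#' @export
write_reports <- function(reports, dir, dialect, delim = NULL, prefix = "reports") {
  dialect <- match.arg(dialect, PV_DATABASES)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  x <- tibble::as_tibble(reports)
  fmt_date <- function(d) ifelse(is.na(d), "", format(d, "%Y-%m-%d"))
  fmt_num <- function(v) ifelse(is.na(v), "", format(v, trim = TRUE, digits = 15))
  fmt_chr <- function(v) ifelse(is.na(v), "", v)
  role_rev <- setNames(names(faers_role_map), faers_role_map)
  crit_rev <- setNames(names(faers_outc_map), faers_outc_map)

  if (dialect == "FAERS_LIKE") {
    delim <- delim %||% "\t"
    # one demo row per report (first drug row's demographics are
    # authoritative; the generator emits identical demographics per report)
    first <- !duplicated(x$report_id)
    demo <- tibble::tibble(
      primaryid = x$report_id[first],
      age = fmt_num(x$age_years[first]),
      age_cod = ifelse(is.na(x$age_years[first]), "", "YR"),
      wt = fmt_num(x$weight_kg[first]),
      occr_country = fmt_chr(x$country[first]),
      event_dt = fmt_date(x$event_date[first]),
      serious = ifelse(is.na(x$serious[first]), "",
                       ifelse(x$serious[first], "Y", "N")),
      outcome = fmt_chr(x$outcome[first]))
    seq_in_report <- stats::ave(seq_len(nrow(x)), x$report_id,
                                FUN = seq_along)
    drug <- tibble::tibble(
      primaryid = x$report_id, drug_seq = seq_in_report,
      role_cod = unname(role_rev[x$drug_role]),
      drugname = x$drug_verbatim)
    reac <- tidyr::unnest(
      tibble::tibble(primaryid = x$report_id[first],
                     pt = x$event_terms[first]), "pt")
    outc <- tidyr::unnest(
      tibble::tibble(primaryid = x$report_id[first],
                     outc_cod = lapply(x$seriousness_criteria[first],
                                       function(v) unname(crit_rev[v]))),
      "outc_cod")
    indi <- tibble::tibble(primaryid = x$report_id,
                           indi_drug_seq = seq_in_report,
                           indi_pt = fmt_chr(x$indication))
    paths <- c(demo = file.path(dir, paste0(prefix, "_demo.txt")),
               drug = file.path(dir, paste0(prefix, "_drug.txt")),
               reac = file.path(dir, paste0(prefix, "_reac.txt")),
               outc = file.path(dir, paste0(prefix, "_outc.txt")),
               indi = file.path(dir, paste0(prefix, "_indi.txt")))
    readr::write_delim(demo, paths["demo"], delim = delim)
    readr::write_delim(drug, paths["drug"], delim = delim)
    readr::write_delim(reac, paths["reac"], delim = delim)
    readr::write_delim(outc, paths["outc"], delim = delim)
    readr::write_delim(indi, paths["indi"], delim = delim)
    return(paths)
  }

  if (dialect == "CVAR_LIKE") {
    delim <- delim %||% ","
    df <- tibble::tibble(
      report_id = x$report_id,
      age_y = fmt_num(x$age_years),
      weight_kg = fmt_num(x$weight_kg),
      country = fmt_chr(x$country),
      event_date = fmt_date(x$event_date),
      drug_name = x$drug_verbatim,
      drug_role = x$drug_role,
      indication = fmt_chr(x$indication),
      reactions = vapply(x$event_terms, join_multi, character(1)),
      serious = ifelse(is.na(x$serious), "", ifelse(x$serious, "Y", "N")),
      seriousness_criteria = vapply(x$seriousness_criteria, join_multi,
                                    character(1)),
      outcome = fmt_chr(x$outcome))
    path <- c(cvar = file.path(dir, paste0(prefix, ".csv")))
    readr::write_delim(df, path, delim = delim)
    return(path)
  }

  # JADER_LIKE
  delim <- delim %||% "\t"
  first <- !duplicated(x$report_id)
  demo <- tibble::tibble(
    report_id = x$report_id[first],
    age_years = fmt_num(x$age_years[first]),
    weight_kg = fmt_num(x$weight_kg[first]),
    event_date = fmt_date(x$event_date[first]),
    outcome = fmt_chr(x$outcome[first]))
  drug <- tibble::tibble(report_id = x$report_id,
                         drug_name = x$drug_verbatim,
                         drug_role = x$drug_role,
                         indication = fmt_chr(x$indication))
  reac <- tidyr::unnest(
    tibble::tibble(report_id = x$report_id[first],
                   pt = x$event_terms[first]), "pt")
  paths <- c(demo = file.path(dir, paste0(prefix, "_demo.tsv")),
             drug = file.path(dir, paste0(prefix, "_drug.tsv")),
             reac = file.path(dir, paste0(prefix, "_reac.tsv")))
  readr::write_delim(demo, paths["demo"], delim = delim)
  readr::write_delim(drug, paths["drug"], delim = delim)
  readr::write_delim(reac, paths["reac"], delim = delim)
  paths
}
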