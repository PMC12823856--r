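#' Drug vocabulary: canonical names, classes and synonyms
#'
#' A vocabulary maps verbatim drug strings (generic and trade names) onto
#' canonical study-drug names and assigns each canonical name a drug class.
#' Matching is case-insensitive after whitespace normalization. Synonym sets
#' must be pairwise disjoint across canonical names, so any verbatim string
#' resolves to at most one canonical drug.
#'
#' @param entries Named list: canonical name -> character vector of synonyms
#'   (the canonical name itself is always accepted and need not be listed).
#' @param class Named character vector: canonical name -> one of
#'   [PV_DRUG_CLASSES].
#' @return An object of class `drug_vocabulary`.
#' @seealso [default_drug_vocabulary()], [read_vocabulary()]
#' @export
drug_vocabulary <- function(entries, class) {
  assert_that(is.list(entries) && length(entries) > 0 && !is.null(names(entries)),
              "entries must be a non-empty named list")
  canon <- names(entries)
  assert_that(all(canon %in% names(class)),
              "every canonical name needs a class entry")
  bad <- setdiff(unname(class[canon]), PV_DRUG_CLASSES)
  assert_that(length(bad) == 0,
              paste0("unknown drug class: ", paste(bad, collapse = ", ")))
  lookup <- character(0)
  for (cn in canon) {
    terms <- unique(normalize_term(c(cn, entries[[cn]])))
    clash <- intersect(terms, names(lookup))
    assert_that(length(clash) == 0,
                paste0("synonym(s) mapped to more than one canonical name: ",
                       paste(clash, collapse = ", ")))
    lookup[terms] <- cn
  }
  structure(
    list(entries = entries, class = class[canon], lookup = lookup),
    class = "drug_vocabulary"
  )
}

#' @export
print.drug_vocabulary <- function(x, ...) {
  cat("<drug_vocabulary> ", length(x$entries), " canonical drugs, ",
      length(x$lookup), " match terms\n", sep = "")
  tab <- table(x$class)
  cat("  classes:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Canonical drug names in a vocabulary
#' @param vocabulary A [drug_vocabulary()].
#' @return Character vector of canonical names.
#' @export
vocabulary_drugs <- function(vocabulary) names(vocabulary$entries)

#' Map verbatim drug strings to canonical names
#'
#' @param x Character vector of verbatim drug names.
#' @param vocabulary A [drug_vocabulary()].
#' @return Character vector: canonical name where matched, `NA` otherwise.
#' @export
match_drug <- function(x, vocabulary) {
  unname(vocabulary$lookup[normalize_term(x)])
}

#' Built-in study-drug vocabulary
#'
#' Thirteen FDA-approved drugs used in ovarian-cancer regimens: five novel
#' antineoplastic agents (three PARP inhibitors, one monoclonal antibody,
#' one antibody-drug conjugate) and eight conventional chemotherapy agents,
#' with common trade-name synonyms. Shipped as an editable CSV in
#' `inst/extdata/drug_vocabulary.csv`.
#'
#' @return A [drug_vocabulary()].
#' @export
default_drug_vocabulary <- function() {
  read_vocabulary(system.file("extdata", "drug_vocabulary.csv",
                              package = "pvsignal", mustWork = TRUE))
}

#' Read a drug vocabulary from CSV
#'
#' Expected columns: `canonical`, `class`, `synonyms` (semicolon-separated,
#' may be empty).
#'
#' @param path Path to the CSV file.
#' @return A [drug_vocabulary()].
#' @export
read_vocabulary <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  for (col in c("canonical", "class")) {
    assert_that(col %in% names(df),
                paste0("vocabulary file lacks mandatory column '", col, "'"))
  }
  syn <- if ("synonyms" %in% names(df)) df$synonyms else rep("", nrow(df))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    s <- syn[i]
    if (is.na(s)) character(0) else split_multi(s)
  })
  names(entries) <- df$canonical
  drug_vocabulary(entries, setNames(df$class, df$canonical))
}

# SMQ ---------------------------------------------------------------------

#' Standardized MedDRA-query definition
#'
#' A named set of Preferred Terms (PTs) identifying an adverse-event class.
#' Term matching downstream is case-insensitive after whitespace
#' normalization.
#'
#' @param name Query name.
#' @param preferred_terms Non-empty character vector of PTs.
#' @param scope `"NARROW"` or `"BROAD"`.
#' @return An object of class `smq_definition`.
#' @export
smq_definition <- function(name, preferred_terms, scope = "NARROW") {
  assert_that(is.character(preferred_terms) && length(preferred_terms) > 0,
              "preferred_terms must be a non-empty character vector")
  scope <- match.arg(scope, c("NARROW", "BROAD"))
  structure(
    list(name = name, scope = scope,
         preferred_terms = unique(preferred_terms),
         term_keys = unique(normalize_term(preferred_terms))),
    class = "smq_definition"
  )
}

#' @export
print.smq_definition <- function(x, ...) {
  cat("<smq_definition> ", x$name, " [", x$scope, "], ",
      length(x$preferred_terms), " preferred terms\n", sep = "")
  invisible(x)
}

#' Does a set of event terms hit an SMQ?
#' @param terms Character vector of event Preferred Terms.
#' @param smq An [smq_definition()].
#' @return Single logical.
#' @export
smq_matches <- function(terms, smq) {
  any(normalize_term(terms) %in% smq$term_keys)
}

#' Built-in narrow interstitial-lung-disease query
#'
#' A default narrow-scope PT list for interstitial lung disease (ILD),
#' covering the terms commonly retrieved by the narrow ILD standardized
#' query. The licensed MedDRA dictionary is not bundled; the list ships as
#' an editable text file (`inst/extdata/smq_ild_narrow.txt`, one PT per
#' line, `#` comments) and should be replaced with the licensed term list
#' where available.
#'
#' @return An [smq_definition()].
#' @export
default_ild_smq <- function() {
  read_smq(system.file("extdata", "smq_ild_narrow.txt",
                       package = "pvsignal", mustWork = TRUE),
           name = "Interstitial lung disease (narrow)", scope = "NARROW")
}

#' Read an SMQ term list from a text file
#'
#' One Preferred Term per line; blank lines and lines starting with `#`
#' are ignored.
#'
#' @param path Path to the term-list file.
#' @inheritParams smq_definition
#' @return An [smq_definition()].
#' @export
read_smq <- function(path, name = basename(path), scope = "NARROW") {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  assert_that(length(lines) > 0, "SMQ term list is empty")
  smq_definition(name, lines, scope)
}

#' Default cohort indication terms
#'
#' Substring patterns (case-insensitive) for the ovarian, fallopian-tube
#' and primary-peritoneal cancer indications that define the cohort.
#'
#' @return Character vector of indication terms.
#' @export
default_indication_terms <- function() {
  c("ovarian cancer", "ovarian neoplasm", "ovarian epithelial cancer",
    "fallopian tube cancer", "fallopian tube neoplasm",
    "peritoneal cancer", "peritoneal neoplasm",
    "peritoneal carcinoma")
}
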