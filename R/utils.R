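#' Round half away from zero
#'
#' Fixed-digit rounding with halves carried away from zero, matching how
#' signal tables are conventionally displayed (base [round()] uses
#' round-half-even). Used for all 2-decimal display values.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` places.
#' @export
#' @examples
#' round_half_up(2.675, 2)  # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Case-insensitive, whitespace-normalized term key used for SMQ, vocabulary
# and indication matching.
normalize_term <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

# Collapse a character vector to a single ';'-separated field (inverse of
# split_multi); NA and empty entries dropped.
join_multi <- function(x) {
  x <- x[!is.na(x) & nzchar(x)]
  if (length(x) == 0) "" else paste(x, collapse = ";")
}

split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
}
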