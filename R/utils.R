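## internal helpers shared across modules

MISSING_TOKENS <- c("", "na", "nan")

is_missing_token <- function(x) {
  is.na(x) | tolower(trimws(as.character(x))) %in% MISSING_TOKENS
}

parse_num <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))   # exact; no string round trip
  x <- as.character(x)
  out <- suppressWarnings(as.numeric(x))
  out[is_missing_token(x)] <- NA_real_
  out
}

## complement of an allele string, base by base (multi-base alleles are
## complemented in place; they are never treated as palindromic anyway)
comp_allele <- function(a) {
  chartr("ACGT", "TGCA", toupper(a))
}

valid_allele <- function(a) {
  !is.na(a) & grepl("^[ACGT]+$", toupper(a))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

set_seed_if <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
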