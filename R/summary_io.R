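## Reading, validating and writing GWAS summary-statistic tables.
##
## A `gwas_table` is a data.frame with canonical columns
##   snp, effect_allele, other_allele, beta, se, eaf, pval, n
## plus phenotype metadata stored as attributes. Alleles are uppercased on
## construction; rows violating per-record invariants are dropped and logged
## in the `audit` attribute.

CANONICAL_COLUMNS <- c("SNP", "effect_allele", "other_allele", "beta", "se",
                       "eaf", "pval", "samplesize", "Phenotype", "units")

#' Describe how source columns map onto the canonical GWAS fields
#'
#' The canonical field names mirror a typical summary-statistic upload form:
#' `SNP`, `effect_allele`, `other_allele`, `beta`, `se`, `eaf`, `pval`,
#' `samplesize`, `Phenotype`, `units`. `snp`, `effect_allele`, `other_allele`,
#' `beta` and `se` must be mapped; the rest may be `NA` (unmapped), in which
#' case the corresponding field is missing for every record.
#'
#' @param snp,effect_allele,other_allele,beta,se Required source column names.
#' @param eaf,pval,n,phenotype,units Optional source column names, or `NA`.
#' @param delimiter Single-character field delimiter of the source file.
#' @return An object of class `column_mapping`.
#' @export
column_mapping <- function(snp = "SNP", effect_allele = "effect_allele",
                           other_allele = "other_allele", beta = "beta",
                           se = "se", eaf = "eaf", pval = "pval",
                           n = "samplesize", phenotype = "Phenotype",
                           units = "units", delimiter = "\t") {
  if (!is.character(delimiter) || nchar(delimiter) != 1L)
    stopf("delimiter must be a single character")
  req <- list(snp = snp, effect_allele = effect_allele,
              other_allele = other_allele, beta = beta, se = se)
  for (f in names(req)) {
    if (is.null(req[[f]]) || is.na(req[[f]]))
      stopf("required field '%s' must be mapped to a source column", f)
  }
  structure(list(snp = snp, effect_allele = effect_allele,
                 other_allele = other_allele, beta = beta, se = se,
                 eaf = eaf, pval = pval, n = n, phenotype = phenotype,
                 units = units, delimiter = delimiter),
            class = "column_mapping")
}

## per-row invariant scan; returns a character matrix of reasons (one column
## per invariant) so validate_gwas() can count every violation independently
## while the constructor drops on the first one
row_issues <- function(df) {
  n <- nrow(df)
  iss <- list(
    missing_snp_id   = is_missing_token(df$snp),
    invalid_allele   = !valid_allele(df$effect_allele) |
                       !valid_allele(df$other_allele),
    identical_alleles = toupper(as.character(df$effect_allele)) ==
                        toupper(as.character(df$other_allele)),
    missing_beta     = is.na(df$beta),
    nonpositive_se   = is.na(df$se) | df$se <= 0,
    eaf_out_of_range = !is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
    pval_out_of_range = !is.na(df$pval) & (df$pval < 0 | df$pval > 1),
    nonpositive_n    = !is.na(df$n) & df$n <= 0
  )
  iss$identical_alleles[is.na(iss$identical_alleles)] <- FALSE
  do.call(cbind, lapply(iss, function(x) { x[is.na(x)] <- TRUE; x }))
}

#' Construct a validated GWAS summary table
#'
#' Rows violating any per-record invariant (missing SNP id, invalid or
#' identical alleles, missing beta, non-positive standard error, `eaf` or
#' `pval` outside `[0, 1]`, non-positive sample size) are dropped and counted
#' in the audit log. Duplicate SNP ids keep the record with the smallest
#' p-value (missing p-values sort last); the rest are dropped and logged.
#'
#' @param df data.frame with columns `snp`, `effect_allele`, `other_allele`,
#'   `beta`, `se` and optionally `eaf`, `pval`, `n`.
#' @param phenotype_name,phenotype_id,units Phenotype metadata; `units` is
#'   recorded verbatim (the value `"log odds"` flags a binary trait).
#' @param sample_type `"continuous"` or `"binary"`.
#' @return A `gwas_table`: the validated data.frame with attributes
#'   `phenotype_name`, `phenotype_id`, `units`, `sample_type` and `audit`
#'   (a data.frame of dropped rows with reasons).
#' @export
gwas_table <- function(df, phenotype_name = "exposure",
                       phenotype_id = phenotype_name, units = "",
                       sample_type = c("continuous", "binary")) {
  sample_type <- match.arg(sample_type)
  for (col in c("snp", "effect_allele", "other_allele", "beta", "se")) {
    if (!col %in% names(df)) stopf("missing required column '%s'", col)
  }
  for (col in c("eaf", "pval", "n"))
    if (!col %in% names(df)) df[[col]] <- rep(NA_real_, nrow(df))
  df <- df[, c("snp", "effect_allele", "other_allele", "beta", "se",
               "eaf", "pval", "n"), drop = FALSE]
  df$snp <- as.character(df$snp)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in c("beta", "se", "eaf", "pval", "n")) df[[col]] <- parse_num(df[[col]])

  iss <- row_issues(df)
  bad <- rowSums(iss) > 0
  reasons <- apply(iss, 1L, function(r) paste(gsub("_", " ", colnames(iss)[r]),
                                              collapse = "; "))
  audit <- data.frame(snp = df$snp[bad], reason = reasons[bad],
                      stringsAsFactors = FALSE)
  df <- df[!bad, , drop = FALSE]

  ## duplicate snp ids: keep smallest pval (missing pval sorts last)
  if (anyDuplicated(df$snp)) {
    key <- ifelse(is.na(df$pval), Inf, df$pval)
    ord <- order(df$snp, key)
    dfo <- df[ord, , drop = FALSE]
    dup <- duplicated(dfo$snp)
    audit <- rbind(audit, data.frame(snp = dfo$snp[dup],
                                     reason = "duplicate snp id",
                                     stringsAsFactors = FALSE))
    keep_rows <- sort(ord[!dup])   # restore original order of survivors
    df <- df[keep_rows, , drop = FALSE]
  }
  rownames(df) <- NULL
  structure(df, class = c("gwas_table", "data.frame"),
            phenotype_name = phenotype_name, phenotype_id = phenotype_id,
            units = units, sample_type = sample_type, audit = audit)
}

#' Read a delimited GWAS summary-statistic file
#'
#' @param path Path to a delimited text file with a header row.
#' @param mapping A [column_mapping()]; unmapped optional fields yield missing
#'   values. The mapping's delimiter controls parsing.
#' @param phenotype_name,phenotype_id,units,sample_type Metadata overrides;
#'   when `NULL`, phenotype/units are taken from mapped columns if present.
#' @return A [gwas_table()].
#' @export
read_gwas <- function(path, mapping = column_mapping(),
                      phenotype_name = NULL, phenotype_id = NULL,
                      units = NULL, sample_type = "continuous") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.table(path, header = TRUE, sep = mapping$delimiter,
                           colClasses = "character", quote = "\"",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) stopf("empty file: %s", path)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se")
  for (f in required) {
    if (!mapping[[f]] %in% names(raw))
      stopf("mapped column '%s' (field %s) not found in header", mapping[[f]], f)
  }
  pick <- function(f) {
    col <- mapping[[f]]
    if (is.null(col) || is.na(col) || !col %in% names(raw))
      rep(NA_character_, nrow(raw)) else raw[[col]]
  }
  df <- data.frame(snp = pick("snp"), effect_allele = pick("effect_allele"),
                   other_allele = pick("other_allele"), beta = pick("beta"),
                   se = pick("se"), eaf = pick("eaf"), pval = pick("pval"),
                   n = pick("n"), stringsAsFactors = FALSE)
  phen <- pick("phenotype"); unit <- pick("units")
  name <- phenotype_name %||%
    (if (!all(is.na(phen)) && nrow(raw) > 0) phen[[1L]] else "trait")
  gwas_table(df,
             phenotype_name = name,
             phenotype_id = phenotype_id %||% name,
             units = units %||%
               (if (!all(is.na(unit)) && nrow(raw) > 0) unit[[1L]] else ""),
             sample_type = sample_type)
}

#' Validate a GWAS table and report per-invariant violation counts
#'
#' Reporting only: the table is not modified. Accepts either a raw data.frame
#' with canonical columns or a `gwas_table` (which, by construction, reports
#' all zeros except possibly duplicates already removed).
#'
#' @param table data.frame or `gwas_table`.
#' @return Named integer vector of violation counts, one per invariant, plus
#'   `duplicate_snp_id`.
#' @export
validate_gwas <- function(table) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  for (col in c("eaf", "pval", "n")) if (!col %in% names(df)) df[[col]] <- NA_real_
  df$effect_allele <- as.character(df$effect_allele)
  df$other_allele <- as.character(df$other_allele)
  for (col in c("beta", "se", "eaf", "pval", "n")) df[[col]] <- parse_num(df[[col]])
  iss <- row_issues(df)
  counts <- colSums(iss)
  c(counts, duplicate_snp_id = sum(duplicated(df$snp)))
}

#' Write a result or summary table as delimited text
#'
#' Numeric columns are written with full (15 significant digit) precision so
#' that read-write round trips are stable to below 1e-9 relative error.
#'
#' @param table data.frame (or `gwas_table`).
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param allow_empty Permit writing a header-only file for empty tables.
#' @return `path`, invisibly.
#' @export
write_mr_table <- function(table, path, format = c("tsv", "csv"),
                           allow_empty = FALSE) {
  format <- match.arg(format)
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  if (nrow(df) == 0L && !allow_empty)
    stopf("refusing to write an empty table (set allow_empty = TRUE)")
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = NA))
  })
  sep <- if (format == "tsv") "\t" else ","
  ok <- tryCatch({
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
                       na = "NA")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stopf("cannot write to path: %s", path)
  invisible(path)
}

#' Write a GWAS table (with metadata columns) as delimited text
#'
#' Emits the canonical upload-form column names (`SNP`, `effect_allele`,
#' `other_allele`, `beta`, `se`, `eaf`, `pval`, `samplesize`, `Phenotype`,
#' `units`) so the file can be re-read with the default [column_mapping()].
#'
#' @inheritParams write_mr_table
#' @param table A `gwas_table`.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(table, path, format = c("tsv", "csv"),
                       allow_empty = FALSE) {
  stopifnot(inherits(table, "gwas_table"))
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  out <- data.frame(SNP = df$snp, effect_allele = df$effect_allele,
                    other_allele = df$other_allele, beta = df$beta,
                    se = df$se, eaf = df$eaf, pval = df$pval,
                    samplesize = df$n,
                    Phenotype = rep(attr(table, "phenotype_name"), nrow(df)),
                    units = rep(attr(table, "units"), nrow(df)),
                    stringsAsFactors = FALSE)
  write_mr_table(out, path, format = format, allow_empty = allow_empty)
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %s (id: %s)\n", attr(x, "phenotype_name"),
              attr(x, "phenotype_id")))
  units <- attr(x, "units")
  cat(sprintf("  %d SNPs; units: %s; trait type: %s\n", nrow(x),
              if (nzchar(units)) units else "(unspecified)",
              attr(x, "sample_type")))
  dropped <- nrow(attr(x, "audit"))
  if (dropped > 0) cat(sprintf("  %d record(s) dropped at read (see audit)\n",
                               dropped))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}
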