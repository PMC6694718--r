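## Instrument selection by p-value threshold and greedy LD clumping.

#' Select instrument SNPs by association p-value
#'
#' Retains records with `pval < p_threshold` in their original order. Records
#' with missing p-values are excluded with an audit note.
#'
#' @param table A `gwas_table`.
#' @param p_threshold Significance threshold; the genome-wide convention is
#'   5e-8 (the default). Relaxed thresholds (e.g. 5e-5) admit more, weaker
#'   instruments.
#' @return A `gwas_table` of the selected records.
#' @export
select_instruments <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "gwas_table"))
  missing_p <- is.na(table$pval)
  keep <- !missing_p & table$pval < p_threshold
  audit <- attr(table, "audit")
  if (any(missing_p)) {
    audit <- rbind(audit, data.frame(snp = table$snp[missing_p],
                                     reason = "missing pval at selection",
                                     stringsAsFactors = FALSE))
  }
  if (!any(keep)) warnf("no SNPs pass p < %g", p_threshold)
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "audit") <- audit
  out
}

#' Read a pairwise LD r-squared matrix
#'
#' Square TSV with SNP ids as both the header row and the first column.
#'
#' @param path File path.
#' @return An `ld_matrix`: a numeric matrix with SNP-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                          check.names = FALSE, stringsAsFactors = FALSE)
  ld_matrix(as.matrix(df))
}

#' Validate a pairwise LD r-squared matrix
#'
#' @param m Square numeric matrix with identical row/column SNP ids; must be
#'   symmetric (within 1e-12), have a unit diagonal and entries in `[0, 1]`.
#' @return The matrix, classed `ld_matrix`.
#' @export
ld_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("LD matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stopf("LD matrix needs identical row and column SNP ids")
  if (any(is.na(m)) || any(m < 0) || any(m > 1))
    stopf("LD r2 values must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-12) stopf("LD matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-12) stopf("LD matrix diagonal must be 1")
  structure(m, class = c("ld_matrix", class(m)))
}

#' Greedy LD clumping
#'
#' Sorts SNPs by ascending p-value (ties broken by SNP id), then repeatedly
#' takes the most significant remaining SNP as an index SNP and removes every
#' remaining SNP with r2 >= `r2_threshold` to it (and, when `chr`/`pos`
#' columns are present, only those within `window_kb`). SNPs absent from the
#' LD matrix are treated as independent and logged.
#'
#' @param table A `gwas_table`; every record needs a p-value.
#' @param ld An [ld_matrix()] covering (a subset of) the table's SNPs.
#' @param r2_threshold LD pruning threshold, default 0.001.
#' @param window_kb Clumping window in kb, default 10000; only applied when
#'   the table carries `chr` and `pos` columns.
#' @param p_threshold Optional pre-filter on p-values before clumping;
#'   default 1 (no filtering — use [select_instruments()] for selection).
#' @return A `gwas_table` of index SNPs, sorted by ascending p-value.
#' @export
clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000,
                  p_threshold = 1) {
  stopifnot(inherits(table, "gwas_table"))
  if (any(is.na(table$pval))) stopf("clumping requires a p-value for every SNP")
  tab <- table[table$pval < p_threshold | table$pval == p_threshold & p_threshold == 1,
               , drop = FALSE]
  if (nrow(tab) == 0L) return(tab)
  have_pos <- all(c("chr", "pos") %in% names(tab))
  absent <- setdiff(tab$snp, rownames(ld))
  if (length(absent))
    warnf("%d SNP(s) absent from LD matrix treated as independent: %s",
          length(absent), paste(utils::head(absent, 5L), collapse = ", "))
  ord <- order(tab$pval, tab$snp)
  remaining <- ord
  keep_idx <- integer(0)
  while (length(remaining) > 0L) {
    idx <- remaining[1L]
    keep_idx <- c(keep_idx, idx)
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    snp_i <- tab$snp[idx]
    r2 <- rep(0, length(remaining))
    if (snp_i %in% rownames(ld)) {
      others <- tab$snp[remaining]
      known <- others %in% colnames(ld)
      r2[known] <- ld[snp_i, others[known]]
    }
    prune <- r2 >= r2_threshold
    if (have_pos) {
      same_win <- tab$chr[remaining] == tab$chr[idx] &
        abs(tab$pos[remaining] - tab$pos[idx]) <= window_kb * 1000
      prune <- prune & same_win
    }
    remaining <- remaining[!prune]
  }
  out <- tab[keep_idx, , drop = FALSE]
  rownames(out) <- NULL
  out
}
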