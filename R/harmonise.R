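## Allele harmonisation: align exposure and outcome records to a shared
## effect allele, resolving allele swaps, strand flips and palindromic
## ambiguity, with optional LD-proxy substitution for outcome SNPs.

#' Is an allele pair palindromic?
#'
#' A SNP is palindromic when its two alleles are strand complements of each
#' other ({A,T} or {G,C}), so the strand cannot be resolved from allele labels
#' alone. Indel alleles (length > 1) are never palindromic.
#'
#' @param effect_allele,other_allele Allele strings.
#' @return Logical vector.
#' @export
is_palindromic <- function(effect_allele, other_allele) {
  a1 <- toupper(effect_allele); a2 <- toupper(other_allele)
  nchar(a1) == 1L & nchar(a2) == 1L & a2 == comp_allele(a1) & a1 != a2
}

## frequency side classification for palindromic inference:
## "low" (< t), "high" (> 1 - t) or "mid" (ambiguous; boundaries count as mid)
freq_side <- function(eaf, t) {
  ifelse(is.na(eaf), "mid",
         ifelse(eaf < t, "low", ifelse(eaf > 1 - t, "high", "mid")))
}

#' Align one exposure/outcome record pair to the exposure's effect allele
#'
#' Implements the harmonisation truth table: (a) identical alleles kept as-is;
#' (b) swapped alleles negate the outcome beta and reflect its frequency;
#' (c) strand-complemented alleles are matched after complementing, then (a)
#' or (b) applies; (d) palindromic SNPs under `action = 2` have their
#' orientation inferred from allele frequencies against `maf_threshold`, and
#' are flagged ambiguous (and dropped) when either frequency is missing or
#' lies inside `[maf_threshold, 1 - maf_threshold]`; (e) under `action = 1`
#' palindromic SNPs are aligned by labels alone, under `action = 3` they are
#' always dropped; (f) irreconcilable alleles are dropped.
#'
#' @param exp,out Single-row data.frames (or lists) with fields
#'   `effect_allele`, `other_allele`, `beta`, `se`, `eaf`.
#' @param action 1 (trust forward strand), 2 (infer palindromic orientation
#'   from frequency; the default), or 3 (drop all palindromic SNPs).
#' @param maf_threshold Palindromic-inference minor-allele-frequency
#'   threshold in (0, 0.5], default 0.3.
#' @return List with the aligned outcome statistics and flags
#'   (`beta_out`, `se_out`, `eaf_out`, `palindromic`, `ambiguous`, `flipped`,
#'   `mr_keep`, `reason`).
#' @export
align_pair <- function(exp, out, action = 2, maf_threshold = 0.3) {
  if (!action %in% 1:3) stopf("action must be 1, 2 or 3")
  if (maf_threshold <= 0 || maf_threshold > 0.5)
    stopf("maf_threshold must be in (0, 0.5]")
  e1 <- toupper(exp$effect_allele); e2 <- toupper(exp$other_allele)
  o1 <- toupper(out$effect_allele); o2 <- toupper(out$other_allele)
  res <- list(beta_out = out$beta, se_out = out$se, eaf_out = out$eaf,
              palindromic = FALSE, ambiguous = FALSE, flipped = FALSE,
              mr_keep = TRUE, reason = "")
  swap <- function(r) {
    r$beta_out <- -r$beta_out
    r$eaf_out <- 1 - r$eaf_out
    r$flipped <- !r$flipped
    r
  }
  drop <- function(r, reason, ambiguous = FALSE) {
    r$mr_keep <- FALSE; r$reason <- reason; r$ambiguous <- ambiguous
    r
  }

  if (is_palindromic(e1, e2)) {
    res$palindromic <- TRUE
    if (action == 3) return(drop(res, "palindromic SNP removed (action 3)"))
    ## label alignment first (an A/T pair may be listed T/A)
    if (o1 == e1 && o2 == e2) {
      ## as-is
    } else if (o1 == e2 && o2 == e1) {
      res <- swap(res)
    } else {
      return(drop(res, "incompatible alleles"))
    }
    if (action == 1) return(res)
    ## action 2: infer strand from frequency sides
    s_exp <- freq_side(exp$eaf, maf_threshold)
    s_out <- freq_side(res$eaf_out, maf_threshold)
    if (s_exp == "mid" || s_out == "mid")
      return(drop(res, "palindromic SNP with ambiguous effect allele",
                  ambiguous = TRUE))
    if (s_exp != s_out) res <- swap(res)
    return(res)
  }

  if (o1 == e1 && o2 == e2) return(res)
  if (o1 == e2 && o2 == e1) return(swap(res))
  c1 <- comp_allele(o1); c2 <- comp_allele(o2)
  if (c1 == e1 && c2 == e2) return(res)          # strand flip only
  if (c1 == e2 && c2 == e1) return(swap(res))    # strand flip + swap
  drop(res, "incompatible alleles")
}

#' Read an LD-proxy table
#'
#' Expected columns: `target_snp`, `proxy_snp`, `r2`, `proxy_a1`, `proxy_a2`,
#' `target_a1`, `target_a2`. The allele phase map (`proxy_a1` corresponds to
#' `target_a1`, `proxy_a2` to `target_a2`) translates proxy alleles onto the
#' target SNP's alleles.
#'
#' @param path TSV file path.
#' @return data.frame of class `proxy_table`.
#' @export
read_proxy_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  proxy_table(df)
}

#' Construct and validate an LD-proxy table
#'
#' @param df data.frame with columns `target_snp`, `proxy_snp`, `r2`,
#'   `proxy_a1`, `proxy_a2`, `target_a1`, `target_a2`.
#' @return data.frame of class `proxy_table`.
#' @export
proxy_table <- function(df) {
  need <- c("target_snp", "proxy_snp", "r2", "proxy_a1", "proxy_a2",
            "target_a1", "target_a2")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("proxy table missing column(s): %s",
                          paste(miss, collapse = ", "))
  df$r2 <- parse_num(df$r2)
  if (any(is.na(df$r2) | df$r2 < 0 | df$r2 > 1))
    stopf("proxy r2 values must lie in [0, 1]")
  for (col in c("proxy_a1", "proxy_a2", "target_a1", "target_a2"))
    df[[col]] <- toupper(as.character(df[[col]]))
  if (any(df$proxy_a1 == df$proxy_a2) || any(df$target_a1 == df$target_a2))
    stopf("proxy allele phase map must be a bijection over two distinct alleles")
  structure(df, class = c("proxy_table", "data.frame"))
}

## substitute a proxy outcome record for a missing target SNP; returns a
## one-row outcome-style data.frame with alleles translated onto the target's,
## or NULL when no admissible proxy exists
find_proxy <- function(snp, outcome, proxies, min_r2) {
  cand <- proxies[proxies$target_snp == snp &
                  proxies$proxy_snp %in% outcome$snp &
                  proxies$r2 >= min_r2, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$r2, cand$proxy_snp), , drop = FALSE]
  for (i in seq_len(nrow(cand))) {
    px <- cand[i, ]
    rec <- outcome[outcome$snp == px$proxy_snp, , drop = FALSE][1L, ]
    p1 <- rec$effect_allele; p2 <- rec$other_allele
    ## match the proxy record's alleles against the phase map (direct, swapped,
    ## or strand-complemented); translate onto the target alleles
    trans <- NULL
    if (p1 == px$proxy_a1 && p2 == px$proxy_a2) {
      trans <- c(px$target_a1, px$target_a2)
    } else if (p1 == px$proxy_a2 && p2 == px$proxy_a1) {
      trans <- c(px$target_a2, px$target_a1)
    } else if (comp_allele(p1) == px$proxy_a1 && comp_allele(p2) == px$proxy_a2) {
      trans <- c(px$target_a1, px$target_a2)
    } else if (comp_allele(p1) == px$proxy_a2 && comp_allele(p2) == px$proxy_a1) {
      trans <- c(px$target_a2, px$target_a1)
    }
    if (is.null(trans)) next
    rec$effect_allele <- trans[1L]
    rec$other_allele <- trans[2L]
    rec$snp <- snp
    attr(rec, "proxy_snp") <- px$proxy_snp
    return(rec)
  }
  NULL
}

#' Harmonise exposure and outcome GWAS tables to a common effect allele
#'
#' Joins the two tables on SNP id, aligns every outcome record to the
#' exposure's effect allele via [align_pair()], and (optionally) substitutes
#' the best available LD proxy (r2 >= `proxy_min_r2`; ties broken by larger
#' r2 then lexicographic proxy id) for exposure SNPs absent from the outcome.
#' Only the outcome record is ever proxied. The result is ordered by SNP id.
#'
#' @param exposure,outcome `gwas_table` objects.
#' @param action Palindromic-SNP handling, see [align_pair()]. Default 2.
#' @param maf_threshold Palindromic-inference MAF threshold, default 0.3.
#' @param proxies Optional [proxy_table()].
#' @param proxy_min_r2 Minimum LD r2 for a proxy, default 0.8.
#' @param use_proxies Use `proxies` when a SNP is missing from the outcome.
#' @return An `mr_harmonised` data.frame with columns `snp`, `effect_allele`,
#'   `other_allele`, `beta_exp`, `se_exp`, `eaf_exp`, `pval_exp`, `n_exp`,
#'   `beta_out`, `se_out`, `eaf_out`, `n_out`, `palindromic`, `ambiguous`,
#'   `proxy_used`, `mr_keep`, `reason`; study metadata and an audit log are
#'   carried as attributes.
#' @export
harmonise <- function(exposure, outcome, action = 2, maf_threshold = 0.3,
                      proxies = NULL, proxy_min_r2 = 0.8, use_proxies = TRUE) {
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  if (nrow(exposure) == 0L) stopf("exposure table is empty")
  log <- character(0)
  out_df <- as.data.frame(outcome, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ex <- exposure[i, ]
    snp <- ex$snp
    proxy_id <- NA_character_
    hit <- out_df[out_df$snp == snp, , drop = FALSE]
    if (nrow(hit) == 0L) {
      if (use_proxies && !is.null(proxies)) {
        sub <- find_proxy(snp, out_df, proxies, proxy_min_r2)
        if (is.null(sub)) {
          log <- c(log, sprintf("%s: absent from outcome, no proxy with r2 >= %g",
                                snp, proxy_min_r2))
          next
        }
        proxy_id <- attr(sub, "proxy_snp")
        log <- c(log, sprintf("%s: outcome record substituted by proxy %s",
                              snp, proxy_id))
        hit <- sub
      } else {
        log <- c(log, sprintf("%s: absent from outcome", snp))
        next
      }
    }
    ot <- hit[1L, ]
    al <- align_pair(ex, ot, action = action, maf_threshold = maf_threshold)
    if (al$flipped) log <- c(log, sprintf("%s: outcome orientation flipped", snp))
    if (!al$mr_keep) log <- c(log, sprintf("%s: dropped (%s)", snp, al$reason))
    rows[[i]] <- data.frame(
      snp = snp, effect_allele = ex$effect_allele,
      other_allele = ex$other_allele,
      beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf,
      pval_exp = ex$pval, n_exp = ex$n,
      beta_out = al$beta_out, se_out = al$se_out, eaf_out = al$eaf_out,
      n_out = ot$n,
      palindromic = al$palindromic, ambiguous = al$ambiguous,
      proxy_used = proxy_id, mr_keep = al$mr_keep, reason = al$reason,
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) stopf("no SNPs remain after harmonisation")
  dat <- do.call(rbind, rows)
  dat <- dat[order(dat$snp), , drop = FALSE]
  rownames(dat) <- NULL
  structure(dat, class = c("mr_harmonised", "data.frame"),
            exposure_name = attr(exposure, "phenotype_name"),
            exposure_id = attr(exposure, "phenotype_id"),
            exposure_units = attr(exposure, "units"),
            outcome_name = attr(outcome, "phenotype_name"),
            outcome_id = attr(outcome, "phenotype_id"),
            outcome_units = attr(outcome, "units"),
            outcome_type = attr(outcome, "sample_type"),
            audit = log)
}

#' @export
print.mr_harmonised <- function(x, ...) {
  cat(sprintf("Harmonised dataset: %s (exposure) on %s (outcome)\n",
              attr(x, "exposure_name"), attr(x, "outcome_name")))
  cat(sprintf("  %d SNPs (%d kept for MR, %d palindromic, %d via proxy)\n",
              nrow(x), sum(x$mr_keep), sum(x$palindromic),
              sum(!is.na(x$proxy_used))))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("  ... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

## kept records as plain vectors, the estimators' working form
mr_inputs <- function(dataset) {
  stopifnot(inherits(dataset, "mr_harmonised"))
  d <- dataset[dataset$mr_keep, , drop = FALSE]
  if (nrow(d) == 0L) stopf("no SNPs kept for MR in this dataset")
  list(snp = d$snp, bx = d$beta_exp, bxse = d$se_exp,
       by = d$beta_out, byse = d$se_out, L = nrow(d))
}
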