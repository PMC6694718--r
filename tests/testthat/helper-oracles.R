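# Independent oracles and fixture builders used across the suite.

# build a minimal harmonised dataset directly from summary vectors
make_dataset <- function(bx, by, byse, bxse = rep(1e-8, length(bx)),
                         snp = sprintf("rs%03d", seq_along(bx)),
                         n_exp = 1e5, n_out = 5e4) {
  df <- data.frame(snp = snp, effect_allele = "A", other_allele = "G",
                   beta_exp = bx, se_exp = bxse, eaf_exp = 0.3,
                   pval_exp = 2 * pnorm(-abs(bx / bxse)), n_exp = n_exp,
                   beta_out = by, se_out = byse, eaf_out = 0.3, n_out = n_out,
                   palindromic = FALSE, ambiguous = FALSE,
                   proxy_used = NA_character_, mr_keep = TRUE, reason = "",
                   stringsAsFactors = FALSE)
  structure(df, class = c("mr_harmonised", "data.frame"),
            exposure_name = "X", exposure_id = "X", exposure_units = "SD",
            outcome_name = "Y", outcome_id = "Y", outcome_units = "SD",
            outcome_type = "continuous", audit = character(0))
}

# generic weighted-least-squares oracle via stats::lm
wls_oracle <- function(bx, by, byse, intercept = FALSE) {
  w <- 1 / byse^2
  fit <- if (intercept) lm(by ~ bx, weights = w) else lm(by ~ 0 + bx, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  list(coef = co[, "Estimate"],
       se_fe = co[, "Std. Error"] / sm$sigma,      # unit-dispersion (fixed-effect) SE
       sigma = sm$sigma)
}

# brute-force interpolated weighted median: scan cumulative weights
wmedian_oracle <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord] / sum(w)
  cum <- numeric(length(w))
  run <- 0
  for (i in seq_along(w)) {
    cum[i] <- run + 0.5 * w[i]
    run <- run + w[i]
  }
  if (cum[1] >= 0.5) return(r[1])
  n <- length(r)
  if (cum[n] <= 0.5) return(r[n])
  j <- max(which(cum < 0.5))
  r[j] + (r[j + 1] - r[j]) * (0.5 - cum[j]) / (cum[j + 1] - cum[j])
}

# brute-force greedy clumping oracle over snp ids
clump_oracle <- function(snps, pvals, ldmat, r2) {
  ord <- order(pvals, snps)
  pool <- snps[ord]
  kept <- character(0)
  while (length(pool) > 0) {
    idx <- pool[1]
    kept <- c(kept, idx)
    pool <- pool[-1]
    if (!idx %in% rownames(ldmat)) next
    drop <- vapply(pool, function(s) {
      s %in% colnames(ldmat) && ldmat[idx, s] >= r2
    }, logical(1))
    pool <- pool[!drop]
  }
  kept
}

# direct weighted gaussian-KDE grid argmax (same grid rule as the mode
# estimator, computed independently of stats::density's FFT implementation)
kde_argmax_oracle <- function(r, w, h, n = 1000) {
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = n)
  dens <- sapply(grid, function(g) sum(w / sum(w) * dnorm((g - r) / h)) / h)
  grid[which.max(dens)]
}

# random symmetric LD r2 matrix with unit diagonal
random_ld <- function(snps) {
  k <- length(snps)
  m <- matrix(0, k, k, dimnames = list(snps, snps))
  vals <- runif(k * (k - 1) / 2)^2
  m[upper.tri(m)] <- vals
  m <- m + t(m)
  diag(m) <- 1
  m
}

write_gwas_fixture <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}
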