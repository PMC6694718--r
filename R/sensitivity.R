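## Sensitivity battery: heterogeneity, pleiotropy, directionality,
## leave-one-out, single-SNP, funnel and scatter diagnostics.

#' Cochran's Q heterogeneity statistics
#'
#' Q = sum of w_j (by_j - fitted_j)^2 with weights byse^-2 and fitted values
#' from the IVW (zero-intercept; df = L - 1) or Egger (free intercept;
#' df = L - 2) fit. Lower heterogeneity indicates more consistent per-SNP
#' causal estimates; excess Q is a pleiotropy red flag.
#'
#' @param dataset An `mr_harmonised` dataset.
#' @param method `"ivw"`, `"egger"`, or both (default).
#' @return data.frame with `method`, `Q`, `df`, `pval` (upper chi-square tail).
#' @export
mr_heterogeneity <- function(dataset, method = c("ivw", "egger")) {
  method <- match.arg(method, several.ok = TRUE)
  d <- mr_inputs(dataset)
  rows <- lapply(method, function(m) {
    if (m == "ivw") {
      if (d$L < 2L) stopf("heterogeneity (IVW) needs >= 2 SNPs")
      b <- mr_ivw(dataset, "fe")$b
      q <- ivw_q(d$bx, d$by, d$byse, b)
      df <- d$L - 1L
    } else {
      if (d$L < 3L) stopf("heterogeneity (Egger) needs >= 3 SNPs")
      q <- egger_wls(d$bx, d$by, d$byse)$q
      df <- d$L - 2L
    }
    data.frame(method = m, Q = q, df = df,
               pval = stats::pchisq(q, df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Egger-intercept test for directional horizontal pleiotropy
#'
#' The intercept of the MR-Egger regression estimates the average pleiotropic
#' effect across instruments; identical numbers to [mr_egger()]'s intercept
#' block. p-value from a t distribution with L - 2 df.
#'
#' @param dataset An `mr_harmonised` dataset (>= 3 kept SNPs).
#' @return data.frame with `intercept`, `se`, `pval`.
#' @export
mr_pleiotropy <- function(dataset) {
  mr_egger(dataset)$intercept
}

#' Steiger-style causal direction test
#'
#' Per SNP, the variance explained is r2_j = t_j^2 / (t_j^2 + n - 2) with
#' t_j = beta_j / se_j; these are summed per study. The assumed direction is
#' supported when the instrument explains more variance in the exposure than
#' in the outcome. The test compares Fisher-z transforms of the aggregate
#' correlations, scaled by the pooled sampling variance. The result is a
#' direction flag, never an effect estimate, and cannot establish that any
#' causal association exists.
#'
#' @param dataset An `mr_harmonised` dataset.
#' @param n_exp,n_out Study sample sizes; taken from the dataset's `n_exp` /
#'   `n_out` columns when omitted.
#' @return data.frame with `r2_exposure`, `r2_outcome`, `correct_direction`,
#'   `test_pval`.
#' @export
mr_direction <- function(dataset, n_exp = NULL, n_out = NULL) {
  d <- dataset[dataset$mr_keep, , drop = FALSE]
  if (nrow(d) == 0L) stopf("no SNPs kept for MR in this dataset")
  n_exp <- n_exp %||% stats::median(d$n_exp, na.rm = TRUE)
  n_out <- n_out %||% stats::median(d$n_out, na.rm = TRUE)
  if (!is.finite(n_exp)) stopf("missing sample size on the exposure side")
  if (!is.finite(n_out)) stopf("missing sample size on the outcome side")
  r2_one <- function(beta, se, n) {
    t2 <- (beta / se)^2
    sum(t2 / (t2 + n - 2))
  }
  r2_exp <- r2_one(d$beta_exp, d$se_exp, n_exp)
  r2_out <- r2_one(d$beta_out, d$se_out, n_out)
  z <- (atanh(sqrt(pmin(r2_exp, 1 - 1e-12))) -
        atanh(sqrt(pmin(r2_out, 1 - 1e-12)))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  data.frame(r2_exposure = r2_exp, r2_outcome = r2_out,
             correct_direction = r2_exp > r2_out,
             test_pval = 2 * stats::pnorm(-abs(z)))
}

#' Leave-one-out analysis
#'
#' Repeats the default IVW estimate omitting each SNP in turn, plus a final
#' `"All"` row with the full-data estimate, to reveal single outlying SNPs
#' driving the result.
#'
#' @param dataset An `mr_harmonised` dataset (>= 3 kept SNPs).
#' @return data.frame with `snp`, `b`, `se`, `pval`; the last row is `"All"`.
#' @export
mr_leaveoneout <- function(dataset) {
  d <- mr_inputs(dataset)
  if (d$L < 3L) stopf("leave-one-out needs >= 3 SNPs")
  kept <- which(dataset$mr_keep)
  rows <- lapply(seq_along(kept), function(j) {
    sub <- dataset
    sub$mr_keep[kept[j]] <- FALSE
    r <- mr_ivw(sub, "default")
    data.frame(snp = d$snp[j], b = r$b, se = r$se, pval = r$pval,
               stringsAsFactors = FALSE)
  })
  all_r <- mr_ivw(dataset, "default")
  out <- rbind(do.call(rbind, rows),
               data.frame(snp = "All", b = all_r$b, se = all_r$se,
                          pval = all_r$pval, stringsAsFactors = FALSE))
  rownames(out) <- NULL
  out
}

#' Single-SNP (forest) analysis
#'
#' One Wald-ratio row per SNP plus overall rows for the default IVW and,
#' when at least three SNPs are kept, MR-Egger.
#'
#' @param dataset An `mr_harmonised` dataset (>= 1 kept SNP).
#' @return data.frame with `snp`, `b`, `se`, `pval`; overall rows are named
#'   `"All - Inverse variance weighted"` and `"All - MR Egger"`.
#' @export
mr_singlesnp <- function(dataset) {
  d <- mr_inputs(dataset)
  rows <- lapply(seq_len(d$L), function(j) {
    r <- mr_wald_ratio(d$bx[j], d$bxse[j], d$by[j], d$byse[j])
    data.frame(snp = d$snp[j], b = r$b, se = r$se, pval = r$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (d$L >= 2L) {
    r <- mr_ivw(dataset, "default")
    out <- rbind(out, data.frame(snp = "All - Inverse variance weighted",
                                 b = r$b, se = r$se, pval = r$pval,
                                 stringsAsFactors = FALSE))
  }
  if (d$L >= 3L) {
    r <- mr_egger(dataset)$slope
    out <- rbind(out, data.frame(snp = "All - MR Egger", b = r$b, se = r$se,
                                 pval = r$pval, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Funnel-plot data
#'
#' Per SNP: the Wald ratio and its precision (1 / first-order SE). Asymmetry
#' about the pooled estimate suggests directional horizontal pleiotropy.
#'
#' @param dataset An `mr_harmonised` dataset (>= 1 kept SNP).
#' @return data.frame with `snp`, `ratio`, `precision`.
#' @export
funnel_data <- function(dataset) {
  d <- mr_inputs(dataset)
  if (any(d$bx == 0)) stopf("undefined ratio: SNP-exposure effect is zero")
  data.frame(snp = d$snp, ratio = d$by / d$bx,
             precision = abs(d$bx) / d$byse, stringsAsFactors = FALSE)
}

#' Scatter (method-comparison) plot data
#'
#' Per-SNP effect pairs oriented so the SNP-exposure effect is always
#' positive, with SEs for error bars, plus one regression line per fitted
#' method (intercept zero except MR-Egger, whose intercept equals the
#' pleiotropy estimate).
#'
#' @param dataset An `mr_harmonised` dataset.
#' @param fit An `mr_fit` on the same dataset.
#' @return data.frame with `snp`, `beta_exp`, `se_exp`, `beta_out`, `se_out`;
#'   the per-method lines are in the `"lines"` attribute
#'   (`method`, `slope`, `intercept`).
#' @export
scatter_data <- function(dataset, fit) {
  stopifnot(inherits(fit, "mr_fit"))
  d <- mr_inputs(dataset)
  o <- orient_positive(d$bx, d$by)
  pts <- data.frame(snp = d$snp, beta_exp = o$bx, se_exp = d$bxse,
                    beta_out = o$by, se_out = d$byse, stringsAsFactors = FALSE)
  egger_int <- attr(fit, "egger_intercept")
  lines <- data.frame(method = fit$method, slope = fit$b,
                      intercept = ifelse(grepl("^egger", fit$method),
                                         if (is.null(egger_int)) 0
                                         else egger_int$intercept, 0),
                      stringsAsFactors = FALSE)
  structure(pts, lines = lines)
}

## -- plot renderers (base graphics) ----------------------------------------

#' Forest plot of single-SNP Wald ratios with overall estimates
#' @param dataset An `mr_harmonised` dataset.
#' @param ... Passed to [graphics::plot()].
#' @return The single-SNP table, invisibly.
#' @export
mr_plot_forest <- function(dataset, ...) {
  ss <- mr_singlesnp(dataset)
  idx <- rev(seq_len(nrow(ss)))
  graphics::plot(ss$b, idx, xlim = range(ss$b - 1.96 * ss$se,
                                         ss$b + 1.96 * ss$se),
                 yaxt = "n", ylab = "", xlab = "MR effect size", pch = 19, ...)
  graphics::segments(ss$b - 1.96 * ss$se, idx, ss$b + 1.96 * ss$se, idx)
  graphics::axis(2, at = idx, labels = ss$snp, las = 1, cex.axis = 0.6)
  graphics::abline(v = 0, lty = 2)
  invisible(ss)
}

#' Leave-one-out forest plot
#' @inheritParams mr_plot_forest
#' @return The leave-one-out table, invisibly.
#' @export
mr_plot_loo <- function(dataset, ...) {
  loo <- mr_leaveoneout(dataset)
  idx <- rev(seq_len(nrow(loo)))
  graphics::plot(loo$b, idx, xlim = range(loo$b - 1.96 * loo$se,
                                          loo$b + 1.96 * loo$se),
                 yaxt = "n", ylab = "", xlab = "IVW estimate omitting SNP",
                 pch = 19, ...)
  graphics::segments(loo$b - 1.96 * loo$se, idx, loo$b + 1.96 * loo$se, idx)
  graphics::axis(2, at = idx, labels = loo$snp, las = 1, cex.axis = 0.6)
  graphics::abline(v = loo$b[nrow(loo)], lty = 2)
  invisible(loo)
}

#' Funnel plot (Wald ratio vs precision)
#' @inheritParams mr_plot_forest
#' @return The funnel table, invisibly.
#' @export
mr_plot_funnel <- function(dataset, ...) {
  fd <- funnel_data(dataset)
  graphics::plot(fd$ratio, fd$precision, xlab = "Wald ratio",
                 ylab = expression(1 / SE[ratio]), pch = 19, ...)
  b <- if (nrow(fd) >= 2L) mr_ivw(dataset)$b else fd$ratio[1L]
  graphics::abline(v = b, lty = 2)
  invisible(fd)
}
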