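## Causal-effect estimators for two-sample MR on harmonised summary data.
##
## Notation: per SNP j, (bx_j, bxse_j) are the SNP-exposure association and
## its SE, (by_j, byse_j) the SNP-outcome association and SE, L the number of
## SNPs kept after harmonisation. All estimates are on the exposure-unit
## scale (log odds for binary outcomes); see beta_to_or() for the OR scale.

mr_result <- function(method, nsnp, b, se, pval) {
  data.frame(method = method, nsnp = as.integer(nsnp), b = b, se = se,
             pval = pval, stringsAsFactors = FALSE)
}

#' Two-sided p-value under each method's reference distribution
#'
#' Wald ratio, IVW (all variants), maximum likelihood and the median methods
#' use the standard normal; the Egger slope and intercept use a t distribution
#' with `nsnp - 2` degrees of freedom; the mode methods use a t with
#' `nsnp - 1`.
#'
#' @param b,se Estimate and standard error (`se > 0`).
#' @param nsnp Number of SNPs behind the estimate.
#' @param method Method name (any of the names accepted by [mr_fit()]).
#' @return Two-sided p-value.
#' @export
mr_pvalue <- function(b, se, nsnp, method) {
  stopifnot(all(se > 0))
  key <- sub("_(bootstrap|nome)$", "", method)
  df <- switch(key,
               egger = nsnp - 2L,
               simple_mode = , weighted_mode = nsnp - 1L,
               NA_integer_)
  if (is.na(df)) return(2 * stats::pnorm(-abs(b / se)))
  if (df < 1) stopf("p-value undefined: df = %d < 1 for method %s", df, method)
  2 * stats::pt(-abs(b / se), df = df)
}

#' Convert a log-scale estimate to an odds ratio with confidence interval
#'
#' Only meaningful when the outcome's effects are on the log-odds scale;
#' estimates are never exponentiated automatically.
#'
#' @param b,se Log-odds estimate and its standard error.
#' @param level Confidence level, default 0.95.
#' @return data.frame with `or`, `ci_low`, `ci_high`.
#' @export
beta_to_or <- function(b, se, level = 0.95) {
  stopifnot(all(se > 0), level > 0, level < 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(or = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se))
}

#' Wald ratio estimator (single instrument)
#'
#' b = by / bx with first-order (delta method) standard error byse / |bx|;
#' the exposure-side sampling error is ignored (NOME).
#'
#' @param bx,bxse SNP-exposure effect and SE (`bxse` unused first-order).
#' @param by,byse SNP-outcome effect and SE.
#' @return One-row MR result data.frame.
#' @export
mr_wald_ratio <- function(bx, bxse, by, byse) {
  if (bx == 0) stopf("undefined ratio: SNP-exposure effect is zero")
  b <- by / bx
  se <- byse / abs(bx)
  mr_result("wald_ratio", 1L, b, se, mr_pvalue(b, se, 1L, "wald_ratio"))
}

## Cochran's Q about the zero-intercept (IVW) fit, weights byse^-2
ivw_q <- function(bx, by, byse, b) {
  sum((by - b * bx)^2 / byse^2)
}

#' Inverse-variance-weighted estimator
#'
#' Zero-intercept weighted regression of outcome on exposure effects with
#' weights byse^-2: b = sum(w bx by) / sum(w bx^2). The fixed-effect SE is
#' (sum(w bx^2))^-1/2; the multiplicative random-effects variant scales it by
#' the residual dispersion sigma = sqrt(Q / (L - 1)); the default applies
#' max(1, sigma) so under-dispersion never shrinks the SE below fixed-effect.
#'
#' @param dataset An `mr_harmonised` dataset (>= 2 kept SNPs).
#' @param variant `"default"`, `"fe"` or `"mre"`.
#' @return One-row MR result data.frame.
#' @export
mr_ivw <- function(dataset, variant = c("default", "fe", "mre")) {
  variant <- match.arg(variant)
  d <- mr_inputs(dataset)
  if (d$L < 2L) stopf("IVW needs >= 2 SNPs; use mr_wald_ratio() for one")
  w <- 1 / d$byse^2
  b <- sum(w * d$bx * d$by) / sum(w * d$bx^2)
  se_fe <- sqrt(1 / sum(w * d$bx^2))
  sigma <- sqrt(ivw_q(d$bx, d$by, d$byse, b) / (d$L - 1))
  se <- switch(variant, fe = se_fe, mre = se_fe * sigma,
               default = se_fe * max(1, sigma))
  method <- switch(variant, default = "ivw", fe = "ivw_fe", mre = "ivw_mre")
  mr_result(method, d$L, b, se, mr_pvalue(b, se, d$L, method))
}

## orient pairs so the SNP-exposure effect is non-negative
orient_positive <- function(bx, by) {
  s <- ifelse(bx < 0, -1, 1)
  list(bx = s * bx, by = s * by)
}

egger_wls <- function(bx, by, byse) {
  o <- orient_positive(bx, by)
  w <- 1 / byse^2
  X <- cbind(1, o$bx)
  XtWX <- crossprod(X * sqrt(w))
  det <- XtWX[1, 1] * XtWX[2, 2] - XtWX[1, 2]^2
  if (det <= .Machine$double.eps * XtWX[1, 1] * XtWX[2, 2])
    stopf("Egger slope unidentifiable: SNP-exposure effects are collinear")
  coefs <- solve(XtWX, crossprod(X, w * o$by))
  fitted <- X %*% coefs
  q <- sum(w * (o$by - fitted)^2)
  L <- length(bx)
  sigma <- if (L > 2) sqrt(q / (L - 2)) else 0
  vcv <- solve(XtWX)
  list(intercept = coefs[1L], slope = coefs[2L],
       se_intercept = sqrt(vcv[1, 1]) * max(1, sigma),
       se_slope = sqrt(vcv[2, 2]) * max(1, sigma),
       sigma = sigma, q = q)
}

#' MR-Egger regression
#'
#' Weighted regression of outcome effects on exposure effects with a free
#' intercept (weights byse^-2), after orienting every pair so the exposure
#' effect is positive. The slope estimates the causal effect; the intercept
#' estimates the average directional pleiotropy. SEs are inflated by
#' max(1, residual dispersion); p-values use a t with L - 2 df. The bootstrap
#' variant resamples (bx, by) from their normal sampling errors and reports
#' the SD over replicates as the SE.
#'
#' @param dataset An `mr_harmonised` dataset (>= 3 kept SNPs).
#' @param bootstrap Use parametric-bootstrap SEs.
#' @param reps Bootstrap replicates, default 1000.
#' @param seed Optional RNG seed for the bootstrap.
#' @return List with `slope` (one-row MR result) and `intercept`
#'   (data.frame `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(dataset, bootstrap = FALSE, reps = 1000, seed = NULL) {
  d <- mr_inputs(dataset)
  if (d$L < 3L) stopf("MR-Egger needs >= 3 SNPs")
  fit <- egger_wls(d$bx, d$by, d$byse)
  se_slope <- fit$se_slope
  se_int <- fit$se_intercept
  method <- "egger"
  if (bootstrap) {
    set_seed_if(seed)
    boots <- matrix(NA_real_, reps, 2L)
    for (r in seq_len(reps)) {
      bxs <- stats::rnorm(d$L, d$bx, d$bxse)
      bys <- stats::rnorm(d$L, d$by, d$byse)
      f <- tryCatch(egger_wls(bxs, bys, d$byse), error = function(e) NULL)
      if (!is.null(f)) boots[r, ] <- c(f$intercept, f$slope)
    }
    se_int <- stats::sd(boots[, 1L], na.rm = TRUE)
    se_slope <- stats::sd(boots[, 2L], na.rm = TRUE)
    method <- "egger_bootstrap"
  }
  slope <- mr_result(method, d$L, fit$slope, se_slope,
                     mr_pvalue(fit$slope, se_slope, d$L, "egger"))
  intercept <- data.frame(intercept = fit$intercept, se = se_int,
                          pval = mr_pvalue(fit$intercept, se_int, d$L, "egger"))
  list(slope = slope, intercept = intercept)
}

## interpolated weighted median: cumulative normalized weight crossing 0.5
weighted_median <- function(r, w) {
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cum <- (cumsum(w) - 0.5 * w) / sum(w)
  if (cum[1L] >= 0.5) return(r[1L])
  if (cum[length(cum)] <= 0.5) return(r[length(r)])
  stats::approx(cum, r, xout = 0.5, ties = "ordered")$y
}

median_weights <- function(d, variant, penalty_scale) {
  r <- d$by / d$bx
  w <- switch(variant,
              simple = rep(1 / d$L, d$L),
              (abs(d$bx) / d$byse)^2)   # weighted & penalised: inverse ratio variance
  if (variant == "penalised") {
    b0 <- weighted_median(r, w)
    qj <- w * (r - b0)^2
    pj <- stats::pchisq(qj, df = 1, lower.tail = FALSE)
    w <- w * pmin(1, penalty_scale * pj)
  }
  list(r = r, w = w)
}

#' Median-based estimators
#'
#' The causal estimate is the interpolated weighted median of the per-SNP
#' Wald ratios: equal weights (`simple`), inverse-variance weights
#' (`weighted`), or inverse-variance weights down-weighted by each SNP's
#' chi-square outlyingness about the weighted-median fit (`penalised`,
#' penalty factor `min(1, penalty_scale * p_j)`). Consistent when more than
#' half the weight lies on valid instruments. The SE is a parametric
#' bootstrap over the summary-data sampling errors.
#'
#' @param dataset An `mr_harmonised` dataset (>= 3 kept SNPs).
#' @param variant `"weighted"` (default), `"simple"` or `"penalised"`.
#' @param reps Bootstrap replicates, default 1000.
#' @param seed Optional RNG seed.
#' @param penalty_scale Penalisation constant, default 20.
#' @return One-row MR result data.frame.
#' @export
mr_median <- function(dataset, variant = c("weighted", "simple", "penalised"),
                      reps = 1000, seed = NULL, penalty_scale = 20) {
  variant <- match.arg(variant)
  d <- mr_inputs(dataset)
  if (d$L < 3L) stopf("median estimators need >= 3 SNPs")
  if (any(d$bx == 0)) stopf("undefined ratio: SNP-exposure effect is zero")
  rw <- median_weights(d, variant, penalty_scale)
  b <- weighted_median(rw$r, rw$w)
  set_seed_if(seed)
  boots <- numeric(reps)
  for (i in seq_len(reps)) {
    db <- list(bx = stats::rnorm(d$L, d$bx, d$bxse),
               by = stats::rnorm(d$L, d$by, d$byse),
               byse = d$byse, L = d$L)
    rwb <- median_weights(db, variant, penalty_scale)
    boots[i] <- weighted_median(rwb$r, rwb$w)
  }
  se <- stats::sd(boots)
  method <- paste0(variant, "_median")
  mr_result(method, d$L, b, se, mr_pvalue(b, se, d$L, method))
}

## Silverman reference bandwidth
silverman_bw <- function(x) {
  n <- length(x)
  s <- min(stats::sd(x), stats::IQR(x) / 1.349)
  0.9 * s * n^(-1 / 5)
}

## weighted gaussian-KDE argmax over a 1000-point grid spanning the ratios
## +/- 3 bandwidths
kde_mode <- function(r, w, h) {
  if (!is.finite(h) || h <= 0) return(r[which.max(w)])
  den <- stats::density(r, weights = w / sum(w), bw = h, kernel = "gaussian",
                        n = 1000L, from = min(r) - 3 * h, to = max(r) + 3 * h)
  den$x[which.max(den$y)]
}

mode_ratio_se <- function(d, nome) {
  if (nome) d$byse / abs(d$bx)
  else sqrt(d$byse^2 / d$bx^2 + d$by^2 * d$bxse^2 / d$bx^4)
}

#' Mode-based estimators
#'
#' The causal estimate is the peak of a kernel-smoothed density of the
#' per-SNP Wald ratios — the estimate from the largest cluster of SNPs.
#' Requires ZEMPA (the modal pleiotropic bias is zero). Weights are uniform
#' (`simple`) or inverse-variance of the ratio (`weighted`); under `nome`
#' the ratio variance omits the exposure-side term. Bandwidth is
#' `phi` x the Silverman reference bandwidth of the ratios. The SE is the
#' median absolute deviation of a parametric bootstrap; p-values use a t
#' with L - 1 df.
#'
#' @param dataset An `mr_harmonised` dataset (>= 3 kept SNPs).
#' @param variant `"weighted"` (default) or `"simple"`.
#' @param nome Assume no measurement error in the SNP-exposure effects.
#' @param phi Bandwidth multiplier, default 1 (> 0).
#' @param reps Bootstrap replicates, default 1000.
#' @param seed Optional RNG seed.
#' @return One-row MR result data.frame.
#' @export
mr_mode <- function(dataset, variant = c("weighted", "simple"), nome = FALSE,
                    phi = 1, reps = 1000, seed = NULL) {
  variant <- match.arg(variant)
  if (phi <= 0) stopf("bandwidth multiplier phi must be > 0")
  d <- mr_inputs(dataset)
  if (d$L < 3L) stopf("mode estimators need >= 3 SNPs")
  if (any(d$bx == 0)) stopf("undefined ratio: SNP-exposure effect is zero")
  r <- d$by / d$bx
  s <- mode_ratio_se(d, nome)
  w <- if (variant == "simple") rep(1 / d$L, d$L) else 1 / s^2
  b <- kde_mode(r, w, phi * silverman_bw(r))
  ## parametric bootstrap from the fitted ratio model: centring the draws on
  ## the fitted values (not the observed ones) keeps the bootstrap ratio
  ## cloud at the sampling dispersion; re-noising the observed statistics
  ## would double it and overstate the SE of a density-argmax statistic
  set_seed_if(seed)
  boots <- numeric(reps)
  for (i in seq_len(reps)) {
    bxs <- stats::rnorm(d$L, d$bx, d$bxse)
    bys <- stats::rnorm(d$L, b * d$bx, d$byse)
    rb <- bys / bxs
    boots[i] <- kde_mode(rb, w, phi * silverman_bw(rb))
  }
  se <- stats::mad(boots)
  method <- paste0(variant, "_mode", if (nome) "_nome" else "")
  mr_result(method, d$L, b, se, mr_pvalue(b, se, d$L, method))
}

#' Maximum-likelihood estimator
#'
#' Joint normal model: bx_j ~ N(xi_j, bxse_j^2) and by_j ~ N(theta xi_j,
#' byse_j^2) independently; the likelihood is maximised over
#' (xi_1..xi_L, theta) by BFGS with analytic gradient, initialised at
#' xi = bx and theta = the IVW estimate, with objective tolerance 1e-10.
#' The SE comes from the observed information (inverse Hessian).
#'
#' @param dataset An `mr_harmonised` dataset (>= 2 kept SNPs).
#' @return One-row MR result data.frame.
#' @export
mr_maxlik <- function(dataset) {
  d <- mr_inputs(dataset)
  if (d$L < 2L) stopf("maximum likelihood needs >= 2 SNPs")
  wx <- 1 / d$bxse^2; wy <- 1 / d$byse^2
  nll <- function(p) {
    xi <- p[seq_len(d$L)]; th <- p[d$L + 1L]
    0.5 * sum(wx * (d$bx - xi)^2) + 0.5 * sum(wy * (d$by - th * xi)^2)
  }
  grad <- function(p) {
    xi <- p[seq_len(d$L)]; th <- p[d$L + 1L]
    gxi <- -wx * (d$bx - xi) - th * wy * (d$by - th * xi)
    gth <- -sum(xi * wy * (d$by - th * xi))
    c(gxi, gth)
  }
  init <- c(d$bx, mr_ivw(dataset, "fe")$b)
  opt <- stats::optim(init, nll, grad, method = "BFGS", hessian = TRUE,
                      control = list(reltol = 1e-10, maxit = 10000L))
  if (opt$convergence != 0)
    stopf("likelihood optimisation did not converge (code %d: %s)",
          opt$convergence, opt$message %||% "")
  k <- d$L + 1L
  vcv <- tryCatch(solve(opt$hessian), error = function(e)
    stopf("observed information is singular at the optimum"))
  b <- opt$par[k]
  se <- sqrt(vcv[k, k])
  mr_result("maximum_likelihood", d$L, b, se,
            mr_pvalue(b, se, d$L, "maximum_likelihood"))
}
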