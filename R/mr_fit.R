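## The central fitting interface: mr_fit() runs a set of estimators on a
## harmonised dataset and returns a classed object with the usual methods.

MR_METHOD_LABELS <- c(
  wald_ratio = "Wald ratio",
  ivw = "Inverse variance weighted",
  ivw_fe = "Inverse variance weighted (fixed effects)",
  ivw_mre = "Inverse variance weighted (multiplicative random effects)",
  egger = "MR Egger",
  egger_bootstrap = "MR Egger (bootstrap)",
  simple_median = "Simple median",
  weighted_median = "Weighted median",
  penalised_median = "Penalised weighted median",
  simple_mode = "Simple mode",
  weighted_mode = "Weighted mode",
  simple_mode_nome = "Simple mode (NOME)",
  weighted_mode_nome = "Weighted mode (NOME)",
  maximum_likelihood = "Maximum likelihood")

#' Default MR method set
#'
#' Wald ratio (applied automatically for single-SNP instruments), MR-Egger,
#' weighted median, inverse-variance-weighted and weighted mode.
#' @return Character vector of method names.
#' @export
mr_default_methods <- function() {
  c("egger", "weighted_median", "ivw", "weighted_mode")
}

run_one_method <- function(method, dataset, reps, seed, phi, penalty_scale) {
  d <- mr_inputs(dataset)
  switch(method,
    wald_ratio = {
      if (d$L != 1L) stopf("wald_ratio applies to single-SNP datasets")
      mr_wald_ratio(d$bx, d$bxse, d$by, d$byse)
    },
    ivw = mr_ivw(dataset, "default"),
    ivw_fe = mr_ivw(dataset, "fe"),
    ivw_mre = mr_ivw(dataset, "mre"),
    egger = mr_egger(dataset)$slope,
    egger_bootstrap = mr_egger(dataset, bootstrap = TRUE, reps = reps,
                               seed = seed)$slope,
    simple_median = mr_median(dataset, "simple", reps, seed),
    weighted_median = mr_median(dataset, "weighted", reps, seed),
    penalised_median = mr_median(dataset, "penalised", reps, seed,
                                 penalty_scale),
    simple_mode = mr_mode(dataset, "simple", FALSE, phi, reps, seed),
    weighted_mode = mr_mode(dataset, "weighted", FALSE, phi, reps, seed),
    simple_mode_nome = mr_mode(dataset, "simple", TRUE, phi, reps, seed),
    weighted_mode_nome = mr_mode(dataset, "weighted", TRUE, phi, reps, seed),
    maximum_likelihood = mr_maxlik(dataset),
    stopf("unknown MR method '%s'", method))
}

#' Fit two-sample MR estimators to a harmonised dataset
#'
#' Runs each requested estimator and collects one result row per method
#' (`method`, `nsnp`, `b`, `se`, `pval`). With exactly one kept SNP only the
#' Wald ratio can run, and it replaces any requested multi-SNP methods.
#'
#' @param dataset An `mr_harmonised` dataset with >= 1 kept SNP.
#' @param methods Character vector of method names; see
#'   [mr_default_methods()] and the `MR_METHOD_LABELS` mapping for the full
#'   list (`ivw`, `ivw_fe`, `ivw_mre`, `egger`, `egger_bootstrap`,
#'   `simple_median`, `weighted_median`, `penalised_median`, `simple_mode`,
#'   `weighted_mode`, `simple_mode_nome`, `weighted_mode_nome`,
#'   `maximum_likelihood`, `wald_ratio`).
#' @param reps Bootstrap replicates for the median/mode/bootstrap methods.
#' @param seed Optional RNG seed for the stochastic methods.
#' @param phi Mode-estimator bandwidth multiplier, default 1.
#' @param penalty_scale Penalised-median constant, default 20.
#' @return An object of class `mr_fit`: the results data.frame with the
#'   dataset, Egger intercept and metadata attached as attributes. Methods:
#'   `print`, `summary`, `coef`, `confint`, `predict`, `residuals`, `plot`.
#' @export
mr_fit <- function(dataset, methods = mr_default_methods(), reps = 1000,
                   seed = NULL, phi = 1, penalty_scale = 20) {
  d <- mr_inputs(dataset)   # errors when nothing is kept
  if (d$L == 1L) methods <- "wald_ratio"
  res <- do.call(rbind, lapply(methods, run_one_method, dataset = dataset,
                               reps = reps, seed = seed, phi = phi,
                               penalty_scale = penalty_scale))
  rownames(res) <- NULL
  intercept <- if (d$L >= 3L) mr_egger(dataset)$intercept else NULL
  structure(res, class = c("mr_fit", "data.frame"), dataset = dataset,
            egger_intercept = intercept, seed = seed)
}

#' Format an mr_fit as the standard MR results table
#'
#' Columns: `id.exposure`, `id.outcome`, `outcome`, `exposure`, `method`
#' (display label), `nsnp`, `b`, `se`, `pval`.
#'
#' @param fit An `mr_fit`.
#' @return data.frame in the standard column layout.
#' @export
mr_results_table <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  ds <- attr(fit, "dataset")
  data.frame(
    id.exposure = attr(ds, "exposure_id"),
    id.outcome = attr(ds, "outcome_id"),
    outcome = attr(ds, "outcome_name"),
    exposure = attr(ds, "exposure_name"),
    method = unname(MR_METHOD_LABELS[fit$method]),
    nsnp = fit$nsnp, b = fit$b, se = fit$se, pval = fit$pval,
    stringsAsFactors = FALSE)
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  ds <- attr(x, "dataset")
  cat(sprintf("Two-sample MR: %s -> %s\n", attr(ds, "exposure_name"),
              attr(ds, "outcome_name")))
  df <- as.data.frame(x)
  df$method <- unname(MR_METHOD_LABELS[df$method])
  df$b <- signif(df$b, digits); df$se <- signif(df$se, digits)
  df$pval <- signif(df$pval, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$b, object$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- cbind(object$b - z * object$se, object$b + z * object$se)
  dimnames(out) <- list(object$method,
                        sprintf("%g %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  out
}

## fitted outcome effects under one method's line (Egger adds its intercept)
#' @export
predict.mr_fit <- function(object, method = "ivw", ...) {
  if (!method %in% object$method) stopf("method '%s' not in this fit", method)
  ds <- attr(object, "dataset")
  d <- mr_inputs(ds)
  b <- object$b[object$method == method][1L]
  a <- 0
  if (grepl("^egger", method)) {
    a <- attr(object, "egger_intercept")$intercept
    o <- orient_positive(d$bx, d$by)
    return(stats::setNames(a + b * o$bx, d$snp))
  }
  stats::setNames(b * d$bx, d$snp)
}

#' @export
residuals.mr_fit <- function(object, method = "ivw", ...) {
  ds <- attr(object, "dataset")
  d <- mr_inputs(ds)
  by <- d$by
  if (grepl("^egger", method)) by <- orient_positive(d$bx, d$by)$by
  stats::setNames(by - predict(object, method = method), d$snp)
}

#' @export
summary.mr_fit <- function(object, ...) {
  ds <- attr(object, "dataset")
  out <- list(results = mr_results_table(object),
              egger_intercept = attr(object, "egger_intercept"),
              heterogeneity = tryCatch(mr_heterogeneity(ds),
                                       error = function(e) NULL),
              outcome_units = attr(ds, "outcome_units"))
  class(out) <- "summary.mr_fit"
  out
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  df <- x$results
  df$b <- signif(df$b, digits); df$se <- signif(df$se, digits)
  df$pval <- signif(df$pval, digits)
  print(df[, c("method", "nsnp", "b", "se", "pval")], row.names = FALSE)
  if (identical(x$outcome_units, "log odds")) {
    cat("\nOdds-ratio scale (binary outcome):\n")
    or <- beta_to_or(x$results$b, x$results$se)
    print(data.frame(method = x$results$method,
                     OR = signif(or$or, 3),
                     ci_low = signif(or$ci_low, 3),
                     ci_high = signif(or$ci_high, 3)), row.names = FALSE)
  }
  if (!is.null(x$heterogeneity)) {
    cat("\nHeterogeneity:\n")
    print(x$heterogeneity, row.names = FALSE)
  }
  if (!is.null(x$egger_intercept)) {
    cat(sprintf("\nEgger intercept: %.4g (SE %.4g; p = %.3g)\n",
                x$egger_intercept$intercept, x$egger_intercept$se,
                x$egger_intercept$pval))
  }
  invisible(x)
}

#' @export
plot.mr_fit <- function(x, ...) {
  sc <- scatter_data(attr(x, "dataset"), x)
  lines <- attr(sc, "lines")
  graphics::plot(sc$beta_exp, sc$beta_out,
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", pch = 19, ...)
  graphics::arrows(sc$beta_exp, sc$beta_out - sc$se_out, sc$beta_exp,
                   sc$beta_out + sc$se_out, angle = 90, code = 3,
                   length = 0.02, col = "grey60")
  for (i in seq_len(nrow(lines)))
    graphics::abline(lines$intercept[i], lines$slope[i], col = i + 1, lwd = 2)
  graphics::legend("topleft", legend = unname(MR_METHOD_LABELS[lines$method]),
                   col = seq_len(nrow(lines)) + 1, lwd = 2, bty = "n",
                   cex = 0.8)
  invisible(x)
}
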