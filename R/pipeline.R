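## End-to-end pipeline: select -> (clump) -> harmonise -> fit -> sensitivity
## battery -> plots, with a run log. Mirrors the standard workflow defaults:
## clumping off, LD proxies on at r2 >= 0.8, palindromic alignment from
## frequency with MAF threshold 0.3, and the default method set.

#' Pipeline run configuration
#'
#' Defaults reproduce the standard workflow: no LD clumping, proxies enabled
#' at minimum r2 0.8, palindromic strand alignment attempted (action 2) with
#' MAF threshold 0.3, and the Wald ratio / MR-Egger / weighted median / IVW /
#' weighted mode method set.
#'
#' @param exposure_path,outcome_path Input summary-statistic files.
#' @param exposure_mapping,outcome_mapping [column_mapping()]s.
#' @param p_threshold Instrument-selection p-value threshold, default 5e-8.
#' @param clump Perform LD clumping (default off).
#' @param ld_path Path to an LD r2 matrix (required when `clump = TRUE`).
#' @param clump_r2,clump_kb Clumping parameters, defaults 0.001 / 10000 kb.
#' @param action,maf_threshold Harmonisation options, defaults 2 / 0.3.
#' @param proxy_path Optional LD-proxy table path.
#' @param proxy_r2 Minimum proxy r2, default 0.8.
#' @param use_proxies Enable proxy substitution, default TRUE.
#' @param methods Method names, default [mr_default_methods()].
#' @param reps,phi Stochastic-method options.
#' @param seed RNG seed recorded in the log and used by every stochastic step.
#' @param outdir Output directory.
#' @return Object of class `run_config`.
#' @export
run_config <- function(exposure_path, outcome_path,
                       exposure_mapping = column_mapping(),
                       outcome_mapping = column_mapping(),
                       p_threshold = 5e-8, clump = FALSE, ld_path = NULL,
                       clump_r2 = 0.001, clump_kb = 10000,
                       action = 2, maf_threshold = 0.3, proxy_path = NULL,
                       proxy_r2 = 0.8, use_proxies = TRUE,
                       methods = mr_default_methods(), reps = 1000, phi = 1,
                       seed = 1, outdir = "mr_output") {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full MR pipeline and write the result bundle
#'
#' Executes instrument selection, optional clumping, harmonisation, the
#' estimator suite and the sensitivity battery, writing every table as TSV
#' plus SVG plots and a log of defaults, drops and the seed. Single-SNP runs
#' produce only the Wald-ratio result: the multi-SNP sensitivity analyses and
#' plots are skipped, since they require multiple instruments.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the fitted `mr_fit`, the harmonised dataset
#'   and the output directory.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "log.txt")
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s (check inputs and options)",
            name, conditionMessage(e)))
  }
  note("seed: %s", config$seed)
  note("settings: p_threshold=%g clump=%s action=%d maf_threshold=%g proxy_r2=%g methods=%s",
       config$p_threshold, config$clump, config$action, config$maf_threshold,
       config$proxy_r2, paste(config$methods, collapse = ","))

  exposure <- stage("read exposure",
                    read_gwas(config$exposure_path, config$exposure_mapping))
  outcome <- stage("read outcome",
                   read_gwas(config$outcome_path, config$outcome_mapping))
  note("exposure: %d records (%d dropped at read)", nrow(exposure),
       nrow(attr(exposure, "audit")))
  note("outcome: %d records (%d dropped at read)", nrow(outcome),
       nrow(attr(outcome, "audit")))

  sel <- stage("select instruments",
               select_instruments(exposure, config$p_threshold))
  note("instrument selection: %d of %d SNPs at p < %g", nrow(sel),
       nrow(exposure), config$p_threshold)
  if (config$clump) {
    if (is.null(config$ld_path)) stopf("pipeline stage 'clump' failed: clump = TRUE requires ld_path")
    ld <- stage("read LD matrix", read_ld_matrix(config$ld_path))
    sel <- stage("clump", clump(sel, ld, r2_threshold = config$clump_r2,
                                window_kb = config$clump_kb))
    note("clumping: %d index SNPs at r2 < %g", nrow(sel), config$clump_r2)
  } else {
    note("clumping: off (default)")
  }

  proxies <- if (!is.null(config$proxy_path))
    stage("read proxies", read_proxy_table(config$proxy_path)) else NULL
  dat <- stage("harmonise",
               harmonise(sel, outcome, action = config$action,
                         maf_threshold = config$maf_threshold,
                         proxies = proxies, proxy_min_r2 = config$proxy_r2,
                         use_proxies = config$use_proxies))
  for (line in attr(dat, "audit")) note("harmonise: %s", line)
  note("harmonised: %d SNPs, %d kept", nrow(dat), sum(dat$mr_keep))
  write_mr_table(dat, file.path(config$outdir, "harmonised.tsv"))

  fit <- stage("mr", mr_fit(dat, methods = config$methods, reps = config$reps,
                            seed = config$seed, phi = config$phi))
  write_mr_table(mr_results_table(fit),
                 file.path(config$outdir, "mr_results.tsv"))

  L <- sum(dat$mr_keep)
  if (L >= 2L) {
    write_mr_table(mr_heterogeneity(dat, "ivw"),
                   file.path(config$outdir, "heterogeneity.tsv"))
    write_mr_table(mr_singlesnp(dat),
                   file.path(config$outdir, "single_snp.tsv"))
    write_mr_table(funnel_data(dat), file.path(config$outdir, "funnel.tsv"))
    sc <- scatter_data(dat, fit)
    write_mr_table(sc, file.path(config$outdir, "scatter.tsv"))
    write_mr_table(attr(sc, "lines"),
                   file.path(config$outdir, "scatter_lines.tsv"))
    dir_res <- tryCatch(mr_direction(dat), error = function(e) {
      note("direction test skipped: %s", conditionMessage(e)); NULL
    })
    if (!is.null(dir_res))
      write_mr_table(dir_res, file.path(config$outdir, "direction.tsv"))
  }
  if (L >= 3L) {
    write_mr_table(mr_heterogeneity(dat),
                   file.path(config$outdir, "heterogeneity.tsv"))
    write_mr_table(mr_pleiotropy(dat),
                   file.path(config$outdir, "pleiotropy.tsv"))
    write_mr_table(mr_leaveoneout(dat), file.path(config$outdir, "loo.tsv"))
  }
  if (L >= 2L) {
    render <- function(file, code) {
      grDevices::svg(file.path(config$outdir, file), width = 7, height = 6)
      on.exit(grDevices::dev.off())
      code
    }
    render("scatter.svg", plot(fit))
    render("forest.svg", mr_plot_forest(dat))
    render("funnel.svg", mr_plot_funnel(dat))
    if (L >= 3L) render("loo.svg", mr_plot_loo(dat))
  } else {
    note("single-SNP instrument: no graphical results produced")
  }
  writeLines(log_lines, log_path)
  invisible(list(fit = fit, dataset = dat, outdir = config$outdir))
}

#' One-screen digest of a pipeline result bundle
#'
#' Reads the TSV artifacts from a [run_pipeline()] output directory and
#' prints per-method estimates (with odds ratios when the outcome is on the
#' log-odds scale), heterogeneity, the Egger intercept and the direction
#' flag. Missing files are listed, not fatal.
#'
#' @param outdir Bundle directory.
#' @param outcome_units Units of the outcome effects; `"log odds"` triggers
#'   OR-scale reporting.
#' @return Character vector of digest lines, invisibly (also printed).
#' @export
report_summary <- function(outdir, outcome_units = "") {
  if (!dir.exists(outdir)) stopf("bundle directory not found: %s", outdir)
  lines <- character(0)
  say <- function(fmt, ...) lines <<- c(lines, sprintf(fmt, ...))
  missing <- character(0)
  grab <- function(file) {
    p <- file.path(outdir, file)
    if (!file.exists(p)) { missing <<- c(missing, file); return(NULL) }
    utils::read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  res <- grab("mr_results.tsv")
  if (!is.null(res)) {
    for (i in seq_len(nrow(res))) {
      say("%s (nsnp %d): b = %.4g, se = %.4g, p = %.3g", res$method[i],
          res$nsnp[i], res$b[i], res$se[i], res$pval[i])
      if (identical(outcome_units, "log odds")) {
        or <- beta_to_or(res$b[i], res$se[i])
        say("  OR: %.2f, 95%% CI: %.2f to %.2f", or$or, or$ci_low, or$ci_high)
      }
    }
  }
  het <- grab("heterogeneity.tsv")
  if (!is.null(het))
    for (i in seq_len(nrow(het)))
      say("heterogeneity (%s): Q = %.3g on %d df, p = %.3g", het$method[i],
          het$Q[i], het$df[i], het$pval[i])
  ple <- grab("pleiotropy.tsv")
  if (!is.null(ple))
    say("Egger intercept: %.4g (SE %.4g; p = %.3g)", ple$intercept, ple$se,
        ple$pval)
  dir_res <- grab("direction.tsv")
  if (!is.null(dir_res))
    say("causal direction: %s (r2 exposure %.3g vs outcome %.3g, p = %.3g)",
        if (dir_res$correct_direction) "supported" else "not supported",
        dir_res$r2_exposure, dir_res$r2_outcome, dir_res$test_pval)
  if (length(missing)) say("missing bundle files: %s",
                           paste(missing, collapse = ", "))
  cat(paste(lines, collapse = "\n"), "\n")
  invisible(lines)
}
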