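## Synthetic two-sample GWAS generator with known causal truth.
##
## Generative model: true SNP-exposure effects gamma_j ~ N(gamma_mean,
## gamma_sd^2); pleiotropic effects alpha_j per scenario; true SNP-outcome
## effects Gamma_j = theta * gamma_j + alpha_j. Observed summary statistics
## are drawn with independent sampling noise in the two studies:
## bx_j ~ N(gamma_j, se_x^2), by_j ~ N(Gamma_j, se_y^2) (no sample overlap).
## Reported p-values are the two-sided normal p of beta/se. Allele structure
## (palindromic fraction, allele swaps, strand flips in the outcome table)
## exercises the harmonisation layer; the applied perturbations are recorded
## in the truth table.

#' Configuration for the two-sample GWAS simulator
#'
#' @param L Number of SNPs.
#' @param theta True causal effect of the exposure on the outcome.
#' @param gamma_mean,gamma_sd Moments of the true SNP-exposure effects.
#'   The defaults (mean 0.2, sd 0.3/sqrt(12), i.e. uniform on 0.05-0.35 SD)
#'   emulate instruments selected at genome-wide significance and reported
#'   for the exposure-increasing allele: effects positive and bounded away
#'   from zero.
#' @param gamma_dist Shape of the instrument-effect distribution:
#'   `"uniform"` (default; support `gamma_mean +/- sqrt(3) * gamma_sd`) or
#'   `"normal"`.
#' @param scenario Pleiotropy scenario: `"none"` (alpha = 0), `"balanced"`
#'   (alpha ~ N(0, alpha_sd^2)), `"directional"` (alpha ~ N(alpha_mean,
#'   alpha_sd^2); instrument strength stays independent of alpha, so InSIDE
#'   holds), or `"correlated"` (alpha correlated with gamma at `rho`,
#'   violating InSIDE).
#' @param alpha_mean,alpha_sd Pleiotropy moments.
#' @param rho Correlation between alpha and gamma (correlated scenario).
#' @param frac_invalid Fraction of SNPs receiving a pleiotropic effect
#'   (the first `floor(frac_invalid * L)` SNPs); default 1.
#' @param se_x,se_y Sampling-error SDs of the exposure/outcome summary
#'   statistics (scalar or length-L). Defaults 0.01 and 0.05.
#' @param n_exp,n_out Nominal GWAS sample sizes written to the tables.
#' @param maf_min,maf_max Uniform support of the effect-allele frequency.
#' @param frac_palindromic Fraction of SNPs given A/T or G/C allele pairs.
#' @param frac_strand_flipped,frac_allele_swapped Fractions of outcome
#'   records reported on the complementary strand / with effect and other
#'   allele labels exchanged.
#' @param seed RNG seed; the generator is fully reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(L = 100, theta = 0.2, gamma_mean = 0.2,
                       gamma_sd = 0.3 / sqrt(12),
                       gamma_dist = c("uniform", "normal"),
                       scenario = c("none", "balanced", "directional",
                                    "correlated"),
                       alpha_mean = 0, alpha_sd = 0, rho = 0,
                       frac_invalid = 1, se_x = 0.01, se_y = 0.05,
                       n_exp = 100000, n_out = 50000,
                       maf_min = 0.05, maf_max = 0.95,
                       frac_palindromic = 0, frac_strand_flipped = 0,
                       frac_allele_swapped = 0, seed = NULL) {
  scenario <- match.arg(scenario)
  gamma_dist <- match.arg(gamma_dist)
  stopifnot(L >= 1, gamma_sd >= 0, alpha_sd >= 0,
            all(se_x >= 0), all(se_y >= 0),
            frac_invalid >= 0, frac_invalid <= 1,
            frac_palindromic >= 0, frac_palindromic <= 1,
            frac_strand_flipped >= 0, frac_strand_flipped <= 1,
            frac_allele_swapped >= 0, frac_allele_swapped <= 1,
            rho >= -1, rho <= 1,
            maf_min >= 0, maf_max <= 1, maf_min < maf_max)
  structure(as.list(environment()), class = "sim_config")
}

## draw an allele pair; palindromic pairs are A/T or G/C (either order)
draw_alleles <- function(L, frac_palindromic) {
  pal <- stats::runif(L) < frac_palindromic
  e <- o <- character(L)
  pal_pairs <- matrix(c("A", "T", "T", "A", "G", "C", "C", "G"), ncol = 2,
                      byrow = TRUE)
  npal_pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C",
                         "G", "A", "C", "A", "G", "T", "C", "T"), ncol = 2,
                       byrow = TRUE)
  ip <- sample.int(4L, L, replace = TRUE)
  inp <- sample.int(8L, L, replace = TRUE)
  e[pal] <- pal_pairs[ip[pal], 1L]; o[pal] <- pal_pairs[ip[pal], 2L]
  e[!pal] <- npal_pairs[inp[!pal], 1L]; o[!pal] <- npal_pairs[inp[!pal], 2L]
  data.frame(effect_allele = e, other_allele = o, palindromic = pal,
             stringsAsFactors = FALSE)
}

#' Simulate a two-sample GWAS summary-statistic pair with known truth
#'
#' @param config A [sim_config()].
#' @return List with elements `exposure` and `outcome` (both `gwas_table`)
#'   and `truth` — a data.frame with the per-SNP true effects (`gamma`,
#'   `alpha`, `Gamma`), the exposure-oriented true outcome association
#'   (`beta_out_true`), the applied perturbations (`swapped`, `flipped`) and
#'   allele metadata, plus the config in its `"config"` attribute.
#' @export
simulate_two_sample <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set_seed_if(config$seed)
  L <- config$L
  gamma <- if (config$gamma_dist == "uniform") {
    half <- sqrt(3) * config$gamma_sd
    stats::runif(L, config$gamma_mean - half, config$gamma_mean + half)
  } else {
    stats::rnorm(L, config$gamma_mean, config$gamma_sd)
  }
  alpha <- rep(0, L)
  n_inv <- floor(config$frac_invalid * L)
  inv <- seq_len(n_inv)
  if (config$scenario == "balanced") {
    alpha[inv] <- stats::rnorm(n_inv, 0, config$alpha_sd)
  } else if (config$scenario == "directional") {
    alpha[inv] <- stats::rnorm(n_inv, config$alpha_mean, config$alpha_sd)
  } else if (config$scenario == "correlated") {
    gs <- if (config$gamma_sd > 0) (gamma[inv] - config$gamma_mean) / config$gamma_sd
          else rep(0, n_inv)
    alpha[inv] <- config$alpha_mean + config$alpha_sd *
      (config$rho * gs + sqrt(1 - config$rho^2) * stats::rnorm(n_inv))
  }
  Gamma <- config$theta * gamma + alpha
  se_x <- rep(config$se_x, length.out = L)
  se_y <- rep(config$se_y, length.out = L)
  bx <- gamma + (if (all(se_x == 0)) 0 else stats::rnorm(L, 0, se_x))
  by <- Gamma + (if (all(se_y == 0)) 0 else stats::rnorm(L, 0, se_y))
  eaf <- stats::runif(L, config$maf_min, config$maf_max)
  al <- draw_alleles(L, config$frac_palindromic)
  snp <- sprintf("rs%06d", seq_len(L))
  pnorm2 <- function(b, se) ifelse(se > 0, 2 * stats::pnorm(-abs(b / se)), 0)

  exposure <- gwas_table(
    data.frame(snp = snp, effect_allele = al$effect_allele,
               other_allele = al$other_allele, beta = bx,
               se = pmax(se_x, 1e-12), eaf = eaf, pval = pnorm2(bx, se_x),
               n = config$n_exp, stringsAsFactors = FALSE),
    phenotype_name = "simulated exposure", phenotype_id = "sim-exp",
    units = "SD")

  ## outcome table: same underlying orientation, then reporting perturbations
  swapped <- stats::runif(L) < config$frac_allele_swapped
  flipped <- stats::runif(L) < config$frac_strand_flipped
  o_e <- al$effect_allele; o_o <- al$other_allele
  o_b <- by; o_eaf <- eaf
  ## allele-label swap: same information, opposite reference allele
  o_e[swapped] <- al$other_allele[swapped]
  o_o[swapped] <- al$effect_allele[swapped]
  o_b[swapped] <- -o_b[swapped]
  o_eaf[swapped] <- 1 - o_eaf[swapped]
  ## strand flip: complementary labels, statistics unchanged
  o_e[flipped] <- comp_allele(o_e[flipped])
  o_o[flipped] <- comp_allele(o_o[flipped])

  outcome <- gwas_table(
    data.frame(snp = snp, effect_allele = o_e, other_allele = o_o, beta = o_b,
               se = pmax(se_y, 1e-12), eaf = o_eaf, pval = pnorm2(by, se_y),
               n = config$n_out, stringsAsFactors = FALSE),
    phenotype_name = "simulated outcome", phenotype_id = "sim-out",
    units = "SD")

  truth <- data.frame(snp = snp, gamma = gamma, alpha = alpha, Gamma = Gamma,
                      beta_out_true = by, eaf = eaf,
                      palindromic = al$palindromic, swapped = swapped,
                      flipped = flipped, stringsAsFactors = FALSE)
  attr(truth, "config") <- config
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Canonical simulation scenario grid
#'
#' Named configurations derived from a base config: `null_effect` (theta = 0,
#' type-I error), `moderate_effect` (power/bias), `directional_invalid40`
#' (40% of SNPs carry a directional pleiotropic effect; median robustness),
#' `inside_violation` (pleiotropy correlated with instrument strength), and
#' `palindrome_rich` (half the SNPs palindromic with strand flips and allele
#' swaps; harmonisation stress test).
#'
#' @param base A [sim_config()] supplying shared parameters.
#' @return Named list of `sim_config` objects.
#' @export
scenario_suite <- function(base = sim_config()) {
  stopifnot(inherits(base, "sim_config"))
  base_args <- unclass(base)
  mk <- function(...) do.call(sim_config, utils::modifyList(base_args, list(...)))
  list(
    null_effect = mk(theta = 0, scenario = "none"),
    moderate_effect = mk(theta = 0.2, scenario = "none"),
    directional_invalid40 = mk(scenario = "directional", frac_invalid = 0.4,
                               alpha_mean = 0.1, alpha_sd = 0),
    inside_violation = mk(scenario = "correlated", alpha_mean = 0.05,
                          alpha_sd = 0.02, rho = 0.7, frac_invalid = 1),
    palindrome_rich = mk(frac_palindromic = 0.5, frac_strand_flipped = 0.3,
                         frac_allele_swapped = 0.3)
  )
}
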