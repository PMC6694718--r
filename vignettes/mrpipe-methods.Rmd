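---
title: "Two-sample Mendelian randomization with mrpipe: models, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Mendelian randomization (MR) estimates the causal effect of an exposure on an
outcome by using genetic variants as instrumental variables. A valid
instrument SNP must (i) associate with the exposure, (ii) affect the outcome
only through the exposure (no horizontal pleiotropy), and (iii) share no
common cause with the outcome. In the *two-sample* design, the SNP–exposure
associations $(\hat\beta_{Xj}, \sigma_{Xj})$ and SNP–outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ come from summary statistics of two separate,
non-overlapping GWAS samples, so no individual-level data are needed.

`mrpipe` implements this design offline: summary-table ingestion and
validation, allele harmonisation, instrument selection and LD clumping, a
suite of causal-effect estimators behind one fitting function (`mr_fit()`),
the standard sensitivity battery, a synthetic-data generator with known
causal truth, and a command-line pipeline (`inst/cli/mrpipe.R`). No remote
database or LD reference panel is used; LD information is injected as plain
files (a pairwise $r^2$ matrix, a proxy table), which keeps every analysis
reproducible and testable on a desk.

## Harmonisation

Both studies must express effects for the same effect allele. For each SNP
the outcome record is aligned to the exposure's alleles through a
deterministic truth table: identical alleles are kept; swapped labels negate
$\hat\beta_Y$ and reflect the effect-allele frequency ($p \mapsto 1-p$);
strand-complemented labels are matched after complementing and then treated
the same way; anything irreconcilable is dropped with a recorded reason.

Palindromic SNPs (A/T, G/C) are special: their strand cannot be resolved
from labels, because the complement of the pair is the pair itself. Under
the default policy (`action = 2`) orientation is inferred from allele
frequency: with MAF threshold $t = 0.3$, if both studies' frequencies lie on
the same side of the $(t, 1-t)$ window the alleles are taken as aligned, on
opposite sides the orientation is flipped, and if either frequency falls
inside the window (or is missing) the SNP is flagged ambiguous and excluded
— close to 0.5 the effect allele cannot be inferred. Boundary values count
as ambiguous (strict inequalities): the conservative reading. `action = 1`
trusts the forward strand; `action = 3` drops every palindromic SNP. Indel
alleles (length > 1) are accepted but never classed palindromic.

Exposure SNPs absent from the outcome study can be replaced by an LD proxy
with $r^2 \ge 0.8$ (ties resolved by larger $r^2$, then lexicographic proxy
id), with proxy alleles translated through an explicit phase map. Only the
outcome record is ever proxied.

## Estimators

All multi-SNP estimators operate on the per-SNP Wald ratios
$r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ or, equivalently, on weighted
regressions of $\hat\beta_Y$ on $\hat\beta_X$:

* **Wald ratio** (single SNP): $\hat\theta = r_j$, first-order SE
  $\sigma_{Yj}/|\hat\beta_{Xj}|$ (exposure-side error ignored — the NOME
  assumption).
* **IVW**: zero-intercept weighted regression with weights
  $w_j = \sigma_{Yj}^{-2}$, i.e.
  $\hat\theta = \sum w_j \hat\beta_{Xj}\hat\beta_{Yj} / \sum w_j \hat\beta_{Xj}^2$.
  The fixed-effect SE is $(\sum w_j\hat\beta_{Xj}^2)^{-1/2}$; the
  multiplicative random-effects variant scales it by the residual dispersion
  $\hat\sigma = \sqrt{Q/(L-1)}$; the default applies $\max(1,\hat\sigma)$ so
  under-dispersion never shrinks the SE below fixed-effect.
* **MR-Egger**: the same regression with a free intercept, after orienting
  every pair so $\hat\beta_{Xj} \ge 0$. The slope is the causal estimate;
  the intercept estimates average directional pleiotropy. Valid under
  InSIDE (instrument strength independent of the direct effects). SEs are
  inflated by $\max(1,\hat\sigma)$; inference uses a $t$ with $L-2$ df. A
  bootstrap variant resamples the summary statistics from their normal
  sampling errors.
* **Median estimators**: the interpolated weighted median of the ratios,
  with equal weights (simple), inverse-variance weights (weighted), or
  weights multiplied by $\min(1, 20\,p_j)$ where $p_j$ is the upper
  $\chi^2_1$ tail of SNP $j$'s heterogeneity contribution about the
  weighted-median fit (penalised). Consistent when more than half the
  weight is on valid instruments.
* **Mode estimators**: the argmax of a weighted Gaussian KDE of the ratios
  (bandwidth $\varphi \times$ Silverman reference, evaluated on a
  1000-point grid spanning the ratios $\pm 3$ bandwidths). Valid under
  ZEMPA — the modal pleiotropic bias is zero. The NOME variants use the
  first-order ratio SE in the weights; the default weighted variant keeps
  the exposure-side delta-method term.
* **Maximum likelihood**: joint normal model
  $\hat\beta_{Xj} \sim N(\xi_j, \sigma_{Xj}^2)$,
  $\hat\beta_{Yj} \sim N(\theta\xi_j, \sigma_{Yj}^2)$, maximised by BFGS
  with analytic gradient (objective tolerance $10^{-10}$, initialised at
  $\xi = \hat\beta_X$, $\theta = \hat\theta_{IVW}$); SE from the observed
  information.

P-value conventions follow the published results table they reproduce:
standard normal for the Wald ratio, IVW, maximum likelihood and the median
methods; $t_{L-2}$ for the Egger slope and intercept; $t_{L-1}$ for the
mode methods. Estimates stay on the exposure-unit (or log-odds) scale;
`beta_to_or()` exponentiates only when the caller knows the outcome is on
the log-odds scale — units are metadata, never guessed.

### Bootstrap standard errors

The median and mode SEs come from seeded parametric bootstraps
(default 1000 replicates). The median bootstrap re-noises the observed
summary statistics — near-exact for a quantile statistic. The mode
bootstrap instead draws from the *fitted* ratio model
($\hat\beta^{*}_{Yj} \sim N(\hat\theta\,\hat\beta_{Xj}, \sigma_{Yj})$):
re-noising the observed statistics doubles the dispersion of the bootstrap
ratio cloud, and a density-argmax statistic — unlike a mean or median — is
directly sensitive to that widening, which overstates its SE by roughly
$\sqrt 2$ and pushes coverage far above nominal. The mode SE is the median
absolute deviation of the bootstrap modes (robust to the occasional
replicate whose argmax jumps to a minor cluster); the median SE is the
bootstrap SD.

## Sensitivity battery

* **Cochran's Q** about the IVW ($df = L-1$) and Egger ($df = L-2$) fits,
  with $\chi^2$ upper-tail p-values; excess heterogeneity is a pleiotropy
  red flag, and the Egger residual Q never exceeds the IVW Q.
* **Egger intercept** as the directional-pleiotropy test.
* **Steiger-style direction test**: per-SNP variance explained
  $r^2_j = t_j^2/(t_j^2 + n - 2)$ summed per study; the assumed direction
  is supported when the instrument explains more variance in the exposure
  than in the outcome, with a Fisher-z comparison of the aggregate
  correlations. The per-SNP $r^2$ are aggregated by summation (the exact
  aggregation is a design choice; summation treats the instrument as a
  whole). For binary traits the same $t$-statistic form is applied on the
  log-odds scale — a documented approximation. The result is a flag, never
  an effect estimate.
* **Leave-one-out** (default IVW omitting each SNP, plus an `All` row),
  **single-SNP** forest data (per-SNP Wald ratios plus IVW/Egger overall
  rows), **funnel** data (ratio vs precision $1/s_j$) and **scatter** data
  (effect pairs oriented $\hat\beta_X \ge 0$, one line per method).
  Single-SNP instruments skip the multi-SNP analyses and all plots.

## The synthetic-data generator

`simulate_two_sample()` draws true instrument effects $\gamma_j$, pleiotropic
effects $\alpha_j$ per scenario (`none`, `balanced`, `directional`,
`correlated` — the last violating InSIDE through a planted
$\mathrm{cor}(\gamma, \alpha) = \rho$), sets
$\Gamma_j = \theta\gamma_j + \alpha_j$, and observes
$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_X^2)$,
$\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_Y^2)$ with independent noise (no
sample overlap, the two-sample assumption). Reported p-values are the
two-sided normal p of $\hat\beta/\sigma$; allele pairs, palindromic
fraction, allele-label swaps and strand flips exercise the harmonisation
layer, with every perturbation recorded in a truth table.

Defaults, chosen once as the package's study conditions:

* $\gamma_j \sim \mathrm{Uniform}(0.05, 0.35)$ SD units (parametrised as
  mean 0.2, sd $0.3/\sqrt{12}$). Instruments selected at genome-wide
  significance are reported for the exposure-increasing allele, so true
  effects are positive and bounded away from zero; this also keeps Wald
  ratios well-behaved and leaves the oriented pleiotropy mean undistorted
  by Egger's sign-orientation step. A `gamma_dist = "normal"` option exists
  for unselected effect distributions.
* $\sigma_X = 0.01$, $\sigma_Y = 0.05$: a strong exposure GWAS (the NOME
  regime most estimators assume) and a moderately powered outcome GWAS.
  Weak-instrument studies should raise $\sigma_X$ explicitly.
* Effect-allele frequencies $\sim \mathrm{Uniform}(0.05, 0.95)$, shared
  between the two samples (same source population).

What the generator does *not* emulate: LD between instruments (clumping is
tested against explicit LD-matrix fixtures instead), sample overlap, winner's
curse from instrument selection, allele-frequency differences between
populations, and non-normal sampling error. Passing calibration tests on
this generator therefore demonstrates correctness of the estimators under
their stated assumptions, not robustness to every failure mode of real data.

`scenario_suite()` fixes the canonical grid: a null-effect configuration
(type-I error), a moderate effect ($\theta = 0.2$; bias/coverage), a
40%-invalid directional configuration (median robustness), an InSIDE
violation, and a palindrome-rich configuration (harmonisation stress test).

## Numerical choices and degenerate inputs

* Zero exposure effects make the Wald ratio undefined: a hard error, never a
  silent drop. Collinear (all-equal) oriented exposure effects make the
  Egger slope unidentifiable: a hard error.
* Weighted-median interpolation uses the cumulative normalized weight
  crossing 0.5; ties in ratios are handled by ordered interpolation.
* If every ratio is identical the Silverman bandwidth is zero and the mode
  estimator returns that common value directly.
* Duplicate SNP ids within a table keep the record with the smallest
  p-value (missing p-values sort last) — the strongest-evidence convention.
* Clumping breaks p-value ties lexicographically by SNP id, making the
  output invariant to input row order; SNPs missing from the LD matrix are
  treated as independent with a logged warning.
* Floats are written with 15 significant digits, so read–write round trips
  are stable to below $10^{-9}$ relative error.

## Simulation-study sizes

The calibration studies in the test suite and the acceptance script use 500
replicates for parameter recovery and type-I error (L = 100 SNPs,
$\theta = 0.2$ or $0$), 200 replicates for the pleiotropy studies, and 200
bootstrap replicates inside each replicate; these sizes give Monte-Carlo
standard errors comfortably below the quantities being checked (about
0.001 on a mean estimate, about 1 percentage point on a coverage). Method
defaults for end users remain 1000 bootstrap replicates.

## Known limitations

* The Wald-ratio SE is first-order; with weak instruments
  ($\sigma_X/|\hat\beta_X|$ not small) it understates the true ratio
  variability.
* The direction test's variance-explained formula is exact for continuous
  traits only; for log-odds effects it is an approximation.
* The mode estimator's model-centred bootstrap assumes the no-pleiotropy
  ratio model when estimating its SE; under strong heterogeneity it can
  understate the SE (the heterogeneity statistics are the intended guard).
* No multivariable MR, no LD-aware estimators, and no correction for sample
  overlap: overlapping samples bias estimates and are the caller's
  responsibility to avoid.
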