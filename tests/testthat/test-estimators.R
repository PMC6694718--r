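test_that("Wald ratio point estimate and first-order SE", {
  r <- mr_wald_ratio(1, 0.01, 0.5663, 0.0905)
  expect_equal(r$b, 0.5663)
  expect_equal(r$se, 0.0905)
  r2 <- mr_wald_ratio(2, 0.01, 1.0, 0.2)
  expect_equal(r2$b, 0.5)
  expect_equal(r2$se, 0.1)
  expect_error(mr_wald_ratio(0, 0.01, 0.1, 0.1), "undefined ratio")
})

test_that("first-order Wald SE agrees with a Monte-Carlo ratio oracle when the instrument is strong", {
  set.seed(42)
  bx <- 0.1; bxse <- 0.002; by <- 0.02; byse <- 0.01
  draws <- rnorm(1e6, by, byse) / rnorm(1e6, bx, bxse)
  r <- mr_wald_ratio(bx, bxse, by, byse)
  # first-order SE ignores exposure noise: with bxse/bx = 2% the MC sd is
  # within a few percent of byse/|bx|
  expect_equal(r$se, sd(draws), tolerance = 0.05)
})

test_that("IVW reduces to the common Wald ratio for identical SNPs", {
  dat <- make_dataset(bx = c(0.2, 0.2), by = c(0.1, 0.1), byse = c(0.05, 0.05))
  expect_equal(mr_ivw(dat)$b, 0.5)
  expect_error(mr_ivw(make_dataset(0.2, 0.1, 0.05)), ">= 2 SNPs")
})

test_that("IVW and Egger match the generic weighted-least-squares oracle", {
  set.seed(101)
  for (i in 1:25) {
    L <- sample(3:20, 1)
    bx <- rnorm(L, 0.2, 0.1); by <- rnorm(L, 0.05, 0.1)
    byse <- runif(L, 0.01, 0.2)
    dat <- make_dataset(bx, by, byse)
    o <- wls_oracle(bx, by, byse)
    fe <- mr_ivw(dat, "fe")
    expect_equal(fe$b, unname(o$coef), tolerance = 1e-10)
    expect_equal(fe$se, unname(o$se_fe), tolerance = 1e-10)
    # Egger fits on exposure-positive orientation; oracle on oriented data
    s <- ifelse(bx < 0, -1, 1)
    oe <- wls_oracle(s * bx, s * by, byse, intercept = TRUE)
    eg <- mr_egger(dat)
    expect_equal(eg$slope$b, unname(oe$coef[2]), tolerance = 1e-10)
    expect_equal(eg$intercept$intercept, unname(oe$coef[1]), tolerance = 1e-10)
    expect_equal(eg$slope$se, unname(oe$se_fe[2]) * max(1, oe$sigma),
                 tolerance = 1e-8)
  }
})

test_that("IVW variants order their standard errors as specified", {
  set.seed(55)
  for (i in 1:10) {
    L <- sample(3:15, 1)
    dat <- make_dataset(rnorm(L, 0.2, 0.05), rnorm(L, 0.04, 0.08),
                        runif(L, 0.02, 0.1))
    fe <- mr_ivw(dat, "fe"); mre <- mr_ivw(dat, "mre"); def <- mr_ivw(dat)
    expect_equal(fe$b, mre$b)
    expect_gte(def$se, fe$se)                       # max(1, sigma) floor
    expect_equal(def$se, max(fe$se, mre$se))
  }
})

test_that("Egger recovers planted intercept and slope exactly on noiseless data", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  by <- 0.03 + 0.5 * bx
  dat <- make_dataset(bx, by, rep(0.05, 4))
  eg <- mr_egger(dat)
  expect_equal(eg$slope$b, 0.5, tolerance = 1e-12)
  expect_equal(eg$intercept$intercept, 0.03, tolerance = 1e-12)
  expect_error(mr_egger(make_dataset(c(0.1, 0.2), c(0.1, 0.2), c(0.1, 0.1))),
               ">= 3 SNPs")
  expect_error(mr_egger(make_dataset(rep(0.2, 4), rnorm(4), rep(0.1, 4))),
               "collinear|unidentifiable")
})

test_that("Egger output is invariant to simultaneous sign flips of any SNP", {
  set.seed(9)
  bx <- rnorm(8, 0.2, 0.1); by <- rnorm(8, 0.05, 0.05); byse <- runif(8, 0.02, 0.1)
  base <- mr_egger(make_dataset(bx, by, byse))
  flip <- c(1, -1, 1, -1, -1, 1, 1, -1)
  flipped <- mr_egger(make_dataset(flip * bx, flip * by, byse))
  expect_equal(base$slope$b, flipped$slope$b)
  expect_equal(base$intercept$intercept, flipped$intercept$intercept)
})

test_that("Egger bootstrap SE is close to the analytic SE on well-behaved data", {
  set.seed(12)
  L <- 30
  bx <- rnorm(L, 0.2, 0.08); byse <- rep(0.05, L)
  by <- 0.01 + 0.3 * bx + rnorm(L, 0, 0.05)
  dat <- make_dataset(bx, by, byse)
  an <- mr_egger(dat)
  bo <- mr_egger(dat, bootstrap = TRUE, reps = 800, seed = 4)
  expect_equal(bo$slope$method, "egger_bootstrap")
  expect_equal(bo$slope$se, an$slope$se, tolerance = 0.35)
})

test_that("median estimators: exact odd-n median and weight-concentration limit", {
  dat <- make_dataset(bx = rep(1, 5), by = 1:5, byse = rep(1, 5))
  expect_equal(mr_median(dat, "simple", reps = 50, seed = 1)$b, 3)
  # one SNP holding ~99% of the weight pins the weighted median
  byse <- c(rep(10, 4), 0.01)
  dat2 <- make_dataset(bx = rep(1, 5), by = c(1, 2, 3, 4, 2.5), byse = byse)
  expect_equal(mr_median(dat2, "weighted", reps = 50, seed = 1)$b, 2.5,
               tolerance = 1e-6)
  expect_error(mr_median(make_dataset(c(1, 1), c(1, 2), c(1, 1))), ">= 3 SNPs")
})

test_that("weighted median equals the cumulative-weight scan oracle", {
  set.seed(77)
  for (i in 1:30) {
    L <- sample(3:15, 1)
    r <- rnorm(L); w <- runif(L, 0.1, 2)
    bx <- runif(L, 0.5, 1.5)
    byse <- abs(bx) / sqrt(w)     # so implementation weights equal w
    dat <- make_dataset(bx, r * bx, byse)
    got <- mr_median(dat, "weighted", reps = 2, seed = 1)$b
    expect_equal(got, wmedian_oracle(r, w), tolerance = 1e-12)
  }
})

test_that("penalised median down-weights the heterogeneity outlier", {
  bx <- rep(1, 7)
  by <- c(0.2, 0.21, 0.19, 0.2, 0.22, 0.18, 5)   # one gross outlier
  byse <- rep(0.05, 7)
  dat <- make_dataset(bx, by, byse)
  pen <- mr_median(dat, "penalised", reps = 50, seed = 2)$b
  expect_lt(abs(pen - 0.2), 0.05)
})

test_that("mode estimators find the largest ratio cluster", {
  # point mass: any bandwidth multiplier returns the common ratio
  dat <- make_dataset(bx = rep(1, 4), by = rep(0.7, 4), byse = rep(0.1, 4))
  for (phi in c(0.25, 1, 4))
    expect_equal(mr_mode(dat, "simple", phi = phi, reps = 20, seed = 1)$b, 0.7)
  # largest cluster wins under equal weights
  dat2 <- make_dataset(bx = rep(1, 4), by = c(0.2, 0.2, 0.2, 0.9),
                       byse = rep(0.1, 4))
  r <- c(0.2, 0.2, 0.2, 0.9)
  h <- 0.9 * min(sd(r), IQR(r) / 1.349) * 4^(-0.2)
  b <- mr_mode(dat2, "simple", reps = 20, seed = 1)$b
  oracle <- kde_argmax_oracle(r, rep(1, 4), h)
  step <- (diff(range(r)) + 6 * h) / 999
  expect_lt(abs(b - oracle), 2 * step + 1e-12)
  expect_lt(abs(b - 0.2), 3 * step + h / 2)
  # weight concentration moves the weighted mode to ~0.9
  byse3 <- c(rep(1, 3), 0.01)
  dat3 <- make_dataset(bx = rep(1, 4), by = c(0.2, 0.2, 0.2, 0.9), byse = byse3)
  b3 <- mr_mode(dat3, "weighted", reps = 20, seed = 1)$b
  expect_lt(abs(b3 - 0.9), 0.05)
  expect_error(mr_mode(dat2, phi = 0), "phi")
  expect_error(mr_mode(make_dataset(c(1, 1), c(1, 2), c(1, 1))), ">= 3 SNPs")
})

test_that("mode KDE argmax matches a direct grid oracle on random ratios", {
  set.seed(13)
  for (i in 1:10) {
    L <- sample(5:20, 1)
    bx <- rep(1, L)
    by <- rnorm(L, 0.3, 0.2)
    dat <- make_dataset(bx, by, rep(0.1, L))
    got <- mr_mode(dat, "simple", reps = 2, seed = 1)$b
    h <- 0.9 * min(sd(by), IQR(by) / 1.349) * L^(-0.2)
    oracle <- kde_argmax_oracle(by, rep(1, L), h)
    step <- (diff(range(by)) + 6 * h) / 999
    expect_lt(abs(got - oracle), 2 * step + 1e-12)
  }
})

test_that("maximum likelihood recovers truth and its limits", {
  # noiseless consistent data: theta-hat equals truth
  bx <- c(0.1, 0.2, 0.3, 0.25)
  dat <- make_dataset(bx, 0.4 * bx, rep(0.05, 4), bxse = rep(0.05, 4))
  expect_equal(mr_maxlik(dat)$b, 0.4, tolerance = 1e-6)
  # se_x -> 0 limit approaches the fixed-effect IVW estimate
  set.seed(8)
  bx <- rnorm(10, 0.2, 0.05); by <- 0.3 * bx + rnorm(10, 0, 0.04)
  dat2 <- make_dataset(bx, by, rep(0.04, 10), bxse = rep(1e-8, 10))
  expect_equal(mr_maxlik(dat2)$b, mr_ivw(dat2, "fe")$b, tolerance = 1e-4)
})

test_that("maximum likelihood matches a 2-D profile grid search on 2 SNPs", {
  bx <- c(0.15, 0.3); by <- c(0.06, 0.1)
  bxse <- c(0.03, 0.03); byse <- c(0.04, 0.04)
  dat <- make_dataset(bx, by, byse, bxse = bxse)
  got <- mr_maxlik(dat)$b
  # profile out xi analytically on a theta grid
  prof <- function(th) {
    xi <- (bx / bxse^2 + th * by / byse^2) / (1 / bxse^2 + th^2 / byse^2)
    sum((bx - xi)^2 / bxse^2 + (by - th * xi)^2 / byse^2)
  }
  grid <- seq(-1, 2, length.out = 20001)
  expect_equal(got, grid[which.min(vapply(grid, prof, 1))],
               tolerance = 2 * diff(grid[1:2]))
})

test_that("mr_fit reduces to the Wald ratio for single-SNP datasets", {
  dat <- make_dataset(0.2, 0.1, 0.05)
  fit <- mr_fit(dat)   # default multi-SNP methods requested
  expect_equal(nrow(fit), 1L)
  expect_equal(fit$method, "wald_ratio")
  expect_equal(fit$b, 0.5)
})

test_that("mr_fit returns requested methods in order with the standard table layout", {
  set.seed(2)
  L <- 20
  bx <- rnorm(L, 0.2, 0.08); by <- 0.25 * bx + rnorm(L, 0, 0.03)
  dat <- make_dataset(bx, by, rep(0.03, L))
  fit <- mr_fit(dat, methods = c("ivw", "egger", "weighted_median"),
                reps = 100, seed = 3)
  expect_equal(fit$method, c("ivw", "egger", "weighted_median"))
  expect_true(all(fit$nsnp == L))
  tab <- mr_results_table(fit)
  expect_identical(names(tab), c("id.exposure", "id.outcome", "outcome",
                                 "exposure", "method", "nsnp", "b", "se",
                                 "pval"))
  expect_identical(tab$method[2], "MR Egger")
  # round trip through the writer keeps the layout
  path <- tempfile(fileext = ".tsv")
  write_mr_table(tab, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(names(back), names(tab))
})

test_that("estimates are scale-equivariant in the outcome and exposure units", {
  set.seed(15)
  L <- 12
  bx <- rnorm(L, 0.2, 0.08); by <- 0.3 * bx + rnorm(L, 0, 0.02)
  byse <- runif(L, 0.01, 0.05)
  dat <- make_dataset(bx, by, byse)
  c_y <- 3.7; c_x <- 0.4
  dat_y <- make_dataset(bx, c_y * by, c_y * byse)
  dat_x <- make_dataset(c_x * bx, by, byse)
  for (f in list(function(d) mr_ivw(d), function(d) mr_egger(d)$slope,
                 function(d) mr_median(d, "weighted", reps = 2, seed = 1))) {
    base <- f(dat)
    expect_equal(f(dat_y)$b, c_y * base$b, tolerance = 1e-10)
    expect_equal(f(dat_y)$se, c_y * base$se, tolerance = 1e-10)
    expect_equal(f(dat_x)$b, base$b / c_x, tolerance = 1e-10)
  }
})

test_that("odds-ratio conversion and p-value conventions behave at the edges", {
  or0 <- beta_to_or(0, 0.1)
  expect_equal(or0$or, 1)
  expect_equal(or0$ci_low * or0$ci_high, 1, tolerance = 1e-12)  # symmetric on log scale
  expect_equal(mr_pvalue(0, 0.1, 10, "ivw"), 1)
  expect_equal(mr_pvalue(0, 0.1, 10, "egger"), 1)
  expect_error(mr_pvalue(0.1, 0.1, 2, "egger"), "df")
  # mode uses t with L - 1 df, egger t with L - 2: heavier tails than normal
  expect_gt(mr_pvalue(0.2, 0.1, 5, "weighted_mode"),
            mr_pvalue(0.2, 0.1, 5, "ivw"))
  expect_gt(mr_pvalue(0.2, 0.1, 5, "egger"),
            mr_pvalue(0.2, 0.1, 5, "weighted_mode"))
})
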