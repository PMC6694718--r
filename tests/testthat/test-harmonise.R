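rec <- function(ea, oa, beta = 0.1, se = 0.02, eaf = NA) {
  list(effect_allele = ea, other_allele = oa, beta = beta, se = se, eaf = eaf)
}

two_tables <- function(exp_df, out_df) {
  list(exposure = gwas_table(exp_df, phenotype_name = "X"),
       outcome = gwas_table(out_df, phenotype_name = "Y",
                            phenotype_id = "Y"))
}

test_that("palindromic classification covers A/T, G/C and indels", {
  expect_true(is_palindromic("A", "T"))
  expect_true(is_palindromic("T", "A"))
  expect_true(is_palindromic("G", "C"))
  expect_true(is_palindromic("c", "g"))
  expect_false(is_palindromic("A", "G"))
  expect_false(is_palindromic("AT", "T"))   # indel never palindromic
  expect_false(is_palindromic("A", "A"))
})

test_that("allele-swap rule negates the outcome beta and reflects eaf", {
  al <- align_pair(rec("A", "G", beta = 0.1), rec("G", "A", beta = -0.1, eaf = 0.8))
  expect_true(al$mr_keep)
  expect_equal(al$beta_out, 0.1)
  expect_equal(al$eaf_out, 0.2)
  # double application of the swap is the identity
  al2 <- align_pair(rec("A", "G"), rec("A", "G", beta = al$beta_out, eaf = al$eaf_out))
  expect_equal(al2$beta_out, 0.1)
  expect_false(al2$flipped)
})

test_that("strand flips are resolved by complementing for non-palindromic SNPs", {
  # T/C on the other strand reads A/G
  keep <- align_pair(rec("T", "C", beta = 0.3), rec("A", "G", beta = 0.3, eaf = 0.4))
  expect_true(keep$mr_keep)
  expect_equal(keep$beta_out, 0.3)
  # flip + swap
  fs <- align_pair(rec("T", "C", beta = 0.3), rec("G", "A", beta = 0.3, eaf = 0.4))
  expect_equal(fs$beta_out, -0.3)
  expect_equal(fs$eaf_out, 0.6)
})

test_that("palindromic SNPs under action 2 are oriented by allele frequency", {
  # same low side: aligned
  same <- align_pair(rec("A", "T", eaf = 0.1), rec("A", "T", beta = 0.2, eaf = 0.12))
  expect_true(same$mr_keep)
  expect_equal(same$beta_out, 0.2)
  # opposite sides: flipped
  opp <- align_pair(rec("A", "T", eaf = 0.10), rec("A", "T", beta = 0.2, eaf = 0.91))
  expect_true(opp$mr_keep)
  expect_equal(opp$beta_out, -0.2)
  expect_equal(opp$eaf_out, 0.09)
  # frequency near 0.5: ambiguous, dropped
  amb <- align_pair(rec("G", "C", eaf = 0.50), rec("G", "C", beta = 0.2, eaf = 0.5))
  expect_false(amb$mr_keep)
  expect_true(amb$ambiguous)
  # missing eaf on either side: ambiguous
  expect_false(align_pair(rec("A", "T", eaf = NA),
                          rec("A", "T", beta = 0.2, eaf = 0.1))$mr_keep)
})

test_that("action 1 trusts labels and action 3 drops all palindromes", {
  a1 <- align_pair(rec("A", "T", eaf = 0.5), rec("T", "A", beta = 0.2, eaf = 0.5),
                   action = 1)
  expect_true(a1$mr_keep)
  expect_equal(a1$beta_out, -0.2)
  a3 <- align_pair(rec("A", "T", eaf = 0.1), rec("A", "T", beta = 0.2, eaf = 0.1),
                   action = 3)
  expect_false(a3$mr_keep)
  # maf_threshold = 0.5 behaves like action 1 for frequency-consistent SNPs
  wide <- align_pair(rec("A", "T", eaf = 0.35), rec("A", "T", beta = 0.2, eaf = 0.4),
                     maf_threshold = 0.5)
  expect_true(wide$mr_keep)
  expect_equal(wide$beta_out, 0.2)
  # maf_threshold -> 0 makes every palindrome ambiguous
  tight <- align_pair(rec("A", "T", eaf = 0.01), rec("A", "T", beta = 0.2, eaf = 0.01),
                      maf_threshold = 1e-9)
  expect_false(tight$mr_keep)
})

test_that("irreconcilable alleles are dropped, not raised", {
  bad <- align_pair(rec("A", "G"), rec("A", "C", beta = 0.2, eaf = 0.4))
  expect_false(bad$mr_keep)
  expect_match(bad$reason, "incompatible")
})

test_that("harmonising identical tables keeps everything unchanged", {
  df <- data.frame(snp = c("rs1", "rs2", "rs3"), effect_allele = c("A", "T", "G"),
                   other_allele = c("G", "C", "A"), beta = c(0.1, -0.2, 0.05),
                   se = 0.02, eaf = c(0.2, 0.4, 0.7), pval = 1e-9, n = 1e4)
  tt <- two_tables(df, df)
  dat <- harmonise(tt$exposure, tt$outcome)
  expect_equal(nrow(dat), 3L)
  expect_true(all(dat$mr_keep))
  expect_equal(dat$beta_out, df$beta[order(df$snp)])
})

test_that("harmonisation is idempotent", {
  set.seed(3)
  sim <- simulate_two_sample(sim_config(L = 30, seed = 3, frac_palindromic = 0.4,
                                        frac_allele_swapped = 0.3,
                                        frac_strand_flipped = 0.3))
  dat <- harmonise(sim$exposure, sim$outcome)
  kept <- dat[dat$mr_keep, ]
  exp2 <- gwas_table(data.frame(snp = kept$snp, effect_allele = kept$effect_allele,
                                other_allele = kept$other_allele,
                                beta = kept$beta_exp, se = kept$se_exp,
                                eaf = kept$eaf_exp, pval = kept$pval_exp,
                                n = kept$n_exp))
  out2 <- gwas_table(data.frame(snp = kept$snp, effect_allele = kept$effect_allele,
                                other_allele = kept$other_allele,
                                beta = kept$beta_out, se = kept$se_out,
                                eaf = kept$eaf_out, n = kept$n_out))
  dat2 <- harmonise(exp2, out2)
  expect_equal(dat2$beta_out, kept$beta_out)
  expect_equal(dat2$eaf_out, kept$eaf_out)
  expect_true(all(dat2$mr_keep))
})

test_that("proxy substitution honours the r2 floor and phase map", {
  exp_df <- data.frame(snp = c("rs1", "rs2"), effect_allele = "A",
                       other_allele = "G", beta = c(0.1, 0.2), se = 0.02,
                       eaf = 0.3, pval = 1e-9, n = 1e4)
  # outcome lacks rs1 and rs2; proxies exist for both
  out_df <- data.frame(snp = c("px1", "px2"), effect_allele = c("T", "C"),
                       other_allele = c("C", "T"), beta = c(0.05, 0.07),
                       se = 0.03, eaf = 0.4, pval = 0.01, n = 5e4)
  tt <- two_tables(exp_df, out_df)
  proxies <- proxy_table(data.frame(
    target_snp = c("rs1", "rs2"), proxy_snp = c("px1", "px2"),
    r2 = c(0.9, 0.7),
    proxy_a1 = c("T", "C"), proxy_a2 = c("C", "T"),
    target_a1 = c("A", "A"), target_a2 = c("G", "G")))
  dat <- harmonise(tt$exposure, tt$outcome, proxies = proxies)
  expect_equal(nrow(dat), 1L)            # rs2's proxy fails the 0.8 floor
  expect_equal(dat$snp, "rs1")
  expect_equal(dat$proxy_used, "px1")
  expect_equal(dat$beta_out, 0.05)       # T->A, C->G: same orientation
  # ties: larger r2 wins, then lexicographic proxy id
  out_df3 <- rbind(out_df,
                   data.frame(snp = "px0", effect_allele = "T", other_allele = "C",
                              beta = -0.2, se = 0.03, eaf = 0.4, pval = 0.01,
                              n = 5e4))
  proxies2 <- proxy_table(data.frame(
    target_snp = "rs1", proxy_snp = c("px1", "px0"), r2 = c(0.9, 0.9),
    proxy_a1 = "T", proxy_a2 = "C", target_a1 = "A", target_a2 = "G"))
  tt3 <- two_tables(exp_df[1, ], out_df3)
  dat3 <- harmonise(tt3$exposure, tt3$outcome, proxies = proxies2)
  expect_equal(dat3$proxy_used, "px0")
})

test_that("exposure SNPs absent from outcome without proxy are dropped; no overlap errors", {
  exp_df <- data.frame(snp = "rs1", effect_allele = "A", other_allele = "G",
                       beta = 0.1, se = 0.02, eaf = 0.3, pval = 1e-9, n = 1e4)
  out_df <- data.frame(snp = "rs9", effect_allele = "A", other_allele = "G",
                       beta = 0.1, se = 0.02, eaf = 0.3, pval = 1e-9, n = 1e4)
  tt <- two_tables(exp_df, out_df)
  expect_error(harmonise(tt$exposure, tt$outcome), "no SNPs remain")
})

test_that("planted strand flips and swaps are recovered on synthetic data", {
  sim <- simulate_two_sample(sim_config(L = 200, seed = 17, frac_palindromic = 0.5,
                                        frac_strand_flipped = 0.4,
                                        frac_allele_swapped = 0.4))
  dat <- harmonise(sim$exposure, sim$outcome, action = 2, maf_threshold = 0.3)
  m <- merge(as.data.frame(dat), sim$truth, by = "snp")
  kept <- m$mr_keep
  expect_gt(sum(kept), 0)
  expect_equal(m$beta_out[kept], m$beta_out_true[kept], tolerance = 1e-12)
  # every frequency-inferable SNP is kept; ambiguous ones are palindromic mid-MAF
  amb <- m$palindromic.x & !kept
  expect_true(all(m$eaf[amb] >= 0.3 & m$eaf[amb] <= 0.7))
  # under action 3 no palindromic SNP survives
  dat3 <- harmonise(sim$exposure, sim$outcome, action = 3)
  expect_false(any(dat3$palindromic & dat3$mr_keep))
})
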