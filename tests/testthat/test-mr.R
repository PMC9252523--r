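gw_tab <- function(snp, ea, oa, beta, se = 0.05, eaf = 0.3, pval = 0.01,
                   n = 1000) {
  gwas_summary(data.frame(snp_id = snp, effect_allele = ea, other_allele = oa,
                          eaf = eaf, beta = beta, se = se, pval = pval, n = n,
                          stringsAsFactors = FALSE))
}

test_that("harmonization aligns every allele configuration correctly", {
  ex <- gw_tab(paste0("rs", 1:6), rep("A", 6), rep("G", 6), beta = rep(0.1, 6),
               eaf = 0.2)
  ou <- gwas_summary(data.frame(
    snp_id = paste0("rs", 1:6),
    effect_allele = c("A", "G", "T", "C", "A", "C"),
    other_allele  = c("G", "A", "C", "T", "C", "A"),
    eaf = c(0.2, 0.8, 0.2, 0.8, 0.2, 0.5),
    beta = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
    se = 0.05, pval = 0.01, n = 1000, stringsAsFactors = FALSE))
  h <- harmonize_gwas(ex, ou)
  expect_equal(h$Gamma[1], 0.5)   # identical orientation
  expect_equal(h$Gamma[2], -0.5)  # swapped alleles
  expect_equal(h$Gamma[3], 0.5)   # opposite strand
  expect_equal(h$Gamma[4], -0.5)  # opposite strand + swapped
  expect_false(h$kept[5])         # A/C does not match A/G on either strand
  expect_identical(h$drop_reason[5], "allele_mismatch")
  expect_false(h$kept[6])
  expect_equal(sum(h$kept), 4L)
})

test_that("palindromic SNPs are resolved by allele frequency or dropped", {
  ex <- gw_tab(paste0("rs", 1:4), rep("A", 4), rep("T", 4), beta = rep(0.1, 4),
               eaf = c(0.2, 0.2, 0.5, 0.2))
  ou <- gwas_summary(data.frame(
    snp_id = paste0("rs", 1:4),
    effect_allele = "A", other_allele = "T",
    eaf = c(0.25, 0.78, 0.2, 0.5),
    beta = 0.4, se = 0.05, pval = 0.01, n = 1000, stringsAsFactors = FALSE))
  h <- harmonize_gwas(ex, ou)
  expect_true(h$kept[1]); expect_equal(h$Gamma[1], 0.4)  # same minor side
  expect_true(h$kept[2]); expect_equal(h$Gamma[2], -0.4) # opposite side: flip
  expect_identical(h$drop_reason[3], "palindromic_ambiguous") # exposure eaf 0.5
  expect_identical(h$drop_reason[4], "palindromic_ambiguous") # outcome eaf 0.5
})

test_that("harmonization requires a shared SNP", {
  ex <- gw_tab("rs1", "A", "G", 0.1)
  ou <- gw_tab("rs2", "A", "G", 0.1)
  expect_error(harmonize_gwas(ex, ou), "share no SNPs")
})

test_that("harmonizing simulator output recovers the aligned truth exactly", {
  cfg <- sim_config(seed = 6, n_snps = 300L, strand_flip_fraction = 0.25,
                    allele_swap_fraction = 0.25)
  gw <- simulate_gwas(cfg)
  h <- harmonize_gwas(gw$exposure, gw$outcome)
  expect_true(all(h$kept))
  expect_equal(h$Gamma, gw$truth$outcome_beta_aligned, tolerance = 1e-12)
  expect_equal(h$gamma, gw$exposure$beta, tolerance = 1e-12)
})

test_that("IVW reduces to exact and single-instrument limits", {
  h <- harmonize_gwas(gw_tab(paste0("rs", 1:3), "A", "G", c(1, 2, 3), se = 0.1),
                      gw_tab(paste0("rs", 1:3), "A", "G", c(0.5, 1, 1.5), se = 1))
  iv <- mr_ivw(h)
  expect_equal(iv$slope, 0.5, tolerance = 1e-12)
  expect_equal(iv$cochran_q, 0, tolerance = 1e-12)
  expect_equal(iv$i_squared, 0)
  expect_equal(iv$se_slope, 1 / sqrt(14), tolerance = 1e-12)

  h1 <- harmonize_gwas(gw_tab("rs1", "A", "G", 2, se = 0.1),
                       gw_tab("rs1", "A", "G", 0.6, se = 0.3))
  iv1 <- mr_ivw(h1)
  expect_equal(iv1$slope, 0.3)           # Wald ratio
  expect_equal(iv1$se_slope, 0.3 / 2)    # se_y / |gamma|

  h0 <- harmonize_gwas(gw_tab("rs1", "A", "G", 0), gw_tab("rs1", "A", "G", 1))
  expect_error(mr_ivw(h0), "zero")
})

test_that("Egger solves the weighted normal equations", {
  ex <- gw_tab(paste0("rs", 1:3), "A", "G", c(1, 2, 3), se = 0.01)
  ou <- gw_tab(paste0("rs", 1:3), "A", "G", 0.1 + 0.3 * c(1, 2, 3), se = 1)
  h <- harmonize_gwas(ex, ou)
  eg <- mr_egger(h)
  expect_equal(eg$slope, 0.3, tolerance = 1e-12)
  expect_equal(eg$intercept, 0.1, tolerance = 1e-12)
  expect_equal(eg$cochran_q, 0, tolerance = 1e-12)
  # the same three points fed to IVW are biased upward by the intercept
  expect_equal(mr_ivw(h)$slope, 4.8 / 14, tolerance = 1e-12)

  # vs weighted least squares (independent route) on an overdispersed fixture
  set.seed(8)
  g <- abs(rnorm(20, 0, 0.1)); G <- 0.05 + 0.25 * g + rnorm(20, 0, 0.03)
  se_y <- runif(20, 0.01, 0.05)
  h2 <- harmonize_gwas(gw_tab(paste0("r", 1:20), "A", "G", g, se = 0.001),
                       gw_tab(paste0("r", 1:20), "A", "G", G, se = se_y))
  eg2 <- mr_egger(h2)
  lmfit <- lm(G ~ g, weights = 1 / se_y^2)
  expect_equal(eg2$slope, unname(coef(lmfit)[2]), tolerance = 1e-10)
  expect_equal(eg2$intercept, unname(coef(lmfit)[1]), tolerance = 1e-10)
  if (eg2$cochran_q / 18 > 1) {
    sm <- summary(lmfit)$coefficients
    expect_equal(eg2$se_slope, sm["g", "Std. Error"], tolerance = 1e-10)
    expect_equal(eg2$se_intercept, sm["(Intercept)", "Std. Error"],
                 tolerance = 1e-10)
  }

  expect_error(mr_egger(h2[1:2, ]), "at least 3")
  hc <- harmonize_gwas(gw_tab(paste0("q", 1:3), "A", "G", c(1, -1, 1)),
                       gw_tab(paste0("q", 1:3), "A", "G", c(0.1, 0.2, 0.3)))
  expect_error(mr_egger(hc), "collinear")
})

test_that("estimators are invariant to allele re-coding and equivariant in scale", {
  set.seed(10)
  g <- abs(rnorm(30, 0, 0.1)); G <- 0.02 + 0.2 * g + rnorm(30, 0, 0.02)
  h <- harmonize_gwas(gw_tab(paste0("r", 1:30), "A", "G", g, se = 0.001),
                      gw_tab(paste0("r", 1:30), "A", "G", G, se = 0.02))
  flip <- rep(c(TRUE, FALSE), 15)
  h2 <- h
  h2$gamma[flip] <- -h2$gamma[flip]
  h2$Gamma[flip] <- -h2$Gamma[flip]
  expect_equal(mr_ivw(h2)$slope, mr_ivw(h)$slope, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$slope, mr_egger(h)$slope, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$intercept, mr_egger(h)$intercept, tolerance = 1e-12)

  h3 <- h
  h3$Gamma <- h3$Gamma * 2.5
  h3$se_y <- h3$se_y * 2.5
  expect_equal(mr_ivw(h3)$slope, 2.5 * mr_ivw(h)$slope, tolerance = 1e-12)
  expect_equal(mr_ivw(h3)$p_slope, mr_ivw(h)$p_slope, tolerance = 1e-12)
  expect_equal(mr_egger(h3)$intercept, 2.5 * mr_egger(h)$intercept,
               tolerance = 1e-12)
  expect_equal(mr_egger(h3)$p_intercept, mr_egger(h)$p_intercept,
               tolerance = 1e-12)
})

test_that("stratified MR isolates per-stratum failures", {
  gw_f <- simulate_gwas(sim_config(seed = 15, causal_beta = -0.1))
  ms <- mr_stratified(list(female = gw_f$exposure, male = gw_f$exposure),
                      list(female = gw_f$outcome, male = gw_f$outcome))
  expect_identical(ms$female$ivw$slope, ms$male$ivw$slope)

  bad <- gw_tab("nope", "A", "G", 0.1)
  ms2 <- mr_stratified(list(female = gw_f$exposure, male = gw_f$exposure),
                       list(female = gw_f$outcome, male = bad))
  expect_true(ms2$male$unavailable)
  expect_false(ms2$female$unavailable)
  expect_lt(ms2$female$egger$p_slope, 0.05)
  expect_true(all(ms2$comparison$stratum == "female"))

  expect_error(mr_stratified(list(other = gw_f$exposure),
                             list(other = gw_f$outcome)), "strata")
})
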