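test_that("identical config and seed give byte-identical outputs", {
  cfg <- sim_config(seed = 7, n_genes = 60, n_decoys = 20,
                    n_per_cohort = c(ref_normal = 40L, adj_normal = 40L, tumor = 60L))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$cohort$values, b$cohort$values)
  expect_identical(a$truth$samples, b$truth$samples)
  expect_identical(simulate_survival(cfg, a$cohort, a$truth),
                   simulate_survival(cfg, b$cohort, b$truth))
  expect_identical(simulate_gwas(cfg), simulate_gwas(cfg))
  # and the caller's RNG stream is left untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(simulate_expression(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("null config: signature cohort means equal within sampling error", {
  cfg <- sim_config(seed = 11,
                    cohort_shift = c(ref_normal = 0, adj_normal = 0, tumor = 0),
                    signature_loading = 0, global_loading = 0,
                    n_genes = 60, n_decoys = 0, n_planted_hits = 0)
  sim <- simulate_expression(cfg)
  sig <- cfg$signature_genes$genes
  for (g in sig) {
    v <- sim$cohort$values[g, ]
    fc <- logfc(v[sim$cohort$cohort == "ref_normal"],
                v[sim$cohort$cohort == "tumor"])
    expect_lt(abs(fc), 0.1)
  }
})

test_that("signature genes co-express more strongly than background decoys", {
  # the spec states this property at 200 samples per cohort
  s <- quick_sim(seed = 3, n_per_cohort = c(ref_normal = 200L, adj_normal = 200L,
                                            tumor = 200L))
  tum <- s$cohort$cohort == "tumor"
  lv <- log2(s$cohort$values[, tum] + 1)
  sig <- s$cfg$signature_genes$genes
  bg <- s$truth$genes$gene_id[s$truth$genes$role == "background"][1:20]
  mean_off <- function(m) mean(m[upper.tri(m)])
  expect_gt(mean_off(cor(t(lv[sig, ]))), mean_off(cor(t(lv[bg, ]))))
})

test_that("ground truth bookkeeping is complete", {
  s <- quick_sim(seed = 2)
  g <- s$truth$genes
  expect_equal(sum(g$role == "hit"), 5L)
  expect_equal(sum(!is.na(g$violates)), 200L)
  expect_equal(as.vector(table(g$violates)), rep(40L, 5))
  expect_setequal(s$truth$planted_hits, g$gene_id[g$role == "hit"])
  # expected cohort means follow the declared shifts for signature genes
  em <- s$truth$expected_log2_cohort_means
  sig <- s$cfg$signature_genes$genes
  expect_equal(unname(em[sig, "ref_normal"] - em[sig, "tumor"]),
               rep(1, length(sig)))
})

test_that("direct survival model: protective gene recovered, null gene flat", {
  base <- list(n_genes = 25, n_decoys = 0L, n_planted_hits = 1L,
               n_per_cohort = c(ref_normal = 4L, adj_normal = 4L, tumor = 500L),
               survival_model = "direct")
  cfg <- do.call(sim_config, c(list(seed = 31, hit_log_hr = -0.5), base))
  sim <- simulate_expression(cfg)
  sv <- simulate_survival(cfg, sim$cohort, sim$truth)
  tum <- sim$cohort$cohort == "tumor"
  z <- log2(sim$cohort$values["HIT_01", tum] + 1)
  fit <- cox_univariate(sv$time_days, sv$event, (z - mean(z)) / sd(z))
  expect_lt(fit$hr, 1)
  expect_lt(abs(fit$beta + 0.5), 4 * fit$se)

  # censoring fraction lands near its target
  expect_lt(abs(mean(sv$event == 0) - cfg$censoring_fraction), 0.08)

  # null: no planted effect -> log-rank on a median split is not
  # systematically significant
  cfg0 <- do.call(sim_config, c(list(seed = 77, hit_log_hr = 0), base))
  pvals <- vapply(1:25, function(k) {
    c0 <- do.call(sim_config, c(list(seed = 77 + k, hit_log_hr = 0), base))
    sm <- simulate_expression(c0)
    sv0 <- simulate_survival(c0, sm$cohort, sm$truth)
    r <- median_split_survival(sm$cohort, sv0, "HIT_01", horizon_days = Inf,
                               method = "logrank")
    r$p_value
  }, 0)
  expect_lt(mean(pvals < 0.05), 0.25)
})

test_that("tie rounding produces tied event times on a day grid", {
  cfg <- sim_config(seed = 5, tie_days = 30,
                    n_genes = 25, n_decoys = 0L, n_planted_hits = 1L,
                    n_per_cohort = c(ref_normal = 4L, adj_normal = 4L, tumor = 300L))
  sim <- simulate_expression(cfg)
  sv <- simulate_survival(cfg, sim$cohort, sim$truth)
  expect_true(all(sv$time_days %% 30 == 0))
  expect_gt(sum(duplicated(sv$time_days[sv$event == 1])), 0)
})

test_that("GWAS simulator honours its noiseless and null limits", {
  cfg <- sim_config(seed = 9, n_snps = 40L, causal_beta = 0.3,
                    pleiotropy_mean = 0, pleiotropy_sd = 0,
                    se_exposure = 1e-9, se_outcome = 1e-9,
                    strand_flip_fraction = 0, allele_swap_fraction = 0)
  gw <- simulate_gwas(cfg)
  expect_equal(gw$outcome$beta / gw$exposure$beta, rep(0.3, 40), tolerance = 1e-5)

  cfg0 <- sim_config(seed = 13, n_snps = 100L, causal_beta = 0,
                     pleiotropy_mean = 0, pleiotropy_sd = 0)
  h <- harmonize_gwas(simulate_gwas(cfg0)$exposure, simulate_gwas(cfg0)$outcome)
  iv <- mr_ivw(h)
  expect_lt(abs(iv$slope), 3.5 * iv$se_slope)
})

test_that("pleiotropy effects follow the law of large numbers", {
  cfg <- sim_config(seed = 21, n_snps = 1000L, pleiotropy_mean = 0.02,
                    pleiotropy_sd = 0.01)
  gw <- simulate_gwas(cfg)
  expect_lt(abs(mean(gw$truth$alpha) - 0.02), 0.0015)
})

test_that("simulated alleles are valid and strand flips are bookkept", {
  cfg <- sim_config(seed = 4, n_snps = 200L, strand_flip_fraction = 0.3,
                    allele_swap_fraction = 0.3)
  gw <- simulate_gwas(cfg)
  for (tab in list(gw$exposure, gw$outcome)) {
    expect_true(all(tab$effect_allele %in% c("A", "C", "G", "T")))
    expect_true(all(tab$effect_allele != tab$other_allele))
  }
  fl <- gw$truth$strand_flipped & !gw$truth$alleles_swapped
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(gw$outcome$effect_allele[fl],
                   unname(comp[gw$exposure$effect_allele[fl]]))
  sw <- gw$truth$alleles_swapped
  expect_equal(gw$outcome$beta[sw], -gw$truth$outcome_beta_aligned[sw],
               tolerance = 1e-12)
})

test_that("config validation rejects inconsistent settings", {
  expect_error(sim_config(n_genes = 10), "too small")
  expect_error(sim_config(obesity_factor_sd = -1), "standard deviations")
  expect_error(sim_config(censoring_fraction = 1), "censoring_fraction")
  expect_error(sim_config(tie_days = 0), "tie_days")
  expect_error(sim_config(strand_flip_fraction = 2), "fractions")
})
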