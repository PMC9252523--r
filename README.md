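# adipohep

Is obesity protective in female hepatocellular carcinoma (HCC)?
`adipohep` implements, as a tested R pipeline, the computational chain
behind that question: cohort expression-trend comparison of a 14-gene
obesity signature (ADAMTS9, NOTCH4, EYS, DHX33, EIF6, GNL3, KAT8, POLR1D,
PSMC3, PUM2, RRP12, TCF12, TCF7L2, ZFHX3) normalized to GAPDH; two-marker
(XIST/RPS4Y1) sex inference for unlabeled normal-tissue cohorts;
single-sample GSEA (ssGSEA) scoring of the signature; a five-filter
gene-screening cascade (obesity-score differential expression, female-high,
tumor-low, protective Cox hazard ratio, signature co-expression) with a
full per-gene audit trail; Kaplan–Meier / Gehan–Breslow 5-year survival
comparison; and sex-stratified two-sample Mendelian randomization (IVW and
MR-Egger with the pleiotropy intercept test) from GWAS summary statistics.

It is aimed at biostatisticians and computational biologists who want the
*procedure* — every statistic implemented from its defining formula, every
filter auditable — rather than a wrapper around existing tools. Because
the original inputs are consortium-scale downloads (TCGA, GTEx,
GWAS-atlas), the package ships a synthetic multi-cohort generator with
complete ground-truth bookkeeping (planted protective hits,
single-violation decoys, latent obesity / co-expression / survival-risk
factors, strand-flipped GWAS tables), so every downstream stage is
testable end to end without any network access.

## The statistics at the core

- **ssGSEA** (integral convention): per sample,
  `ES = Σ_i [P_in(i) − P_out(i)]` over the expression ranking, with
  `P_in` the cumulative `r^α` mass of signature genes (α = 0.25) and
  `P_out` the cumulative count of the rest; rank-based, hence invariant to
  monotone transforms of a sample.
- **Cox screening**: Newton–Raphson maximization of the Efron-corrected
  log partial likelihood, observed-information standard errors, score test
  (= log-rank for a binary covariate), monotone-likelihood detection;
  genes with HR < 1 in female tumor survival pass the screen.
- **Survival tests**: product-limit curves plus the weighted
  `Σ w_k (O_k − E_k)` family — log-rank (`w = 1`), Gehan–Breslow
  generalized Wilcoxon (`w = n_k`, equal to minus the pairwise scoring U),
  Tarone–Ware — with exact permutation p values for small samples.
- **MR**: allele harmonization (strand complements, frequency-resolved
  palindromes), IVW `Σwγ Γ / Σwγ²` with multiplicative random-effects
  inflation, MR-Egger weighted regression with intercept
  (directional-pleiotropy test), t-based small-sample p values.

See `vignettes/adipohep-methods.Rmd` for the models, assumptions, the
generator's design (and what a green test does and does not establish).

## Worked example

```r
library(adipohep)

cfg <- sim_config(seed = 1)              # the default synthetic world
sim <- simulate_expression(cfg)          # 3 cohorts, ground truth attached
sv  <- simulate_survival(cfg, sim$cohort, sim$truth)

rep <- run_cascade(sim$cohort, sv, cfg$signature_genes)
print(rep)
#> screening cascade:
#>   stage1_obesity_de             383 ->  240
#>   stage2_sex_de                 240 ->  165
#>   stage3_female_tumor_de        165 ->  117
#>   stage4_protective_hr          117 ->   61
#>   stage5_signature_correlation   61 ->    5
#> final genes: HIT_01, HIT_02, HIT_03, HIT_04, HIT_05
```

The five survivors are exactly the five planted protective genes
(`sim$truth$planted_hits`); the 200 decoys, each built to violate one
filter, are eliminated at their designated stages (see
`rep$audit$eliminated_at`). The first survivor predicts 5-year survival
under the median-split generalized Wilcoxon test:

```r
median_split_survival(sim$cohort, sv, rep$final_genes[1])
#> gehan_wilcoxon test (chisq p): statistic=-13804.0000, chi2=39.8975,
#>   p=2.676e-10 (n = 200/200)
```

(the negative statistic means fewer deaths than expected in the
high-expression group), and the MR arm recovers the planted protective
slope of −0.1 per instrument-SD with a null pleiotropy intercept:

```r
gw <- simulate_gwas(cfg)
h  <- harmonize_gwas(gw$exposure, gw$outcome)
mr_ivw(h)
#> MR ivw: slope=-0.1311 (se 0.0153, p=9.74e-18), n_snps=100; Q=193.27
mr_egger(h)
#> MR egger: slope=-0.1506 (se 0.0260, p=8.29e-08), n_snps=100;
#>   intercept=0.0022 (se 0.0024, p=0.355); Q=191.59
```

All 14 signature/GAPDH ratios decline monotonically across
ref_normal > adj_normal > tumor (`ratio_trend(sim$cohort,
cfg$signature_genes)`), e.g. ADAMTS9 ratio means 0.0335 → 0.0224 → 0.0159
with p(ref vs tumor) ≈ 6e-96.

## Command line

```sh
adipohep run-all --config inst/extdata/demo_config.yaml --outdir demo_run
adipohep simulate|sexinfer|trend|score|survival|mr|cascade ...
```

`run-all` runs simulate → sexinfer → trend → score → cascade → survival →
MR from one YAML config and writes TSV/JSON products plus a
`manifest.json` of per-file MD5 digests; identical config + seed gives
identical digests.

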