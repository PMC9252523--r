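---
title: "Methods: models, generators and design choices in adipohep"
author: "adipohep developers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, generators and design choices in adipohep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question the package operationalizes

Epidemiologically, obesity is usually treated as a tumor-promoting
exposure, but in hepatocellular carcinoma (HCC) its role is disputed, and
there is evidence that in women a high-BMI genotype associates with *lower*
HCC incidence and that obesity-related metabolic genes behave as tumor
suppressors. `adipohep` implements, as a reproducible and fully testable
pipeline, the computational reasoning behind that claim:

1. **Trend**: the expression of a 14-gene obesity signature, normalized to
   the housekeeping gene GAPDH, declines from reference normal liver to
   tumor-adjacent normal to tumor tissue (`ratio_trend()`).
2. **Sex**: reference-normal samples come without sex labels and are sexed
   by 2-means clustering of the XIST/RPS4Y1 markers (`infer_sex()`).
3. **Causality**: two-sample Mendelian randomization on GWAS summary
   statistics tests whether genetically proxied obesity lowers HCC risk,
   overall and per sex (`harmonize_gwas()`, `mr_ivw()`, `mr_egger()`,
   `mr_stratified()`).
4. **Screen**: a five-filter cascade searches the transcriptome for genes
   that behave like obesity-coupled, female-specific tumor suppressors
   (`run_cascade()`), scored per sample against the signature by ssGSEA
   (`ssgsea_scores()`) and screened for protective hazard ratios by a
   from-scratch Cox implementation (`cox_univariate()`).
5. **Prognosis**: surviving genes are checked for a 5-year survival
   benefit by a median-split Gehan–Breslow test (`median_split_survival()`).

All statistical primitives are implemented from their defining formulas;
the pre-installed `survival` package appears only as an independent oracle
in the test suite.

# Statistical components

## ssGSEA score

For one sample, genes are ranked by expression (descending, ties broken by
gene identifier) with rank magnitudes $r_i = N - \mathrm{pos}_i + 1$.
Walking down the ranking, the enrichment score accumulates

$$\mathrm{ES} = \sum_{i=1}^{N} \left[ P_{\mathrm{in}}(i) - P_{\mathrm{out}}(i) \right],
\qquad
P_{\mathrm{in}}(i) = \frac{\sum_{j \le i,\, j \in S} r_j^{\alpha}}{\sum_{j \in S} r_j^{\alpha}},
\quad
P_{\mathrm{out}}(i) = \frac{\#\{j \le i,\, j \notin S\}}{N - |S|}.$$

This is the *integral* (sum-of-increments) convention that single-sample
GSEA uses, not the max-deviation statistic of classic GSEA. Three choices
are not fixed by the source procedure and are documented defaults here:
the exponent $\alpha = 0.25$ (the de-facto ssGSEA default), normalization
by the cohort's score range $(\max - \min)$, and a median split into
high/low groups with ties going to `low` (so scores 1, 2, 3 give a high
group of size one). Because only within-sample ranks enter, any strictly
increasing transform of one sample's profile leaves its score unchanged —
this is asserted exactly in the tests.

## Cox screening

`cox_univariate()` maximizes the Efron-corrected log partial likelihood by
Newton–Raphson from $\beta = 0$ with step-halving, tolerance $10^{-9}$ on
the step, at most 50 iterations; the standard error comes from the
observed information and the score test at $\beta = 0$ is reported (for a
binary covariate without ties it equals the log-rank chi-square, asserted
to $10^{-8}$). Perfectly separating covariates produce a monotone partial
likelihood; the fit is flagged (`monotone_likelihood`) and returned
unconverged rather than silently reporting a huge effect, and the
gene screen (`screen_protective()`) excludes such genes while never
aborting. The covariate is the z-scored $\log_2(x+1)$ expression;
dichotomized mode exists but the continuous covariate avoids an unstated
cut-point. The printed criterion is a point-estimate filter (HR < 1), so
no p-value threshold is applied at this stage.

## Two-sample survival tests

`surv_test()` computes $\sum_k w_k (O_k - E_k)$ over distinct event times
with hypergeometric variances; $w_k = 1$ gives the log-rank test,
$w_k = n_k$ (total at risk) the Gehan–Breslow generalized Wilcoxon test —
the standard reading of "generalized Wilcoxon" — and $w_k = \sqrt{n_k}$
Tarone–Ware. The Gehan statistic equals minus the classical pairwise
scoring $U$; the tests assert this identity and, for $n \le 8$, agreement
of the exact permutation p value with full enumeration over label
assignments. The 5-year horizon for `median_split_survival()` is fixed at
1826 days.

## Mendelian randomization

Harmonization aligns outcome to exposure effect alleles, complementing
strands where needed; palindromic variants carry no orientation in their
letters and are resolved by allele frequency only when both frequencies
lie outside the 0.42–0.58 ambiguity window, otherwise dropped with a
reason. IVW is the weighted regression through the origin with weights
$1/\mathrm{se}_Y^2$, with multiplicative random-effects inflation
$\sqrt{Q/(n-1)}$ when Cochran's $Q$ exceeds its degrees of freedom; a
single instrument reduces to the Wald ratio. MR-Egger adds an intercept
after orienting all instruments to non-negative exposure effects, inflates
by $\max(1, Q/(n-2))$, and uses $t_{n-2}$ p values (small-$n$ honesty);
the intercept estimates directional pleiotropy, which biases IVW but not
(under InSIDE) the Egger slope.

## The screening cascade

Stages run in the printed order on a candidate universe that excludes the
measurement apparatus (the 14 signature genes themselves, GAPDH, and the
sex markers): (1) logFC(high-score, low-score) $< -0.3$ in tumors;
(2) logFC(female, male) $> 0.3$ in reference normal; (3) logFC(female
reference normal, female tumor) $> 0$, strictly; (4) Cox HR $< 1$ in
female tumor survival; (5) Pearson $r > 0.5$ with $p < 0.05$ against at
least 12 of the 14 signature genes across tumors; optional stage 6
intersects user-supplied annotation sets. logFC is
$\log_2(\bar{x}_A + 1) - \log_2(\bar{x}_B + 1)$ on linear-scale
expression, numerator stated in every report; the stage-1 numerator is the
high-score group, so the filter selects genes *lower* in high-obesity
tumors (one config flag flips it). Stage-5 correlations are computed on
$\log_2(x+1)$: Pearson on the raw linear scale is dominated by lognormal
outliers and understates co-expression. Statistics for **all** candidates
at **all** stages are computed once into an audit table; thresholds are
then applied as a pure function (`cascade_apply()`), which is also how the
threshold-monotonicity property is checked without re-simulation. No
multiplicity correction is applied inside the cascade (the source
procedure applies raw thresholds); BH-adjusted trend p values are emitted
alongside raw ones for transparency.

# The synthetic world

Nothing in the pipeline is testable against consortium downloads, so the
generator (`sim_config()`, `simulate_expression()`, `simulate_survival()`,
`simulate_gwas()`) produces the statistical structure the analysis
assumes, with complete ground truth. Log2 expression is additive —
baseline + latent factors + sex and cohort effects + Gaussian noise —
exponentiated to a linear TPM-like scale, which makes logFC thresholds
exact in expectation and keeps values non-negative.

## Why three latent factors

A design-phase analysis showed that the natural one-factor world is
self-contradictory. If a single obesity factor drives signature
co-expression and the ssGSEA score, then any gene positively correlated
with 12+ signature genes is positively associated with every monotone
score of the signature — it cannot simultaneously sit below the
$-0.3$ logFC bound in high-score tumors. The minimal consistent structure
uses three independent per-sample factors:

- **G**, a global co-expression program loading (near-)equally on all
  genes. Equal log-scale loadings cancel in within-sample ranks, so the
  score is exactly G-free, while G still carries Pearson correlation
  between hits and the signature. The signature's G loading is set to the
  average non-signature loading so the cancellation survives the one gene
  class (stage-5 decoys) that deliberately has no G.
- **O**, the obesity factor: loading $+0.4$ on the signature (driving the
  score; measured $\mathrm{cor}(\mathrm{score}, O) \approx 0.95$ at
  default sizes) and $-0.95$ on planted hits.
- **S**, a survival-risk program: the default hazard is
  $h_0 e^{\theta S}$ with $\theta = 2$, protective genes loading $-0.7$
  and stage-4 decoys $+0.7$. A per-gene sum hazard
  $h_0 \exp(\sum_g \beta_g z_g)$ over ~45 factor-correlated genes — the
  naive alternative — yields a linear predictor with sd > 15 (overflow)
  and cannot make a stage-4 decoy look harmful at all, because its
  expression is forced by stages 1/5 to correlate > 0.85 with the hits.
  The direct model is retained (`survival_model = "direct"`) and is used
  for the parameter-recovery acceptance test, where a single active gene
  makes it an exact proportional-hazards model in the observed covariate.
  Empirically, the latent-risk hazard attenuates fitted per-gene
  coefficients to roughly the gene–S correlation (frailty selection),
  which is what fixed the 0.7 loading.

## Hits, decoys and margins

Five planted hits satisfy all five filters in expectation; 200 decoys are
split evenly over the filters, each built to violate exactly its
designated one while satisfying every filter *before* it (the cascade runs
in order, so later-stage behavior of an earlier-stage decoy is
irrelevant — this ordering argument is what makes 1000 decoy eliminations
per class land exactly on their designated stages). The spec's asymptotic
"sex-neutral decoy" idea fails at finite n (a zero-effect gene leaks past
a 0.3 logFC bound ~10% of the time), so decoys carry actively inverted
attributes: male-high ($-1.5$), tumor-high ($+3.5$), harmful risk loading
($+0.7$), obesity-score-positive ($+0.95$), signature-uncoupled (no G).
Effect sizes were chosen once, before the acceptance tests were written,
for roughly 4-sigma margins at the default sizes (200/200/400 samples per
cohort; the tumor cohort mirrors TCGA LIHC's ~371 patients and gives the
stage-4 Cox screen ~200 female samples). Background genes are heavily
dispersed (log2 sd 4): because the 14 signature genes are nearly collinear
(pairwise $r \approx 0.97$), the "12 of 14" rule protects like a *single*
correlation threshold, and the background correlation must sit ~4 sigma
below 0.5 on its own.

Two intentional asymmetries of the world: hit/decoy sex effects act in
the non-tumor cohorts only (the sex filter reads reference normal; this
keeps the tumor variance budget for the stage-1/stage-5 trade-off), and
GAPDH shares the global program G (it is exactly the library-size-like
variation that housekeeping normalization is meant to remove; its
`housekeeping_cv` is the residual variation beyond G).

## GWAS tables

True instrument effects are $|\mathcal{N}(0, 0.1^2)|$ — reported in
trait-increasing orientation, as instrument exports are. This is a
deliberate deviation from a sign-symmetric draw: with symmetric
instrument effects, directional pleiotropy that is independent of allele
orientation cancels out of the IVW slope in expectation
($E[\alpha\gamma] = E[\alpha]E[\gamma] = 0$) and the Egger-vs-IVW bias
comparison would be vacuous. Outcome effects are
$\beta\gamma_j + \alpha_j$ with $\alpha_j \sim \mathcal{N}(\mu_p,
\sigma_p^2)$ independent of $\gamma$ (InSIDE holds), observed effects add
their standard-error noise, and a configurable fraction of outcome rows
is emitted strand-flipped and/or allele-swapped to exercise
harmonization, with exact bookkeeping so tests can demand bit-level
recovery of the aligned effects.

## What a green test does not establish

The generator has no linkage disequilibrium between instruments, no batch
effects, no count noise (expression is lognormal, not negative-binomial),
no correlation between censoring and covariates, and its sex markers are
cleanly bimodal. Green acceptance tests therefore establish that the
*implementations* are correct and that the *procedure* recovers planted
structure under its own assumptions — not that the procedure is robust to
real-data pathologies, and not that the source study's gene lists or p
values are reproduced (those depend on consortium data and are explicitly
out of scope; the spec lists no numeric acceptance targets for this
reason).

# Numerical and degenerate-input policy

- Pseudocount 1 before every $\log_2$; writers emit `%.17g` so text
  round-trips are exact; readers force character parsing first (an allele
  `T` must not become logical `TRUE`).
- Readers either produce an object satisfying the type invariants or
  fail; structurally invalid survival event codes are fatal while
  invalid GWAS rows and non-positive times are dropped with logged counts.
- Degenerate inputs error early with named causes: constant covariates,
  all-equal scores, single-sample clustering, signatures covering the
  whole universe, empty groups.
- Student t tests are pooled-variance (matching the stated method name),
  with Welch as a switch; identical constant groups return $t = 0, p = 1$.
- One root seed per simulated world; per-output substreams at fixed
  offsets (+1 expression, +2 survival, +3 GWAS); generators restore the
  caller's RNG state.

# Known limitations

Univariate screening only (no multivariable Cox); no proportional-hazards
diagnostics; no weighted-median/mode MR estimators or outlier removal;
instrument selection (clumping, p-value thresholds) is assumed done
upstream; the cascade's stage-6 annotation sets are consumed, not curated.
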