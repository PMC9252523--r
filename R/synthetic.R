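## Synthetic multi-cohort generator: expression (3 cohorts, sex markers,
## obesity signature, planted hits, single-violation decoys), proportional-
## hazards survival, and two-sample GWAS summary statistics, with complete
## ground-truth bookkeeping.
##
## Generative model for log2 expression of gene g in sample i:
##   log2 x_gi = b_g + lG_g*G_i + lO_g*O_i + lS_g*S_i
##               + sex_g(sample, cohort) + c_g(cohort_i) + N(0, sd_g)
## with three independent standard-normal latent factors per sample:
##   G — a global co-expression program loading EQUALLY on (almost) all
##       genes. Because G shifts every gene's log-expression by the same
##       amount it is exactly invisible to the rank-based ssGSEA score,
##       while still driving Pearson correlation between planted hits and
##       the signature. (A single obesity factor cannot do both jobs: any
##       gene positively correlated with the signature through the factor
##       that drives the score is necessarily higher in high-score samples.)
##   O — the obesity factor: positive on the signature (hence on the
##       enrichment score), negative on hits (making them lower in
##       high-score tumors).
##   S — a survival-risk program: the default hazard is h0*exp(theta*S),
##       protective genes load negatively on S, harmful decoys positively.
##       A per-gene sum hazard over ~45 factor-correlated genes is
##       numerically and statistically degenerate; the latent-risk model is
##       the minimal structure giving per-gene hazard-ratio margins.
## Effect sizes and noise levels are frozen from a design-phase margin
## analysis (see the methods vignette).

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the stated world of the analysis: reference-normal and
#' adjacent-normal cohorts of 200 samples and a tumor cohort of 400 (half
#' per sex, mirroring the GTEx/TCGA size imbalance), a 14-gene obesity
#' signature declining across ref_normal > adj_normal > tumor, 5 planted
#' protective hits, 200 decoys each built to violate exactly one cascade
#' criterion, bimodal XIST/RPS4Y1 sex markers separated by 6 log2 units, a
#' GAPDH housekeeping gene, and GWAS instrument tables with a configurable
#' causal slope and directional pleiotropy. Planted-effect sizes were fixed
#' once by a design-phase margin analysis against the generator's own
#' contract (every hit passes all five filters, every decoy fails its
#' designated filter, each with roughly 4-sigma margins at these sample
#' sizes) and are not meant to be tuned per run.
#'
#' @param seed integer root seed; per-output substreams use fixed offsets
#'   (+1 expression, +2 survival, +3 GWAS)
#' @param n_per_cohort named integer vector, samples per cohort
#' @param n_genes total genes including signature, markers, housekeeping,
#'   hits, decoys and background fill
#' @param signature_genes a [gene_set()]; defaults to the packaged 14-gene
#'   obesity signature
#' @param n_planted_hits number of planted protective genes
#' @param n_decoys number of single-violation decoys (split evenly over the
#'   five cascade criteria)
#' @param obesity_factor_sd sd of the latent obesity factor O
#' @param signature_loading log2 loading of signature genes on O
#' @param global_loading log2 loading of genes on the global program G
#' @param cohort_shift signature-gene log2 shift per cohort (decreasing)
#' @param hit_cohort_shift hit-gene log2 shift per cohort (decreasing)
#' @param hit_obesity_loading log2 loading of hits on O (negative); stage-1
#'   decoys get the opposite sign
#' @param hit_risk_loading log2 loading of protective genes on the survival
#'   risk factor S (negative); stage-4 decoys get `decoy_risk_loading`
#' @param decoy_risk_loading S loading of stage-4 decoys (positive, harmful)
#' @param hit_sex_log2fc female-vs-male log2 effect of hits (applied in the
#'   non-tumor cohorts, where the sex screen operates)
#' @param decoy_sex_log2fc sex effect of stage-2 decoys (male-high)
#' @param decoy_cohort_shift cohort shifts of stage-3 decoys (tumor-high)
#' @param sexmarker_log_separation log2 separation between marker modes
#' @param housekeeping_cv residual coefficient of variation of GAPDH
#' @param noise_sd named vector of residual log2 noise sds per gene role
#'   (background genes are intentionally dispersed so that the shared
#'   program alone cannot carry them past the stage-5 correlation screen)
#' @param baseline_log2_range range of per-gene baselines (log2 units)
#' @param survival_model `"risk_factor"` (default): hazard =
#'   `base_hazard * exp(risk_log_hr * S)`; `"direct"`: hazard =
#'   `base_hazard * exp(sum_g log_hr_g * z_g)` over the planted genes'
#'   z-scored log2 expression (exact proportional hazards in the observed
#'   covariate; use with few active genes)
#' @param risk_log_hr log hazard ratio per SD of the risk factor S
#' @param hit_log_hr direct-model per-SD log hazard ratio of hits
#' @param decoy_log_hr direct-model per-SD log hazard ratio of stage-4 decoys
#' @param base_hazard baseline exponential hazard per day
#' @param censoring_fraction target fraction of censored tumor samples
#' @param tie_days optional rounding granularity (days) to create tied event
#'   times; `NULL` keeps times continuous
#' @param n_snps number of instruments
#' @param causal_beta true causal slope of exposure on outcome
#' @param pleiotropy_mean,pleiotropy_sd directional pleiotropy distribution
#' @param instrument_strength_sd sd of true instrument effects (reported in
#'   trait-increasing orientation, i.e. folded normal)
#' @param se_exposure,se_outcome standard errors of the summary statistics
#' @param strand_flip_fraction fraction of outcome rows reported on the
#'   opposite strand
#' @param allele_swap_fraction fraction of outcome rows with effect/other
#'   alleles swapped (beta negated)
#' @param palindromic_fraction fraction of A/T or C/G SNPs
#' @return validated list of class `sim_config`
#' @export
sim_config <- function(seed = 1L,
                       n_per_cohort = c(ref_normal = 200L, adj_normal = 200L, tumor = 400L),
                       n_genes = 400L,
                       signature_genes = obesity_signature(),
                       n_planted_hits = 5L,
                       n_decoys = 200L,
                       obesity_factor_sd = 1,
                       signature_loading = 0.4,
                       global_loading = 1.5,
                       cohort_shift = c(ref_normal = 1, adj_normal = 0.5, tumor = 0),
                       hit_cohort_shift = c(ref_normal = 2, adj_normal = 1, tumor = 0),
                       hit_obesity_loading = -0.95,
                       hit_risk_loading = -0.7,
                       decoy_risk_loading = 0.7,
                       hit_sex_log2fc = 1.8,
                       decoy_sex_log2fc = -1.5,
                       decoy_cohort_shift = c(ref_normal = 0, adj_normal = 1.75, tumor = 3.5),
                       sexmarker_log_separation = 6,
                       housekeeping_cv = 0.1,
                       noise_sd = c(signature = 0.2, hit = 0.25, background = 4, marker = 0.5),
                       baseline_log2_range = c(3, 8),
                       survival_model = c("risk_factor", "direct"),
                       risk_log_hr = 2,
                       hit_log_hr = -0.5,
                       decoy_log_hr = 0.5,
                       base_hazard = 6.5e-4,
                       censoring_fraction = 0.2,
                       tie_days = NULL,
                       n_snps = 100L,
                       causal_beta = -0.1,
                       pleiotropy_mean = 0,
                       pleiotropy_sd = 0.01,
                       instrument_strength_sd = 0.1,
                       se_exposure = 0.002,
                       se_outcome = 0.01,
                       strand_flip_fraction = 0.2,
                       allele_swap_fraction = 0.2,
                       palindromic_fraction = 0) {
  survival_model <- match.arg(survival_model)
  cfg <- as.list(environment())
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (!all(COHORT_LEVELS %in% names(n_per_cohort)))
    stop("n_per_cohort must name ref_normal, adj_normal and tumor")
  if (any(n_per_cohort < 0)) stop("n_per_cohort must be non-negative")
  sds <- c(obesity_factor_sd, housekeeping_cv, noise_sd, pleiotropy_sd,
           instrument_strength_sd, se_exposure, se_outcome)
  if (any(sds < 0)) stop("all standard deviations / CVs must be >= 0")
  if (!all(c("signature", "hit", "background", "marker") %in% names(noise_sd)))
    stop("noise_sd must name signature, hit, background and marker")
  if (!inherits(signature_genes, "gene_set")) stop("signature_genes must be a gene_set")
  n_fixed <- length(signature_genes$genes) + 3L # + GAPDH, XIST, RPS4Y1
  if (n_planted_hits + n_decoys + n_fixed > n_genes)
    stop("n_genes too small for signature + markers + hits + decoys")
  if (!is.null(cfg$tie_days) && cfg$tie_days <= 0) stop("tie_days must be > 0")
  if (censoring_fraction < 0 || censoring_fraction >= 1)
    stop("censoring_fraction must be in [0, 1)")
  fr <- c(strand_flip_fraction, allele_swap_fraction, palindromic_fraction)
  if (any(fr < 0 | fr > 1)) stop("GWAS fractions must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

## Per-gene parameter table implied by a config. Decoys are spread evenly
## over the five violated criteria; each decoy inherits the hit profile for
## every stage BEFORE its designated one (the cascade runs in order, so a
## stage-k decoy is eliminated exactly at stage k).
sim_gene_table <- function(config) {
  sig <- config$signature_genes$genes
  n_hit <- config$n_planted_hits
  n_dec <- config$n_decoys
  dec_stage <- if (n_dec) sort(rep_len(1:5, n_dec)) else integer(0)
  n_bg <- config$n_genes - length(sig) - 3L - n_hit - n_dec
  ns <- config$noise_sd
  hk_sd <- sqrt(log(1 + config$housekeeping_cv^2)) / log(2)

  role <- c(rep("signature", length(sig)),
            "housekeeping", "sex_marker", "sex_marker",
            rep("hit", n_hit),
            if (n_dec) paste0("decoy_stage", dec_stage),
            rep("background", n_bg))
  gene_id <- c(sig, "GAPDH", "XIST", "RPS4Y1",
               if (n_hit) sprintf("HIT_%02d", seq_len(n_hit)),
               if (n_dec) sprintf("DECOY_S%d_%03d", dec_stage,
                                  stats::ave(dec_stage, dec_stage, FUN = seq_along)),
               if (n_bg) sprintf("BG_%04d", seq_len(n_bg)))

  g <- data.frame(gene_id = gene_id, role = role, stringsAsFactors = FALSE)
  n <- nrow(g)
  g$violates <- NA_integer_
  g$violates[grepl("^decoy_stage", role)] <- dec_stage
  hitlike <- g$role == "hit" | !is.na(g$violates)

  g$loading_global <- config$global_loading
  g$loading_global[g$violates %in% 5L] <- 0 # stage-5 decoy: signature-uncorrelated
  ## Signature G loading balanced to the average non-signature loading so
  ## that the rank-based score is G-free despite the zero-loading decoys.
  is_sig <- g$role == "signature"
  g$loading_global[is_sig] <- mean(g$loading_global[!is_sig])
  g$loading_obesity <- 0
  g$loading_obesity[g$role == "signature"] <- config$signature_loading
  g$loading_obesity[hitlike] <- config$hit_obesity_loading
  g$loading_obesity[g$violates %in% 1L] <- -config$hit_obesity_loading # score-positive
  ## Risk-factor loadings: only genes that reach stage 4 need one (hits and
  ## stage-5 decoys protective, stage-4 decoys harmful; stage-1/2/3 decoys
  ## are eliminated earlier). The +/- groups are nearly equal in size, so
  ## the rank-based score stays (almost) uncoupled from S.
  g$loading_risk <- 0
  g$loading_risk[g$role == "hit" | g$violates %in% 5L] <- config$hit_risk_loading
  g$loading_risk[g$violates %in% 4L] <- config$decoy_risk_loading # harmful

  ## sex effects: markers are bimodal in every cohort; hit/decoy sex effects
  ## act in the non-tumor cohorts (where the sex screen operates)
  g$sex_log2fc <- 0
  g$sex_log2fc[hitlike] <- config$hit_sex_log2fc
  g$sex_log2fc[g$violates %in% 2L] <- config$decoy_sex_log2fc
  g$sex_in_tumor <- FALSE
  g$sex_log2fc[g$gene_id == "XIST"] <- config$sexmarker_log_separation
  g$sex_log2fc[g$gene_id == "RPS4Y1"] <- -config$sexmarker_log_separation
  g$sex_in_tumor[g$role == "sex_marker"] <- TRUE

  shift <- matrix(0, n, 3L, dimnames = list(NULL, COHORT_LEVELS))
  set_shift <- function(shift, rows, values) {
    if (any(rows))
      shift[rows, ] <- matrix(values[COHORT_LEVELS], sum(rows), 3L, byrow = TRUE)
    shift
  }
  shift <- set_shift(shift, g$role == "signature", config$cohort_shift)
  shift <- set_shift(shift, hitlike, config$hit_cohort_shift)
  shift <- set_shift(shift, g$violates %in% 3L, config$decoy_cohort_shift)
  g$shift_ref_normal <- shift[, "ref_normal"]
  g$shift_adj_normal <- shift[, "adj_normal"]
  g$shift_tumor <- shift[, "tumor"]

  g$noise_sd <- ns[["background"]]
  g$noise_sd[g$role == "signature"] <- ns[["signature"]]
  g$noise_sd[hitlike] <- ns[["hit"]]
  g$noise_sd[g$role == "sex_marker"] <- ns[["marker"]]
  g$noise_sd[g$role == "housekeeping"] <- hk_sd

  g$log_hr <- 0
  g$log_hr[g$role == "hit"] <- config$hit_log_hr
  g$log_hr[g$violates %in% 4L] <- config$decoy_log_hr
  g
}

#' Simulate a three-cohort expression data set with ground truth
#'
#' Draws per-sample latent factors (obesity factor O, global program G,
#' survival-risk program S), assigns sexes half-and-half per cohort, and
#' builds log2 expression from the additive model documented in
#' [sim_config()], exponentiated to a linear TPM-like scale. Sex labels are
#' reported as `unknown` for the `ref_normal` cohort (they must be inferred
#' from the markers, as for GTEx) and as known for the two TCGA-like
#' cohorts.
#'
#' @param config a [sim_config()]
#' @return list with elements `cohort` (an [expression_cohort()]) and
#'   `truth` (gene table with loadings, effects and the violated criterion
#'   per decoy; sample table with true sex and latent factors; expected
#'   per-cohort log2 means)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 1L, {
    genes <- sim_gene_table(config)
    n_genes <- nrow(genes)
    baseline <- stats::runif(n_genes, config$baseline_log2_range[1L],
                             config$baseline_log2_range[2L])
    baseline[genes$role == "housekeeping"] <- 10
    baseline[genes$gene_id == "XIST"] <- 1
    baseline[genes$gene_id == "RPS4Y1"] <- 1 + config$sexmarker_log_separation
    genes$baseline <- baseline

    n_c <- config$n_per_cohort[COHORT_LEVELS]
    cohort <- rep(COHORT_LEVELS, times = n_c)
    n <- length(cohort)
    sex <- unlist(lapply(COHORT_LEVELS, function(cc) {
      k <- n_c[[cc]]
      rep(c("female", "male"), c(k %/% 2L, k - k %/% 2L))
    }), use.names = FALSE)
    sample_id <- sprintf("S_%s_%03d", c(ref_normal = "ref", adj_normal = "adj",
                                        tumor = "tum")[cohort],
                         unlist(lapply(n_c, seq_len), use.names = FALSE))
    O <- stats::rnorm(n, 0, config$obesity_factor_sd)
    G <- stats::rnorm(n, 0, 1)
    S <- stats::rnorm(n, 0, 1)

    shift <- cbind(ref_normal = genes$shift_ref_normal,
                   adj_normal = genes$shift_adj_normal,
                   tumor = genes$shift_tumor)
    female <- as.numeric(sex == "female")
    ## sex effect indicator: markers always, hit/decoy effects outside tumor
    sex_active <- outer(genes$sex_in_tumor, rep(TRUE, n)) |
      outer(rep(TRUE, n_genes), cohort != "tumor")
    L <- matrix(genes$baseline, n_genes, n) +
      genes$loading_global %o% G +
      genes$loading_obesity %o% O +
      genes$loading_risk %o% S +
      (genes$sex_log2fc %o% female) * sex_active +
      shift[, cohort] +
      matrix(stats::rnorm(n_genes * n), n_genes, n) * genes$noise_sd
    values <- 2^L
    dimnames(values) <- list(genes$gene_id, sample_id)

    reported_sex <- ifelse(cohort == "ref_normal", "unknown", sex)
    cohort_obj <- expression_cohort(values, cohort, reported_sex)

    p_female <- unlist(lapply(n_c, function(k) (k %/% 2L) / max(k, 1L)))
    sexmat <- genes$sex_log2fc %o% p_female
    sexmat[!genes$sex_in_tumor, "tumor"] <- 0
    expected_log2 <- matrix(genes$baseline, n_genes, 3L,
                            dimnames = list(genes$gene_id, COHORT_LEVELS)) +
      shift + sexmat
    truth <- list(genes = genes,
                  samples = data.frame(sample_id = sample_id, cohort = cohort,
                                       sex = sex, obesity_factor = O,
                                       global_factor = G, risk_factor = S,
                                       stringsAsFactors = FALSE),
                  expected_log2_cohort_means = expected_log2,
                  planted_hits = genes$gene_id[genes$role == "hit"],
                  config = config)
    list(cohort = cohort_obj, truth = truth)
  })
}

## Survival covariate convention shared by the generator and the Cox screen:
## per-gene z-score of log2(x + 1) across the modelled samples.
survival_covariate <- function(values) {
  z <- log2(values + 1)
  sdv <- apply(z, 1L, stats::sd)
  sweep(sweep(z, 1L, rowMeans(z)), 1L, ifelse(sdv > 0, sdv, 1), `/`)
}

#' Simulate proportional-hazards survival for the tumor cohort
#'
#' Event times are exponential with per-sample hazard determined by the
#' configured `survival_model`: by default `base_hazard * exp(theta * S)`
#' with S the latent risk program that planted genes load on (protective
#' genes negatively, stage-4 decoys positively); in `"direct"` mode the
#' hazard is `base_hazard * exp(sum_g log_hr_g * z_g)` over the planted
#' genes' z-scored log2(x+1) expression, which is an exact proportional-
#' hazards model in the observed covariate when a single gene is active.
#' Censoring is independent Uniform(0, tau) with tau solved so the
#' expected censored fraction matches the target. Times are continuous (no
#' ties) unless `tie_days` is set, in which case they are rounded up to
#' that granularity.
#'
#' @param config a [sim_config()]
#' @param cohort the [expression_cohort()] from [simulate_expression()]
#' @param truth the matching ground-truth list
#' @return a [survival_table()] for the tumor samples; attribute `eta`
#'   carries the true linear predictor
#' @export
simulate_survival <- function(config, cohort, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(cohort, "expression_cohort"))
  tum <- which(cohort$cohort == "tumor")
  if (!length(tum)) stop("no tumor samples to simulate survival for")
  genes <- truth$genes
  if (!all(truth$planted_hits %in% rownames(cohort$values)))
    stop("expression does not contain the planted hit genes")
  with_seed(config$seed + 2L, {
    if (config$survival_model == "risk_factor") {
      eta <- config$risk_log_hr * truth$samples$risk_factor[tum]
    } else {
      active <- which(genes$log_hr != 0)
      eta <- rep(0, length(tum))
      if (length(active)) {
        z <- survival_covariate(cohort$values[genes$gene_id[active], tum, drop = FALSE])
        eta <- as.numeric(crossprod(z, genes$log_hr[active]))
      }
    }
    lam <- config$base_hazard * exp(eta)
    tt <- stats::rexp(length(tum), rate = lam)
    if (config$censoring_fraction > 0) {
      target <- config$censoring_fraction
      f <- function(tau) mean((1 - exp(-lam * tau)) / (lam * tau)) - target
      tau <- stats::uniroot(f, lower = 1e-9, upper = 1e12, tol = 1e-8)$root
      cens <- stats::runif(length(tum), 0, tau)
      event <- as.integer(tt <= cens)
      time <- pmin(tt, cens)
    } else {
      event <- rep(1L, length(tum))
      time <- tt
    }
    if (!is.null(config$tie_days))
      time <- ceiling(time / config$tie_days) * config$tie_days
    out <- survival_table(colnames(cohort$values)[tum], time, event,
                          as.character(truth$samples$sex[tum]))
    attr(out, "eta") <- eta
    out
  })
}

complement_alleles <- function(a) c(A = "T", C = "G", G = "C", T = "A")[a]

#' Simulate exposure and outcome GWAS summary statistics
#'
#' True instrument effects gamma_j are |N(0, instrument_strength_sd^2)|
#' (reported in trait-increasing orientation, as instrument exports
#' conventionally are; with sign-symmetric gammas directional pleiotropy
#' would cancel out of the IVW slope and be undetectable). True outcome
#' effects are `causal_beta * gamma_j + alpha_j` with
#' `alpha_j ~ N(pleiotropy_mean, pleiotropy_sd^2)` independent of gamma
#' (InSIDE holds). Observed betas add N(0, se^2) noise. A configurable
#' fraction of outcome rows is emitted on the opposite strand and/or with
#' swapped alleles to exercise harmonization.
#'
#' @param config a [sim_config()]
#' @return list with `exposure` and `outcome` [gwas_summary()] tables and
#'   `truth` (gamma, alpha, causal slope, aligned outcome betas, and the
#'   strand/swap bookkeeping)
#' @export
simulate_gwas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 3L, {
    m <- config$n_snps
    snp_id <- sprintf("rs%06d", seq_len(m))
    gamma <- abs(stats::rnorm(m, 0, config$instrument_strength_sd))
    alpha <- stats::rnorm(m, config$pleiotropy_mean, config$pleiotropy_sd)
    Gamma_true <- config$causal_beta * gamma + alpha
    bx <- gamma + stats::rnorm(m, 0, config$se_exposure)
    by <- Gamma_true + stats::rnorm(m, 0, config$se_outcome)
    sex <- rep(config$se_exposure, m)
    sey <- rep(config$se_outcome, m)

    palin <- stats::runif(m) < config$palindromic_fraction
    ea <- oa <- character(m)
    for (j in seq_len(m)) {
      if (palin[j]) {
        ea[j] <- sample(BASES, 1L)
        oa[j] <- complement_alleles(ea[j])
      } else {
        repeat {
          p <- sample(BASES, 2L)
          if (complement_alleles(p[1L]) != p[2L]) break
        }
        ea[j] <- p[1L]; oa[j] <- p[2L]
      }
    }
    eaf <- ifelse(palin, stats::runif(m, 0.10, 0.40), stats::runif(m, 0.05, 0.95))

    flip <- stats::runif(m) < config$strand_flip_fraction & !palin
    swap <- stats::runif(m) < config$allele_swap_fraction
    out_ea <- ea; out_oa <- oa
    out_ea[flip] <- complement_alleles(ea[flip])
    out_oa[flip] <- complement_alleles(oa[flip])
    tmp <- out_ea[swap]; out_ea[swap] <- out_oa[swap]; out_oa[swap] <- tmp
    out_by <- ifelse(swap, -by, by)
    out_eaf <- ifelse(swap, 1 - eaf, eaf)

    pv <- function(b, s) pmax(2 * stats::pnorm(-abs(b) / s), 1e-300)
    exposure <- gwas_summary(data.frame(
      snp_id = snp_id, effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = bx, se = sex, pval = pv(bx, sex), n = 300000,
      stringsAsFactors = FALSE))
    outcome <- gwas_summary(data.frame(
      snp_id = snp_id, effect_allele = out_ea, other_allele = out_oa,
      eaf = out_eaf, beta = out_by, se = sey, pval = pv(out_by, sey),
      n = 360000, stringsAsFactors = FALSE))
    truth <- list(gamma = gamma, alpha = alpha,
                  causal_beta = config$causal_beta,
                  outcome_beta_aligned = by, strand_flipped = flip,
                  alleles_swapped = swap, palindromic = palin)
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}
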