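## The five-filter gene-screening cascade with per-gene audit trail:
##   1. lower in high- vs low-obesity-score tumors   (logFC < -0.3)
##   2. female-high in reference normal              (logFC > 0.3)
##   3. higher in female reference normal than female tumor (logFC > 0)
##   4. protective in female tumor survival          (Cox HR < 1)
##   5. correlated with >= 12 of the 14 signature genes in tumors
##      (Pearson r > 0.5, two-sided p < 0.05)
## plus an optional stage 6 intersecting with user-supplied annotation sets.
## Stage statistics are computed for every gene in the universe once; the
## thresholds are then applied as a pure function, so threshold-relaxation
## (monotonicity) checks need no re-computation.

#' Log2 fold change between two groups of linear-scale expression
#'
#' `log2(mean(a) + 1) - log2(mean(b) + 1)`; the first argument is the
#' numerator group. Means are taken on the linear scale with a pseudocount
#' of 1.
#'
#' @param a,b non-empty numeric vectors (linear-scale expression)
#' @return a finite real
#' @export
logfc <- function(a, b) {
  if (!length(a) || !length(b)) stop("logfc: empty group")
  log2(mean(a) + 1) - log2(mean(b) + 1)
}

row_logfc <- function(values, idx_a, idx_b) {
  if (!length(idx_a) || !length(idx_b)) stop("logfc: empty group")
  log2(rowMeans(values[, idx_a, drop = FALSE]) + 1) -
    log2(rowMeans(values[, idx_b, drop = FALSE]) + 1)
}

#' Cascade thresholds and options
#'
#' Defaults are the printed screening criteria: stage-1 logFC below -0.3
#' (high- over low-score group), stage-2 female-over-male logFC above 0.3,
#' stage-3 logFC strictly above 0, hazard ratio below 1, and correlation
#' with at least 12 signature genes at r > 0.5 and p < 0.05.
#'
#' @param logfc_obesity_max stage-1 upper bound (strict)
#' @param logfc_sex_min stage-2 lower bound (strict)
#' @param logfc_tumor_min stage-3 lower bound (strict)
#' @param hr_max stage-4 upper bound (strict)
#' @param corr_min stage-5 per-gene correlation bound (strict), in (0, 1)
#' @param corr_p_max stage-5 per-correlation p bound (strict)
#' @param min_correlated_signature_genes how many signature genes must pass
#' @param corr_method `pearson` (default) or `spearman`
#' @param stage1_numerator which score group is the logFC numerator; the
#'   default `high` selects genes lower in high-obesity-score tumors
#' @return validated list of class `cascade_config`
#' @export
cascade_config <- function(logfc_obesity_max = -0.3,
                           logfc_sex_min = 0.3,
                           logfc_tumor_min = 0,
                           hr_max = 1,
                           corr_min = 0.5,
                           corr_p_max = 0.05,
                           min_correlated_signature_genes = 12L,
                           corr_method = c("pearson", "spearman"),
                           stage1_numerator = c("high", "low")) {
  corr_method <- match.arg(corr_method)
  stage1_numerator <- match.arg(stage1_numerator)
  if (is.finite(corr_min) && (corr_min <= 0 || corr_min >= 1))
    stop("corr_min must be in (0, 1) (or -Inf for a permissive screen)")
  cfg <- list(logfc_obesity_max = logfc_obesity_max,
              logfc_sex_min = logfc_sex_min,
              logfc_tumor_min = logfc_tumor_min,
              hr_max = hr_max, corr_min = corr_min,
              corr_p_max = corr_p_max,
              min_correlated_signature_genes = as.integer(min_correlated_signature_genes),
              corr_method = corr_method, stage1_numerator = stage1_numerator)
  class(cfg) <- "cascade_config"
  cfg
}

stage_names <- c("stage1_obesity_de", "stage2_sex_de", "stage3_female_tumor_de",
                 "stage4_protective_hr", "stage5_signature_correlation")

#' Apply cascade thresholds to a precomputed audit table
#'
#' Pure function from per-gene statistics to the nested per-stage survivor
#' sets; used internally by [run_cascade()] and directly for threshold
#' monotonicity checks.
#'
#' @param audit data.frame with columns `gene_id`, `stage1_logfc`,
#'   `stage2_logfc`, `stage3_logfc`, `hr`, `hr_ok` (fit usable),
#'   `n_correlated`
#' @param config a [cascade_config()]
#' @return list with `stages` (name, n_input, n_output, genes) and
#'   `final_genes`
#' @export
cascade_apply <- function(audit, config) {
  stopifnot(inherits(config, "cascade_config"))
  pass <- list(
    audit$stage1_logfc < config$logfc_obesity_max,
    audit$stage2_logfc > config$logfc_sex_min,
    audit$stage3_logfc > config$logfc_tumor_min,
    audit$hr_ok & !is.na(audit$hr) & audit$hr < config$hr_max,
    audit$n_correlated >= config$min_correlated_signature_genes
  )
  surv <- rep(TRUE, nrow(audit))
  stages <- vector("list", 5L)
  for (k in 1:5) {
    n_in <- sum(surv)
    surv <- surv & !is.na(pass[[k]]) & pass[[k]]
    stages[[k]] <- list(name = stage_names[k], n_input = n_in,
                        n_output = sum(surv),
                        genes = audit$gene_id[surv])
  }
  names(stages) <- stage_names
  list(stages = stages, final_genes = audit$gene_id[surv])
}

#' Run the five-filter screening cascade with full provenance
#'
#' Computes every stage's statistic for every gene in the expression
#' universe (the audit trail records all failures, not just the eliminating
#' one), then applies the thresholds in the printed order: obesity-score
#' differential expression in tumors, female-high in reference normal,
#' female reference-normal vs female tumor, protective hazard ratio in
#' female tumor survival, and correlation with the obesity signature in
#' tumors. Per-gene failures (e.g. a non-identifiable Cox fit or a
#' zero-variance candidate) are recorded and the gene eliminated, never
#' aborting the screen. An optional stage 6 intersects the survivors with
#' the union of user-supplied annotation sets.
#'
#' @param cohort an [expression_cohort()] with all three cohorts
#' @param survival a [survival_table()] covering (at least) the female
#'   tumor samples
#' @param signature a [gene_set()], the 14-gene obesity signature
#' @param config a [cascade_config()]
#' @param sex_calls optional data.frame from [infer_sex()] for the
#'   reference-normal samples; by default sex is taken from the cohort
#'   labels and inferred via [infer_sex()] for samples labelled `unknown`
#' @param scores optional precomputed [ssgsea_scores()] for the tumor
#'   samples
#' @param annotation_sets optional list of [gene_set()]s enabling stage 6
#' @param alpha ssGSEA weighting exponent
#' @param candidates candidate gene universe; by default all genes except
#'   the signature itself, the housekeeping gene and the sex markers (the
#'   measurement apparatus: the signature is what candidates are correlated
#'   against, not a candidate)
#' @param housekeeping,sex_markers gene ids excluded from the default
#'   candidate universe
#' @return object of class `cascade_report`: per-stage survivors and
#'   counts, `final_genes`, the full per-gene `audit` table (statistics at
#'   every stage, pass flags, `eliminated_at`), the config, and the scores
#'   used
#' @export
run_cascade <- function(cohort, survival, signature = obesity_signature(),
                        config = cascade_config(), sex_calls = NULL,
                        scores = NULL, annotation_sets = NULL, alpha = 0.25,
                        candidates = NULL, housekeeping = "GAPDH",
                        sex_markers = c("XIST", "RPS4Y1")) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(survival, "survival_table"),
            inherits(signature, "gene_set"))
  values <- cohort$values
  genes <- candidates %||%
    setdiff(rownames(values), c(signature$genes, housekeeping, sex_markers))
  if (!length(genes)) stop("empty candidate universe")
  tum <- which(cohort$cohort == "tumor")
  ref <- which(cohort$cohort == "ref_normal")
  if (!length(tum)) stop("stage1: no tumor samples")
  if (!length(ref)) stop("stage2: no ref_normal samples")

  ## stage 1: obesity-score split in tumors
  tumor_cohort <- cohort[, tum]
  if (is.null(scores)) scores <- ssgsea_scores(tumor_cohort, signature, alpha)
  grp <- dichotomize_scores(scores)
  hi <- tum[grp$group == "high"]; lo <- tum[grp$group == "low"]
  cvals <- values[genes, , drop = FALSE]
  s1 <- if (config$stage1_numerator == "high") row_logfc(cvals, hi, lo)
        else row_logfc(cvals, lo, hi)

  ## stage 2: sex contrast in ref_normal (inferred where unknown)
  sex_ref <- as.character(cohort$sex[ref])
  if (any(sex_ref == "unknown")) {
    if (is.null(sex_calls)) sex_calls <- infer_sex(cohort[, ref])
    idx <- match(colnames(values)[ref], sex_calls$sample_id)
    unk <- sex_ref == "unknown"
    if (anyNA(idx[unk]))
      stop("sex_calls do not cover all unknown-sex ref_normal samples")
    sex_ref[unk] <- sex_calls$inferred_sex[idx[unk]]
  }
  ref_f <- ref[sex_ref == "female"]; ref_m <- ref[sex_ref == "male"]
  if (!length(ref_f) || !length(ref_m))
    stop("stage2: both sexes must be present in ref_normal")
  s2 <- row_logfc(cvals, ref_f, ref_m)

  ## stage 3: female ref_normal vs female tumor
  tum_f <- tum[as.character(cohort$sex[tum]) == "female"]
  if (!length(tum_f)) stop("stage3: no female tumor samples")
  s3 <- row_logfc(cvals, ref_f, tum_f)

  ## stage 4: univariate Cox in female tumor samples
  female_tumor <- cohort[, tum_f]
  scr <- screen_protective(female_tumor, survival, genes = genes)
  hr <- scr$fits$hr[match(genes, scr$fits$gene_id)]
  hr_ok <- with(scr$fits[match(genes, scr$fits$gene_id), ],
                converged & !monotone_likelihood & is.na(error))

  ## stage 5: correlation with the signature across tumors
  sig_present <- intersect(signature$genes, rownames(values))
  if (!length(sig_present))
    stop("stage5: no signature genes present in the expression universe")
  ## correlations on log2(x+1): Pearson on the linear scale is dominated
  ## by lognormal outliers and understates co-expression
  tx <- t(log2(values[, tum, drop = FALSE] + 1))
  if (config$corr_method == "spearman") tx <- apply(tx, 2L, rank)
  sdv <- apply(tx, 2L, stats::sd)
  cand_ok <- sdv[genes] > 0
  cm <- suppressWarnings(stats::cor(tx[, genes, drop = FALSE],
                                    tx[, sig_present, drop = FALSE]))
  n_t <- length(tum)
  tstat <- cm * sqrt((n_t - 2) / pmax(1 - cm^2, .Machine$double.eps))
  pm <- 2 * stats::pt(-abs(tstat), df = n_t - 2)
  passes <- (cm > config$corr_min) & (pm < config$corr_p_max)
  passes[is.na(passes)] <- FALSE
  n_corr <- rowSums(passes)
  n_corr[!cand_ok] <- 0L # zero-variance candidate: correlation undefined

  audit <- data.frame(gene_id = genes,
                      stage1_logfc = s1, stage2_logfc = s2, stage3_logfc = s3,
                      hr = hr, hr_ok = hr_ok,
                      n_correlated = as.integer(n_corr),
                      corr_defined = cand_ok,
                      stringsAsFactors = FALSE)
  rownames(audit) <- NULL
  applied <- cascade_apply(audit, config)

  ## per-gene pass flags and elimination stage
  pass_mat <- cbind(
    stage1 = audit$stage1_logfc < config$logfc_obesity_max,
    stage2 = audit$stage2_logfc > config$logfc_sex_min,
    stage3 = audit$stage3_logfc > config$logfc_tumor_min,
    stage4 = audit$hr_ok & !is.na(audit$hr) & audit$hr < config$hr_max,
    stage5 = audit$n_correlated >= config$min_correlated_signature_genes)
  pass_mat[is.na(pass_mat)] <- FALSE
  elim <- apply(pass_mat, 1L, function(p) {
    f <- which(!p)
    if (length(f)) f[1L] else NA_integer_
  })
  audit <- cbind(audit, pass_mat, eliminated_at = elim)

  final_genes <- applied$final_genes
  stages <- applied$stages
  if (!is.null(annotation_sets)) {
    if (!length(annotation_sets))
      stop("stage6 enabled with an empty annotation set list")
    ann <- unique(unlist(lapply(annotation_sets, function(s) s$genes)))
    n_in <- length(final_genes)
    final_genes <- intersect(final_genes, ann)
    stages$stage6_annotation <- list(name = "stage6_annotation",
                                     n_input = n_in,
                                     n_output = length(final_genes),
                                     genes = final_genes)
  }

  ## structural invariant: survivor sets are nested
  prev <- audit$gene_id
  for (st in stages) {
    stopifnot(all(st$genes %in% prev))
    prev <- st$genes
  }

  structure(list(stages = stages, final_genes = final_genes, audit = audit,
                 config = config, scores = scores,
                 stage5_correlations = cm, stage5_p = pm,
                 n_samples = c(tumor = length(tum), ref_normal = length(ref),
                               female_tumor = length(tum_f))),
            class = "cascade_report")
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("screening cascade:\n")
  for (st in x$stages)
    cat(sprintf("  %-28s %4d -> %4d\n", st$name, st$n_input, st$n_output))
  cat("final genes:", if (length(x$final_genes))
    paste(x$final_genes, collapse = ", ") else "(none)", "\n")
  invisible(x)
}
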