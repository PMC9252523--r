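## Two-marker sex inference and the signature/housekeeping cohort-trend
## comparison.

#' Infer sample sex from XIST / RPS4Y1 expression
#'
#' Runs 2-means clustering on (log2(XIST + 1), log2(RPS4Y1 + 1)) with 50
#' restarts under a fixed internal seed; the cluster with the higher mean
#' XIST is labelled `female`. The call is invariant to multiplying all
#' expression by a positive constant only through the log transform, which
#' is applied internally and consistently.
#'
#' @param cohort an [expression_cohort()] containing both marker genes
#' @param xist,y_marker marker gene ids
#' @param restarts number of k-means restarts
#' @param seed internal clustering seed (the caller's RNG is untouched)
#' @return data.frame with `sample_id`, `inferred_sex` and
#'   `cluster_distance_margin` (absolute difference of the distances to the
#'   two centroids; 0 = maximally ambiguous)
#' @export
infer_sex <- function(cohort, xist = "XIST", y_marker = "RPS4Y1",
                      restarts = 50L, seed = 20240214L) {
  stopifnot(inherits(cohort, "expression_cohort"))
  for (m in c(xist, y_marker))
    if (!m %in% rownames(cohort$values))
      stop("marker gene '", m, "' is absent from the cohort")
  X <- cbind(log2(cohort$values[xist, ] + 1), log2(cohort$values[y_marker, ] + 1))
  if (nrow(X) < 2L) stop("at least 2 samples are required for 2-means clustering")
  if (all(X[, 1L] == X[1L, 1L]) && all(X[, 2L] == X[1L, 2L]))
    stop("all samples are identical on both markers; clusters are undefined")
  km <- with_seed(seed, stats::kmeans(X, centers = 2L, nstart = restarts))
  female_cluster <- which.max(km$centers[, 1L])
  d <- sqrt(cbind(rowSums(sweep(X, 2L, km$centers[1L, ])^2),
                  rowSums(sweep(X, 2L, km$centers[2L, ])^2)))
  data.frame(sample_id = colnames(cohort$values),
             inferred_sex = ifelse(km$cluster == female_cluster, "female", "male"),
             cluster_distance_margin = abs(d[, 1L] - d[, 2L]),
             stringsAsFactors = FALSE)
}

pooled_t <- function(a, b, welch = FALSE) {
  if (length(a) < 2L || length(b) < 2L)
    return(c(t = NA_real_, p = NA_real_))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # degenerate: identical constants -> no evidence of difference
    if (mean(a) == mean(b)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(a) - mean(b)) * Inf, p = 0))
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Cohort trend of signature genes normalized to a housekeeping gene
#'
#' For each signature gene, forms the per-sample ratio gene/housekeeping and
#' compares its mean across the three cohorts with two-sided Student t tests
#' (pooled variance by default, Welch optionally) for each cohort pair.
#' `monotone_decreasing` flags genes whose ratio means are strictly ordered
#' ref_normal > adj_normal > tumor. Raw and Benjamini-Hochberg adjusted
#' p values are both reported; a cohort with fewer than 2 samples yields NA
#' for the pairs involving it rather than an error.
#'
#' @param cohort an [expression_cohort()]
#' @param signature a [gene_set()] (genes absent from the cohort are skipped
#'   with a warning)
#' @param housekeeping housekeeping gene id; must be present with all
#'   values > 0
#' @param welch use Welch instead of pooled-variance t tests
#' @return data.frame, one row per gene: per-cohort ratio means, t and p per
#'   cohort pair, BH-adjusted p values, `monotone_decreasing`
#' @export
ratio_trend <- function(cohort, signature, housekeeping = "GAPDH",
                        welch = FALSE) {
  stopifnot(inherits(cohort, "expression_cohort"), inherits(signature, "gene_set"))
  if (!housekeeping %in% rownames(cohort$values))
    stop("housekeeping gene '", housekeeping, "' is absent from the cohort")
  hk <- cohort$values[housekeeping, ]
  if (any(hk <= 0))
    stop("housekeeping gene '", housekeeping,
         "' has non-positive value(s); ratios are undefined")
  genes <- signature$genes
  missing <- setdiff(genes, rownames(cohort$values))
  if (length(missing)) {
    warning("signature gene(s) absent from cohort: ",
            paste(missing, collapse = ", "))
    genes <- setdiff(genes, missing)
  }
  if (!length(genes)) stop("no signature genes present in the cohort")
  idx <- split(seq_along(cohort$cohort), cohort$cohort)
  pairs <- list(ref_adj = c("ref_normal", "adj_normal"),
                ref_tumor = c("ref_normal", "tumor"),
                adj_tumor = c("adj_normal", "tumor"))
  rows <- lapply(genes, function(g) {
    ratio <- cohort$values[g, ] / hk
    means <- vapply(idx, function(ii)
      if (length(ii)) mean(ratio[ii]) else NA_real_, 0)
    tp <- lapply(pairs, function(p)
      pooled_t(ratio[idx[[p[1L]]]], ratio[idx[[p[2L]]]], welch))
    mono <- !anyNA(means) &&
      means[["ref_normal"]] > means[["adj_normal"]] &&
      means[["adj_normal"]] > means[["tumor"]]
    data.frame(gene_id = g,
               mean_ref_normal = means[["ref_normal"]],
               mean_adj_normal = means[["adj_normal"]],
               mean_tumor = means[["tumor"]],
               t_ref_adj = tp$ref_adj[["t"]], p_ref_adj = tp$ref_adj[["p"]],
               t_ref_tumor = tp$ref_tumor[["t"]], p_ref_tumor = tp$ref_tumor[["p"]],
               t_adj_tumor = tp$adj_tumor[["t"]], p_adj_tumor = tp$adj_tumor[["p"]],
               monotone_decreasing = mono,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (col in c("p_ref_adj", "p_ref_tumor", "p_adj_tumor"))
    out[[sub("^p_", "padj_", col)]] <- stats::p.adjust(out[[col]], "BH")
  out
}
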