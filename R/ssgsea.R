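## Single-sample GSEA: weighted running-sum enrichment in the integral
## (sum-of-increments) convention, computed independently per sample.

#' Single-sample GSEA enrichment scores
#'
#' For each sample, genes are ranked by expression in decreasing order (ties
#' broken by gene id, lexicographically increasing) and assigned rank
#' magnitudes `r = N, N-1, ..., 1` from top to bottom. Walking down the
#' ranked list, the in-set cumulative mass `P_in(i)` (cumulative `r^alpha`
#' of set genes over total in-set `r^alpha`) and out-of-set cumulative count
#' `P_out(i)` (over `N - |S|`) are accumulated, and the raw enrichment score
#' is the sum over all `N` positions of `P_in(i) - P_out(i)` (the integral
#' form, not the maximum deviation). Because only within-sample ranks enter,
#' the score is invariant to any strictly increasing transform of a sample's
#' expression vector. Normalized scores divide the raw scores by
#' `max - min` across the cohort's samples.
#'
#' @param x an [expression_cohort()] or a numeric genes-by-samples matrix
#' @param signature a [gene_set()]; must intersect the gene universe and not
#'   cover it entirely
#' @param alpha rank-weighting exponent (default 0.25, the conventional
#'   ssGSEA weight; `alpha = 0` weights all ranks equally)
#' @return data.frame with `sample_id`, `raw_es`, `normalized_es`;
#'   attributes `alpha` and `signature_name`
#' @export
ssgsea_scores <- function(x, signature, alpha = 0.25) {
  values <- if (inherits(x, "expression_cohort")) x$values else x
  stopifnot(is.matrix(values), inherits(signature, "gene_set"))
  if (alpha < 0) stop("alpha must be >= 0")
  gene_ids <- rownames(values)
  n <- nrow(values)
  in_set <- gene_ids %in% signature$genes
  k <- sum(in_set)
  if (k == 0L)
    stop("signature '", signature$name, "' has empty intersection with the gene universe")
  if (k == n)
    stop("signature '", signature$name,
         "' covers the entire gene universe; out-of-set walk is undefined")
  rank_mag <- as.numeric(n:1)
  w_mag <- rank_mag^alpha
  ## tie-break: decreasing expression, then increasing gene id
  id_order <- order(gene_ids)
  raw <- vapply(seq_len(ncol(values)), function(j) {
    v <- values[, j]
    ord <- id_order[order(v[id_order], decreasing = TRUE)]
    inside <- in_set[ord]
    w <- w_mag * inside
    p_in <- cumsum(w) / sum(w)
    p_out <- cumsum(!inside) / (n - k)
    sum(p_in - p_out)
  }, 0)
  rng <- max(raw) - min(raw)
  norm <- if (rng > 0) raw / rng else rep(NA_real_, length(raw))
  if (rng == 0) warning("all raw scores identical; normalized_es is NA")
  structure(data.frame(sample_id = colnames(values), raw_es = raw,
                       normalized_es = norm, stringsAsFactors = FALSE),
            alpha = alpha, signature_name = signature$name)
}

#' Median-split of enrichment scores into high/low groups
#'
#' Samples strictly above the median score are `high`, those at or below it
#' `low` (so for scores 1, 2, 3 the high group is \{3\}).
#'
#' @param scores data.frame from [ssgsea_scores()] (or any data.frame with
#'   `sample_id` and the score column)
#' @param by score column to split on
#' @return data.frame with `sample_id` and `group`; attribute `counts`
#' @export
dichotomize_scores <- function(scores, by = "raw_es") {
  stopifnot(is.data.frame(scores), by %in% names(scores))
  s <- scores[[by]]
  if (length(s) < 2L) stop("at least 2 samples are required to dichotomize")
  if (max(s) == min(s)) stop("all scores are equal; high/low groups are undefined")
  med <- stats::median(s)
  grp <- ifelse(s > med, "high", "low")
  structure(data.frame(sample_id = scores$sample_id, group = grp,
                       stringsAsFactors = FALSE),
            counts = c(high = sum(grp == "high"), low = sum(grp == "low")))
}
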