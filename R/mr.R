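## Two-sample Mendelian randomization from summary statistics:
## harmonization of effect alleles, inverse-variance-weighted estimate,
## MR-Egger regression with directional-pleiotropy intercept test, and
## sex-stratified wrappers.

is_palindromic <- function(ea, oa) complement_alleles(ea) == oa

#' Harmonize exposure and outcome GWAS summary tables
#'
#' Intersects on `snp_id` and aligns every outcome effect to the exposure's
#' effect allele: swapped alleles flip the sign of the outcome beta;
#' opposite-strand rows are complemented and then aligned. Palindromic SNPs
#' (A/T, C/G) cannot be aligned from the letters; they are resolved by
#' effect-allele frequency when both frequencies are available and both lie
#' outside the ambiguity window (default 0.42-0.58): matching minor/major
#' sides mean the orientations agree, opposite sides mean the outcome is
#' flipped. Otherwise they are dropped, as are rows whose alleles cannot be
#' reconciled or that carry missing effects.
#'
#' @param exposure,outcome [gwas_summary()] tables sharing at least one SNP
#' @param eaf_window palindromic ambiguity window on the allele frequency
#' @return data.frame of class `harmonized_instruments` with one row per
#'   shared SNP: `gamma`/`se_x` (exposure), `Gamma`/`se_y` (outcome, aligned
#'   to the exposure effect allele), `kept`, `drop_reason`
#' @export
harmonize_gwas <- function(exposure, outcome, eaf_window = c(0.42, 0.58)) {
  stopifnot(inherits(exposure, "gwas_summary"), inherits(outcome, "gwas_summary"))
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  if (!length(shared)) stop("exposure and outcome share no SNPs")
  ex <- exposure[match(shared, exposure$snp_id), ]
  ou <- outcome[match(shared, outcome$snp_id), ]
  m <- length(shared)
  Gamma <- ou$beta
  eaf_y <- ou$eaf
  kept <- rep(TRUE, m)
  reason <- rep(NA_character_, m)
  for (j in seq_len(m)) {
    ea_x <- ex$effect_allele[j]; oa_x <- ex$other_allele[j]
    ea_y <- ou$effect_allele[j]; oa_y <- ou$other_allele[j]
    if (anyNA(c(ex$beta[j], ou$beta[j], ex$se[j], ou$se[j]))) {
      kept[j] <- FALSE; reason[j] <- "missing"; next
    }
    if (is_palindromic(ea_x, oa_x)) {
      same_letters <- (ea_y == ea_x && oa_y == oa_x) ||
        (ea_y == oa_x && oa_y == ea_x)
      if (!same_letters) { kept[j] <- FALSE; reason[j] <- "allele_mismatch"; next }
      fx <- ex$eaf[j]
      fy <- if (ea_y == ea_x) ou$eaf[j] else 1 - ou$eaf[j]
      ambiguous <- is.na(fx) || is.na(fy) ||
        (fx > eaf_window[1L] && fx < eaf_window[2L]) ||
        (fy > eaf_window[1L] && fy < eaf_window[2L])
      if (ambiguous) { kept[j] <- FALSE; reason[j] <- "palindromic_ambiguous"; next }
      flip <- (fx < 0.5) != (fy < 0.5)
      base <- if (ea_y == ea_x) ou$beta[j] else -ou$beta[j]
      Gamma[j] <- if (flip) -base else base
      eaf_y[j] <- if (flip) 1 - fy else fy
      next
    }
    if (ea_y == ea_x && oa_y == oa_x) {
      next
    } else if (ea_y == oa_x && oa_y == ea_x) {
      Gamma[j] <- -ou$beta[j]
      eaf_y[j] <- 1 - ou$eaf[j]
    } else {
      cea <- complement_alleles(ea_y); coa <- complement_alleles(oa_y)
      if (cea == ea_x && coa == oa_x) {
        next
      } else if (cea == oa_x && coa == ea_x) {
        Gamma[j] <- -ou$beta[j]
        eaf_y[j] <- 1 - ou$eaf[j]
      } else {
        kept[j] <- FALSE; reason[j] <- "allele_mismatch"
      }
    }
  }
  structure(data.frame(snp_id = shared,
                       effect_allele = ex$effect_allele,
                       other_allele = ex$other_allele,
                       gamma = ex$beta, se_x = ex$se, eaf_x = ex$eaf,
                       Gamma = Gamma, se_y = ou$se, eaf_y = eaf_y,
                       kept = kept, drop_reason = reason,
                       stringsAsFactors = FALSE),
            class = c("harmonized_instruments", "data.frame"))
}

retained <- function(instr) {
  stopifnot(inherits(instr, "harmonized_instruments"))
  instr[instr$kept, , drop = FALSE]
}

mr_result <- function(method, slope, se_slope, p_slope, n_snps, q = NA_real_,
                      i_squared = NA_real_, intercept = NA_real_,
                      se_intercept = NA_real_, p_intercept = NA_real_) {
  structure(list(method = method, slope = slope, se_slope = se_slope,
                 p_slope = p_slope, intercept = intercept,
                 se_intercept = se_intercept, p_intercept = p_intercept,
                 n_snps = n_snps, cochran_q = q, i_squared = i_squared),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s: slope=%.4f (se %.4f, p=%.3g), n_snps=%d",
              x$method, x$slope, x$se_slope, x$p_slope, x$n_snps))
  if (!is.na(x$intercept))
    cat(sprintf("; intercept=%.4f (se %.4f, p=%.3g)",
                x$intercept, x$se_intercept, x$p_intercept))
  if (!is.na(x$cochran_q)) cat(sprintf("; Q=%.2f", x$cochran_q))
  cat("\n")
  invisible(x)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of the aligned outcome effects on the exposure
#' effects through the origin with weights `1/se_y^2`:
#' `slope = sum(w g G) / sum(w g^2)`. The fixed-effect standard error
#' `1/sqrt(sum(w g^2))` is inflated multiplicatively by
#' `sqrt(Q/(n-1))` when Cochran's Q exceeds its degrees of freedom
#' (multiplicative random-effects model). With a single instrument the
#' estimate reduces to the Wald ratio `G/g`. Two-sided normal p value.
#'
#' @param instr a `harmonized_instruments` table (dropped rows are ignored)
#' @return an `mr_result`
#' @export
mr_ivw <- function(instr) {
  h <- retained(instr)
  n <- nrow(h)
  if (n < 1L) stop("no retained instruments")
  if (all(h$gamma == 0)) stop("all exposure effects are zero; slope undefined")
  w <- 1 / h$se_y^2
  denom <- sum(w * h$gamma^2)
  slope <- sum(w * h$gamma * h$Gamma) / denom
  se <- 1 / sqrt(denom)
  q <- sum(w * (h$Gamma - slope * h$gamma)^2)
  if (n >= 2L && q / (n - 1) > 1) se <- se * sqrt(q / (n - 1))
  i2 <- if (n < 2L) NA_real_ else if (q > 0) max(0, (q - (n - 1)) / q) else 0
  mr_result("ivw", slope, se, 2 * stats::pnorm(-abs(slope / se)), n,
            q = if (n >= 2L) q else 0, i_squared = i2)
}

#' MR-Egger regression with pleiotropy intercept test
#'
#' Weighted least squares of the aligned outcome effects on the exposure
#' effects with an intercept, weights `1/se_y^2`, after orienting every
#' instrument so its exposure effect is non-negative (which makes the fit
#' invariant to arbitrary allele coding). The intercept estimates the mean
#' directional pleiotropy; under the InSIDE assumption the slope remains a
#' consistent causal estimate when the intercept is non-zero. Standard
#' errors use a multiplicative residual inflation factor
#' `max(1, Q_egger/(n-2))` and p values are two-sided t with n-2 df.
#'
#' @param instr a `harmonized_instruments` table; at least 3 retained
#'   instruments with non-constant exposure effects
#' @return an `mr_result` with intercept fields
#' @export
mr_egger <- function(instr) {
  h <- retained(instr)
  n <- nrow(h)
  if (n < 3L) stop("MR-Egger requires at least 3 retained instruments")
  flip <- h$gamma < 0
  g <- ifelse(flip, -h$gamma, h$gamma)
  G <- ifelse(flip, -h$Gamma, h$Gamma)
  if (stats::sd(g) == 0)
    stop("all exposure effects equal after orientation; Egger fit is collinear")
  w <- 1 / h$se_y^2
  sw <- sum(w); swx <- sum(w * g); swxx <- sum(w * g^2)
  swy <- sum(w * G); swxy <- sum(w * g * G)
  det <- sw * swxx - swx^2
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  resid <- G - intercept - slope * g
  q <- sum(w * resid^2)
  phi <- max(1, q / (n - 2))
  se_slope <- sqrt(phi * sw / det)
  se_int <- sqrt(phi * swxx / det)
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = n - 2)
  p_int <- 2 * stats::pt(-abs(intercept / se_int), df = n - 2)
  mr_result("egger", slope, se_slope, p_slope, n, q = q,
            intercept = intercept, se_intercept = se_int, p_intercept = p_int)
}

#' Sex-stratified two-sample MR
#'
#' Runs harmonization, IVW and MR-Egger per stratum and assembles a
#' comparison table of slopes and p values. A stratum whose inputs fail the
#' per-method preconditions is reported as unavailable (with the error
#' message) instead of aborting the other strata.
#'
#' @param exposure_by_stratum,outcome_by_stratum named lists of
#'   [gwas_summary()] tables; names from `all`, `female`, `male`
#' @return list of class `mr_stratified`: per-stratum results (`harmonized`,
#'   `ivw`, `egger`, or `unavailable` + `message`) plus a `comparison`
#'   data.frame
#' @export
mr_stratified <- function(exposure_by_stratum, outcome_by_stratum) {
  strata <- names(exposure_by_stratum)
  if (is.null(strata) || !all(strata %in% c("all", "female", "male")))
    stop("strata must be named from {all, female, male}")
  if (!setequal(strata, names(outcome_by_stratum)))
    stop("exposure and outcome strata do not match")
  res <- lapply(strata, function(s) {
    tryCatch({
      h <- harmonize_gwas(exposure_by_stratum[[s]], outcome_by_stratum[[s]])
      list(unavailable = FALSE, harmonized = h,
           ivw = mr_ivw(h), egger = mr_egger(h))
    }, error = function(e)
      list(unavailable = TRUE, message = conditionMessage(e)))
  })
  names(res) <- strata
  rows <- list()
  for (s in strata) {
    if (res[[s]]$unavailable) next
    for (m in c("ivw", "egger")) {
      r <- res[[s]][[m]]
      rows[[length(rows) + 1L]] <-
        data.frame(stratum = s, method = m, slope = r$slope,
                   se = r$se_slope, p = r$p_slope,
                   intercept = r$intercept, p_intercept = r$p_intercept,
                   n_snps = r$n_snps, stringsAsFactors = FALSE)
    }
  }
  res$comparison <- if (length(rows)) do.call(rbind, rows) else NULL
  class(res) <- "mr_stratified"
  res
}

#' @export
print.mr_stratified <- function(x, ...) {
  if (!is.null(x$comparison)) print(x$comparison)
  for (s in setdiff(names(x), "comparison"))
    if (isTRUE(x[[s]]$unavailable))
      cat(sprintf("stratum '%s' unavailable: %s\n", s, x[[s]]$message))
  invisible(x)
}
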