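## Univariate Cox proportional-hazards fitting (Efron tie correction,
## Newton-Raphson with step halving), Kaplan-Meier product-limit curves,
## and weighted two-sample survival tests (log-rank, Gehan-Breslow
## generalized Wilcoxon, Tarone-Ware), implemented from their defining
## formulas. The pre-installed `survival` package is used only as an
## independent oracle in the test suite.

## Efron-corrected log partial likelihood, score and information for a
## single covariate. Returns the three quantities at the given beta.
cox_quantities <- function(beta, time, event, x) {
  ord <- order(time)
  t_s <- time[ord]; d_s <- event[ord]; x_s <- x[ord]
  r <- exp(beta * x_s)
  S0 <- rev(cumsum(rev(r)))
  S1 <- rev(cumsum(rev(x_s * r)))
  S2 <- rev(cumsum(rev(x_s^2 * r)))
  ev_times <- unique(t_s[d_s == 1])
  ll <- 0; U <- 0; I <- 0
  for (tk in ev_times) {
    i0 <- match(TRUE, t_s >= tk) # first index of the risk set
    dead <- which(t_s == tk & d_s == 1)
    d <- length(dead)
    D0 <- sum(r[dead]); D1 <- sum(x_s[dead] * r[dead]); D2 <- sum(x_s[dead]^2 * r[dead])
    frac <- (seq_len(d) - 1) / d
    phi0 <- S0[i0] - frac * D0
    phi1 <- S1[i0] - frac * D1
    phi2 <- S2[i0] - frac * D2
    ll <- ll + beta * sum(x_s[dead]) - sum(log(phi0))
    U <- U + sum(x_s[dead]) - sum(phi1 / phi0)
    I <- I + sum(phi2 / phi0 - (phi1 / phi0)^2)
  }
  list(loglik = ll, score = U, information = I)
}

#' Univariate Cox proportional-hazards fit
#'
#' Maximizes the Efron-corrected log partial likelihood by Newton-Raphson
#' from `beta = 0`, with step-halving whenever a step would decrease the
#' likelihood, convergence at `|delta beta| < 1e-9` and at most `max_iter`
#' iterations. The standard error comes from the observed information at
#' the maximum; the reported p value is the two-sided Wald test. A
#' diverging estimate (|beta| growing without a likelihood interior
#' maximum) sets `monotone_likelihood` and returns the fit unconverged.
#' The score test at `beta = 0` is also reported; with a binary covariate
#' and no ties its chi-square equals the log-rank chi-square.
#'
#' @param time positive follow-up times
#' @param event 0/1 event indicators (>= 1 event required)
#' @param x numeric covariate with positive variance
#' @param tol convergence tolerance on the Newton step
#' @param max_iter maximum Newton iterations
#' @return object of class `cox_fit`: beta, se, hr, Wald z and p, score
#'   test chi-square, log likelihoods, convergence flags
#' @export
cox_univariate <- function(time, event, x, tol = 1e-9, max_iter = 50L) {
  stopifnot(length(time) == length(event), length(x) == length(time))
  if (any(!is.finite(time) | time <= 0)) stop("times must be finite and > 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  if (sum(event) < 1) stop("at least one event is required")
  if (stats::sd(x) == 0)
    stop("covariate is constant; the hazard ratio is not identifiable")
  q0 <- cox_quantities(0, time, event, x)
  score_chisq <- if (q0$information > 0) q0$score^2 / q0$information else NA_real_
  beta <- 0; ll <- q0$loglik; q <- q0
  converged <- FALSE; monotone <- FALSE; iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (q$information <= 0) { monotone <- TRUE; break }
    step <- q$score / q$information
    new_beta <- beta + step
    q_new <- cox_quantities(new_beta, time, event, x)
    halvings <- 0L
    while (q_new$loglik < ll && halvings < 25L) {
      halvings <- halvings + 1L
      step <- step / 2
      new_beta <- beta + step
      q_new <- cox_quantities(new_beta, time, event, x)
    }
    beta <- new_beta; ll <- q_new$loglik; q <- q_new
    if (abs(beta) > 15) { monotone <- TRUE; break }
    if (abs(step) < tol) { converged <- TRUE; break }
  }
  se <- if (q$information > 0) 1 / sqrt(q$information) else NA_real_
  z <- beta / se
  structure(list(beta = beta, se = se, hr = exp(beta), wald_z = z,
                 p_value = 2 * stats::pnorm(-abs(z)),
                 score_chisq = score_chisq,
                 loglik_null = q0$loglik, loglik = ll,
                 n = length(time), n_events = sum(event),
                 iterations = iter, converged = converged,
                 monotone_likelihood = monotone),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("cox_fit: beta=%.4f (se %.4f), HR=%.4f, p=%.3g, n=%d (%d events)%s\n",
              x$beta, x$se, x$hr, x$p_value, x$n, x$n_events,
              if (x$monotone_likelihood) " [monotone likelihood]"
              else if (!x$converged) " [not converged]" else ""))
  invisible(x)
}

#' Screen genes for protective hazard ratios (HR < 1)
#'
#' Fits a univariate Cox model per gene on the z-scored log2(x+1)
#' expression of the samples shared between the expression cohort and the
#' survival table, and returns the genes with fitted HR < 1 (point
#' estimate; no p-value filter, per the printed criterion). Per-gene
#' failures (constant expression, monotone likelihood) are flagged and the
#' gene excluded from the retained list, never aborting the screen.
#'
#' @param cohort an [expression_cohort()] (pre-subset to the samples of
#'   interest, e.g. female tumor)
#' @param survival a [survival_table()]
#' @param genes gene ids to screen (default: all genes in the cohort)
#' @param dichotomize split each gene at its median instead of using the
#'   continuous z-scored covariate
#' @return list with `retained` (gene ids with HR < 1) and `fits` (per-gene
#'   data.frame of beta, se, hr, p, convergence flags, error messages)
#' @export
screen_protective <- function(cohort, survival, genes = NULL,
                              dichotomize = FALSE) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(survival, "survival_table"))
  shared <- intersect(colnames(cohort$values), survival$sample_id)
  if (length(shared) < 10L)
    stop("fewer than 10 samples shared between expression and survival tables")
  sv <- survival[match(shared, survival$sample_id), ]
  genes <- genes %||% rownames(cohort$values)
  vals <- cohort$values[genes, shared, drop = FALSE]
  z <- survival_covariate(vals)
  fits <- lapply(seq_along(genes), function(i) {
    covar <- if (dichotomize) as.numeric(vals[i, ] > stats::median(vals[i, ]))
             else z[i, ]
    tryCatch({
      f <- cox_univariate(sv$time_days, sv$event, covar)
      data.frame(gene_id = genes[i], beta = f$beta, se = f$se, hr = f$hr,
                 wald_z = f$wald_z, p_value = f$p_value,
                 converged = f$converged,
                 monotone_likelihood = f$monotone_likelihood,
                 error = NA_character_, stringsAsFactors = FALSE)
    }, error = function(e)
      data.frame(gene_id = genes[i], beta = NA_real_, se = NA_real_,
                 hr = NA_real_, wald_z = NA_real_, p_value = NA_real_,
                 converged = FALSE, monotone_likelihood = FALSE,
                 error = conditionMessage(e), stringsAsFactors = FALSE))
  })
  fits <- do.call(rbind, fits)
  ok <- fits$converged & !fits$monotone_likelihood & is.na(fits$error)
  list(retained = fits$gene_id[ok & fits$hr < 1], fits = fits,
       n_samples = length(shared))
}

#' Kaplan-Meier product-limit curves
#'
#' @param time,event follow-up times and 0/1 event indicators
#' @param group optional group labels (one curve per group)
#' @return data.frame with `group`, `time` (distinct event times,
#'   ascending), `n_risk`, `n_event`, `survival` (product-limit estimate;
#'   S(0) = 1 is implicit)
#' @export
km_curve <- function(time, event, group = NULL) {
  stopifnot(length(time) == length(event))
  if (is.null(group)) group <- rep("all", length(time))
  time <- unname(time); event <- unname(event); group <- unname(group)
  out <- lapply(split(seq_along(time), group), function(ii) {
    tt <- time[ii]; ev <- event[ii]
    et <- sort(unique(tt[ev == 1]))
    if (!length(et)) return(NULL)
    n_risk <- vapply(et, function(t0) sum(tt >= t0), 0)
    n_event <- vapply(et, function(t0) sum(tt == t0 & ev == 1), 0)
    data.frame(group = group[ii[1L]], time = et, n_risk = n_risk,
               n_event = n_event,
               survival = cumprod(1 - n_event / n_risk),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Two-sample survival test (log-rank family)
#'
#' Computes `sum_i w_i (O_i - E_i)` over the pooled distinct event times,
#' where `O_i` and `E_i` are the observed and hypergeometric-expected
#' deaths in the first group and `w_i` is 1 for the log-rank test, the
#' total number at risk `n_i` for the Gehan-Breslow generalized Wilcoxon
#' test (front-loading early differences) and `sqrt(n_i)` for Tarone-Ware.
#' The variance is the weighted hypergeometric variance and the chi-square
#' statistic is referred to 1 df. Swapping the two group labels negates the
#' statistic exactly and leaves the p value unchanged. For small samples an
#' exact permutation p value (complete enumeration over label assignments
#' preserving group sizes) is available.
#'
#' @param time,event follow-up times and 0/1 event indicators
#' @param group two-level group labels (the "first" group is the first
#'   factor level)
#' @param method `gehan_wilcoxon` (default), `logrank` or `tarone_ware`
#' @param p_method `chisq` (asymptotic) or `permutation` (exact enumeration;
#'   feasible up to `choose(n, n1) <= 1e5`)
#' @return object of class `surv_test_result`: statistic, variance,
#'   chi_square, p_value, method, group sizes
#' @export
surv_test <- function(time, event, group,
                      method = c("gehan_wilcoxon", "logrank", "tarone_ware"),
                      p_method = c("chisq", "permutation")) {
  method <- match.arg(method)
  p_method <- match.arg(p_method)
  group <- factor(group)
  if (nlevels(group) != 2L)
    stop("exactly two non-empty groups are required, got ",
         nlevels(group))
  if (any(table(group) == 0L)) stop("one group is empty")
  if (sum(event) < 1) stop("no events; the test is undefined")
  stat_fun <- function(g1) {
    et <- sort(unique(time[event == 1]))
    U <- 0; V <- 0
    for (t0 in et) {
      at_risk <- time >= t0
      n_i <- sum(at_risk)
      n1_i <- sum(at_risk & g1)
      d_i <- sum(time == t0 & event == 1)
      o1_i <- sum(time == t0 & event == 1 & g1)
      e1_i <- d_i * n1_i / n_i
      w <- switch(method, logrank = 1, gehan_wilcoxon = n_i,
                  tarone_ware = sqrt(n_i))
      U <- U + w * (o1_i - e1_i)
      if (n_i > 1)
        V <- V + w^2 * d_i * (n_i - d_i) / (n_i - 1) *
          (n1_i / n_i) * (1 - n1_i / n_i)
    }
    c(U = U, V = V)
  }
  g1 <- group == levels(group)[1L]
  uv <- stat_fun(g1)
  chi <- if (uv[["V"]] > 0) uv[["U"]]^2 / uv[["V"]] else NA_real_
  if (p_method == "chisq") {
    p <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  } else {
    n <- length(time); n1 <- sum(g1)
    if (choose(n, n1) > 1e5)
      stop("permutation enumeration infeasible: choose(n, n1) > 1e5")
    combos <- utils::combn(n, n1)
    obs <- abs(uv[["U"]])
    stats_perm <- apply(combos, 2L, function(ii) {
      gg <- rep(FALSE, n); gg[ii] <- TRUE
      stat_fun(gg)[["U"]]
    })
    p <- mean(abs(stats_perm) >= obs - 1e-12)
  }
  structure(list(statistic = uv[["U"]], variance = uv[["V"]],
                 chi_square = chi, p_value = p, method = method,
                 p_method = p_method,
                 n = as.vector(table(group)),
                 groups = levels(group)),
            class = "surv_test_result")
}

#' @export
print.surv_test_result <- function(x, ...) {
  cat(sprintf("%s test (%s p): statistic=%.4f, chi2=%.4f, p=%.4g (n = %s)\n",
              x$method, x$p_method, x$statistic, x$chi_square, x$p_value,
              paste(x$n, collapse = "/")))
  invisible(x)
}

#' Median-split survival comparison for one gene
#'
#' Splits the shared samples at the gene's median expression (strictly
#' above the median = `high`), administratively censors follow-up at the
#' horizon (5 years = 1826 days by default), and runs a two-sample survival
#' test between the groups.
#'
#' @param cohort an [expression_cohort()]
#' @param survival a [survival_table()]
#' @param gene gene id
#' @param horizon_days administrative censoring horizon (`Inf` disables)
#' @param method,p_method passed to [surv_test()]
#' @return the [surv_test()] result, with `gene`, `horizon_days` and the
#'   per-group sizes attached
#' @export
median_split_survival <- function(cohort, survival, gene,
                                  horizon_days = 1826,
                                  method = "gehan_wilcoxon",
                                  p_method = "chisq") {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(survival, "survival_table"))
  if (!gene %in% rownames(cohort$values))
    stop("gene '", gene, "' is absent from the cohort")
  shared <- intersect(colnames(cohort$values), survival$sample_id)
  if (!length(shared)) stop("no samples shared between expression and survival")
  v <- cohort$values[gene, shared]
  if (max(v) == min(v))
    stop("gene '", gene, "' has constant expression; the split is degenerate")
  grp <- factor(ifelse(v > stats::median(v), "high", "low"),
                levels = c("high", "low"))
  sv <- survival[match(shared, survival$sample_id), ]
  tt <- sv$time_days; ev <- sv$event
  over <- tt > horizon_days
  ev[over] <- 0L
  tt[over] <- horizon_days
  res <- surv_test(tt, ev, grp, method = method, p_method = p_method)
  res$gene <- gene
  res$horizon_days <- horizon_days
  res
}
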