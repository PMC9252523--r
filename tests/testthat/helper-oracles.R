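# Independent oracles, deliberately written as naive per-position /
# per-pair loops so they share no code path with the package.

# ssGSEA running sum, one explicit position at a time.
oracle_ssgsea <- function(expr, gene_ids, set_genes, alpha) {
  n <- length(expr)
  ord <- order(-expr, gene_ids)
  inside <- gene_ids[ord] %in% set_genes
  k <- sum(inside)
  rmag <- (n:1)^alpha
  denom_in <- sum(rmag[inside])
  p_in <- 0; p_out <- 0; es <- 0
  for (i in seq_len(n)) {
    if (inside[i]) p_in <- p_in + rmag[i] / denom_in
    else p_out <- p_out + 1 / (n - k)
    es <- es + (p_in - p_out)
  }
  es
}

# Exact Cox log partial likelihood for untied data (Breslow = Efron = exact).
oracle_cox_loglik <- function(beta, time, event, x) {
  s <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    s <- s + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  s
}

# Hand-rolled golden-section maximization.
oracle_golden_max <- function(f, lo, hi, tol = 1e-9) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a); d1 <- a + gr * (b - a)
  fc <- f(c1); fd <- f(d1)
  while (b - a > tol) {
    if (fc > fd) {
      b <- d1; d1 <- c1; fd <- fc
      c1 <- b - gr * (b - a); fc <- f(c1)
    } else {
      a <- c1; c1 <- d1; fc <- fd
      d1 <- a + gr * (b - a); fd <- f(d1)
    }
  }
  (a + b) / 2
}

# Gehan's pairwise scoring U: +1 when the group-1 member definitively
# outlives the group-2 member, -1 for the reverse, 0 when indeterminate.
# Equals minus the n_i-weighted observed-minus-expected sum.
oracle_gehan_U <- function(time, event, g1) {
  U <- 0
  for (i in which(g1)) for (j in which(!g1)) {
    if (event[j] == 1 &&
        (time[i] > time[j] || (time[i] == time[j] && event[i] == 0))) {
      U <- U + 1
    } else if (event[i] == 1 &&
               (time[j] > time[i] || (time[j] == time[i] && event[j] == 0))) {
      U <- U - 1
    }
  }
  U
}

# Exact permutation p value of |U| over all label assignments that preserve
# the group sizes.
oracle_gehan_perm_p <- function(time, event, g1) {
  n <- length(time)
  obs <- abs(oracle_gehan_U(time, event, g1))
  combos <- utils::combn(n, sum(g1))
  stats <- apply(combos, 2L, function(ii) {
    gg <- rep(FALSE, n); gg[ii] <- TRUE
    oracle_gehan_U(time, event, gg)
  })
  mean(abs(stats) >= obs - 1e-12)
}

# Tiny expression-cohort fixture: deterministic values, no randomness.
make_toy_cohort <- function() {
  vals <- matrix(c(5, 1, 8,
                   2, 2, 2,
                   9, 3, 1,
                   4, 4, 4,
                   1, 7, 6,
                   10, 10, 10), nrow = 6, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3", "g4", "g5", "GAPDH"),
                                 c("s1", "s2", "s3")))
  expression_cohort(vals, c("ref_normal", "adj_normal", "tumor"),
                    c("female", "male", "female"))
}

quick_sim <- function(seed = 42, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_expression(cfg)
  list(cfg = cfg, cohort = sim$cohort, truth = sim$truth)
}
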