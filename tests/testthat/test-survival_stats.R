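random_surv <- function(n, seed, tie = FALSE, binary = FALSE) {
  set.seed(seed)
  x <- if (binary) rbinom(n, 1, 0.5) else rnorm(n)
  tt <- rexp(n, exp(0.4 * x) / 50)
  if (tie) tt <- ceiling(tt / 10) * 10
  cens <- runif(n, 0, 150)
  list(time = pmin(tt, cens), event = as.integer(tt <= cens), x = x)
}

test_that("cox_univariate agrees with survival::coxph under Efron ties", {
  skip_if_not_installed("survival")
  for (seed in 1:12) {
    d <- random_surv(60, seed, tie = TRUE)
    if (sum(d$event) < 2 || sd(d$x) == 0) next
    fit <- cox_univariate(d$time, d$event, d$x)
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ d$x,
                           ties = "efron")
    expect_equal(fit$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(fit$se, sqrt(as.numeric(ref$var)), tolerance = 1e-6)
    expect_equal(fit$loglik, ref$loglik[2], tolerance = 1e-6)
  }
})

test_that("degenerate Cox inputs are flagged, not mis-fit", {
  expect_error(cox_univariate(c(1, 2, 3), c(1, 1, 0), c(2, 2, 2)),
               "constant")
  expect_error(cox_univariate(c(1, 2), c(0, 0), c(1, 0)), "one event")
  # two subjects, both events, perfectly separating covariate: the partial
  # likelihood e^b/(e^b+1) is monotone in b -> no interior maximum
  fit <- cox_univariate(c(1, 2), c(1, 1), c(1, 0))
  expect_true(fit$monotone_likelihood)
  expect_false(fit$converged)
})

test_that("Newton beta matches golden-section maximization of the exact likelihood", {
  for (seed in 1:10) {
    set.seed(seed + 100)
    n <- sample(4:8, 1)
    d <- list(time = sample(100, n), event = rbinom(n, 1, 0.8), x = rnorm(n))
    if (sum(d$event) < 2 || sd(d$x) == 0) next
    fit <- cox_univariate(d$time, d$event, d$x)
    if (!fit$converged) next
    gold <- oracle_golden_max(function(b) oracle_cox_loglik(b, d$time, d$event, d$x),
                              -10, 10)
    expect_equal(fit$beta, gold, tolerance = 1e-6)
  }
})

test_that("score test equals the log-rank chi-square for a binary covariate", {
  for (seed in 1:10) {
    d <- random_surv(40, seed + 50, binary = TRUE)
    if (sum(d$event) < 2 || sd(d$x) == 0) next
    fit <- cox_univariate(d$time, d$event, d$x)
    lr <- surv_test(d$time, d$event, factor(d$x), method = "logrank")
    expect_equal(fit$score_chisq, lr$chi_square, tolerance = 1e-8)
  }
})

test_that("KM estimator equals the empirical survival function without censoring", {
  tt <- c(3, 1, 4, 1, 5, 9, 2, 6)
  km <- km_curve(tt, rep(1, 8))
  ecdf_surv <- vapply(km$time, function(t0) mean(tt > t0), 0)
  expect_equal(km$survival, ecdf_surv)
  expect_true(all(diff(km$survival) <= 0))
  skip_if_not_installed("survival")
  d <- random_surv(50, 9)
  km2 <- km_curve(d$time, d$event)
  sf <- survival::survfit(survival::Surv(d$time, d$event) ~ 1)
  at <- sf$time %in% km2$time
  expect_equal(km2$survival, sf$surv[at], tolerance = 1e-12)
})

test_that("weighted two-sample statistics behave per their definitions", {
  d <- random_surv(16, 3)
  g <- factor(rep(c("A", "B"), 8))
  for (m in c("gehan_wilcoxon", "logrank", "tarone_ware")) {
    a <- surv_test(d$time, d$event, g, method = m)
    b <- surv_test(d$time, d$event, factor(g, levels = c("B", "A")), method = m)
    expect_equal(a$statistic, -b$statistic, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_gte(a$chi_square, 0)
  }
  # Gehan's weighted O-E sum is minus the classical pairwise scoring U
  for (seed in 4:8) {
    d <- random_surv(10, seed, tie = TRUE)
    if (sum(d$event) < 1) next
    g1 <- rep(c(TRUE, FALSE), 5)
    st <- surv_test(d$time, d$event, factor(ifelse(g1, "A", "B")),
                    method = "gehan_wilcoxon")
    expect_equal(st$statistic, -oracle_gehan_U(d$time, d$event, g1),
                 tolerance = 1e-12)
  }
})

test_that("early separation is front-loaded by the Gehan weights", {
  tm <- c(1, 2, 3, 4, 25, 26, 27, 28, 5, 6, 7, 8, 25, 26, 27, 28)
  ev <- c(1, 1, 1, 1, 0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0)
  g <- factor(rep(c("A", "B"), each = 8))
  gw <- surv_test(tm, ev, g, method = "gehan_wilcoxon")
  lr <- surv_test(tm, ev, g, method = "logrank")
  expect_gte(gw$chi_square, lr$chi_square)
})

test_that("test preconditions are enforced", {
  expect_error(surv_test(1:4, rep(1, 4), factor(rep("A", 4))), "two non-empty|two")
  expect_error(surv_test(1:4, rep(0, 4), factor(rep(c("A", "B"), 2))),
               "no events")
})

test_that("median split respects the horizon and degenerate-split rules", {
  s <- quick_sim(seed = 37)
  cfg <- s$cfg
  sv <- simulate_survival(cfg, s$cohort, s$truth)
  far <- median_split_survival(s$cohort, sv, "HIT_01",
                               horizon_days = max(sv$time_days) + 1)
  untr <- median_split_survival(s$cohort, sv, "HIT_01", horizon_days = Inf)
  expect_equal(far$statistic, untr$statistic)
  expect_equal(far$p_value, untr$p_value)

  # planted protective gene: the high-expression group survives better at 5y
  tum <- which(s$cohort$cohort == "tumor")
  v <- s$cohort$values["HIT_01", sv$sample_id]
  grp <- ifelse(v > median(v), "high", "low")
  tt <- pmin(sv$time_days, 1826); ev <- ifelse(sv$time_days > 1826, 0L, sv$event)
  km <- km_curve(tt, ev, grp)
  s_at <- function(g) min(km$survival[km$group == g])
  expect_gt(s_at("high"), s_at("low"))

  flat <- s$cohort
  flat$values["HIT_01", ] <- 7
  expect_error(median_split_survival(flat, sv, "HIT_01"), "constant")
  expect_error(median_split_survival(s$cohort, sv, "NOPE"), "NOPE")
})

test_that("screen_protective retains planted hits and flags broken genes", {
  s <- quick_sim(seed = 41)
  sv <- simulate_survival(s$cfg, s$cohort, s$truth)
  tum_f <- which(s$cohort$cohort == "tumor" & s$cohort$sex == "female")
  co <- s$cohort[, tum_f]
  co$values["BG_0001", ] <- 5 # constant gene: non-identifiable
  scr <- screen_protective(co, sv,
                           genes = c(s$truth$planted_hits, "DECOY_S4_001",
                                     "BG_0001"))
  expect_true(all(s$truth$planted_hits %in% scr$retained))
  expect_false("DECOY_S4_001" %in% scr$retained)
  expect_false("BG_0001" %in% scr$retained)
  expect_match(scr$fits$error[scr$fits$gene_id == "BG_0001"], "constant")
  expect_error(screen_protective(co[, 1:5], sv), "fewer than 10")
})
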