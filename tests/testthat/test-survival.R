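sim_records <- function(n, beta = 0, seed = 1, horizon = Inf) {
  set.seed(seed)
  z <- rnorm(n)
  t <- rexp(n, 0.3 * exp(beta * z))
  data.frame(
    survival_time_years = pmin(t, horizon),
    event = t <= horizon,
    z = z,
    noise = rnorm(n)
  )
}

test_that("covariate standardisation freezes training statistics", {
  set.seed(1)
  tr <- data.frame(a = rnorm(200, 5, 3), b = runif(200))
  st <- standardize_covariates(tr, c("a", "b"))
  expect_lt(max(abs(colMeans(st[c("a", "b")]))), 1e-10)
  expect_lt(max(abs(vapply(st[c("a", "b")], sd, numeric(1)) - 1)), 1e-10)

  sc <- attr(st, "scaling")
  va <- data.frame(a = tr$a + 3, b = tr$b) # shifted by one training SD
  sv <- standardize_covariates(va, stats = sc)
  expect_equal(mean(sv$a) - mean(st$a), 3 / sc$sd[sc$covariate == "a"], tolerance = 1e-10)

  # restandardising standardised data is a no-op
  st2 <- standardize_covariates(as.data.frame(st[c("a", "b")]), c("a", "b"))
  expect_equal(st2$a, st$a, tolerance = 1e-10)

  tr$const <- 1
  expect_warning(standardize_covariates(tr, c("a", "const")), "zero-SD")
})

test_that("the concordance index equals pairwise enumeration", {
  expect_equal(concordance_index(c(3, 1, 2), c(1, 2, 3), c(TRUE, TRUE, TRUE)), 2 / 3)
  expect_equal(concordance_index(3:1, 1:3, rep(TRUE, 3)), 1.0)
  expect_equal(concordance_index(rep(1, 10), 1:10, rep(TRUE, 10)), 0.5)
  expect_true(is.na(concordance_index(1, 5, TRUE)))

  set.seed(2)
  for (i in 1:30) {
    n <- sample(5:50, 1)
    t <- sample(1:20, n, replace = TRUE)
    e <- rbinom(n, 1, 0.6) == 1
    r <- sample(1:8, n, replace = TRUE)
    if (!any(e)) next
    expect_equal(concordance_index(r, t, e), brute_force_cindex(r, t, e))
  }
})

test_that("Cox fits recover parameters and satisfy the AIC identity", {
  d <- sim_records(2000, beta = 0, seed = 3)
  g <- rep(0:1, 1000)
  d$survival_time_years <- rexp(2000, 0.3 * exp(log(2) * g))
  d$event <- TRUE
  d$grp <- g
  fit <- cox_fit(d, "grp")
  expect_lt(abs(fit$coefficients[["grp"]] - log(2)), 0.1)
  expect_equal(fit$aic, 2 * fit$n_params - 2 * fit$loglik)
  expect_equal(fit$aic, stats::AIC(fit$fit), tolerance = 1e-9)
  expect_equal(unname(fit$hazard_ratios), unname(exp(fit$coefficients)), tolerance = 1e-10)

  # doubling every record leaves the estimate essentially unchanged (the
  # duplicate event times only enter through the Efron tie correction)
  fit2 <- cox_fit(rbind(d, d), "grp")
  expect_equal(fit2$coefficients, fit$coefficients, tolerance = 1e-2)

  # a covariate independent of outcome stays within 2 SE in most runs
  hits <- vapply(1:20, function(s) {
    ds <- sim_records(300, beta = 0, seed = 400 + s)
    f <- cox_fit(ds, "noise")
    abs(f$coefficients[[1]]) < 2 * sqrt(f$fit$var[1, 1])
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(cox_fit(transform(d, k = 1), "k"), "constant")
})

test_that("likelihood-ratio tests compare nested models correctly", {
  d <- sim_records(500, beta = 0.8, seed = 5)
  base <- cox_fit(d, "z")
  full <- cox_fit(d, c("z", "noise"))
  expect_equal(likelihood_ratio_test(base, base)$p, 1)
  lrt <- likelihood_ratio_test(base, full)
  expect_equal(lrt$df, 1)
  expect_gt(lrt$p, 0.001)
  expect_error(likelihood_ratio_test(full, base), "not nested")

  # power: a strong covariate is detected in nearly every run
  pvals <- vapply(1:20, function(s) {
    ds <- sim_records(500, beta = log(3), seed = 600 + s)
    likelihood_ratio_test(cox_fit(ds, "noise"), cox_fit(ds, c("noise", "z")))$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.001), 0.95)
})

test_that("Kaplan-Meier and the log-rank test behave at the extremes", {
  set.seed(6)
  t <- rexp(100)
  # duplicated groups: no difference
  km0 <- km_logrank(c(t, t), rep(TRUE, 200), rep(c("a", "b"), each = 100))
  expect_lt(km0$chisq, 1e-10)
  expect_equal(km0$p, 1, tolerance = 1e-8)

  # without censoring the KM estimate is the empirical survival function
  sf <- survival::survfit(survival::Surv(t, rep(TRUE, 100)) ~ 1)
  emp <- vapply(sf$time, function(u) mean(t > u), numeric(1))
  expect_equal(sf$surv, emp, tolerance = 1e-12)

  # power at HR = 3
  p3 <- vapply(1:20, function(s) {
    set.seed(700 + s)
    g <- rep(0:1, each = 200)
    tt <- rexp(400, 0.3 * exp(log(3) * g))
    km_logrank(tt, rep(TRUE, 400), g)$p
  }, numeric(1))
  expect_gte(mean(p3 < 0.001), 0.95)

  expect_error(km_logrank(t, rep(TRUE, 100), rep("a", 100)), "two")
})

test_that("median-threshold grouping splits on the reference median", {
  p <- c(0.1, 0.4, 0.6, 0.9)
  g <- median_risk_grouping(p, p)
  expect_identical(as.character(g), c("low", "low", "high", "high"))
  expect_lte(abs(sum(g == "high") - sum(g == "low")), 1)
  # monotone transforms preserve the grouping
  g2 <- median_risk_grouping(stats::plogis(10 * p), stats::plogis(10 * p))
  expect_identical(g, g2)
  expect_error(median_risk_grouping(rep(0.5, 4), p), "degenerate")
})

test_that("horizon AUC matches pair enumeration and handles exclusions", {
  sc <- c(0.9, 0.8, 0.7, 0.6, 0.55, 0.5, 0.4, 0.3, 0.2, 0.1)
  tm <- c(0.5, 0.2, 2.0, 0.8, 3.0, 1.5, 0.9, 4.0, 2.5, 5.0)
  ev <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  r <- roc_auc_1yr(sc, tm, ev)
  pos <- ev & tm <= 1
  neg <- tm >= 1
  keep <- pos | neg
  expect_equal(r$auc, brute_force_auc(sc[keep], pos[keep]))
  expect_equal(r$n_excluded, sum(!keep))
  # censored before one year without an event is excluded
  expect_equal(r$n_excluded, sum(!ev & tm < 1))

  expect_equal(roc_auc_1yr(c(1, 2, 3, 4), c(0.5, 0.6, 2, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 0)
  expect_equal(roc_auc_1yr(c(4, 3, 2, 1), c(0.5, 0.6, 2, 3), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)

  set.seed(8)
  r0 <- roc_auc_1yr(rnorm(1000), rexp(1000, 0.3), rep(TRUE, 1000))
  expect_gt(r0$auc, 0.45)
  expect_lt(r0$auc, 0.55)
})

test_that("Schoenfeld diagnostics flag time-varying effects", {
  d <- sim_records(400, beta = 0.7, seed = 9)
  fit <- cox_fit(d, c("z", "noise"))
  ph <- schoenfeld_ph_check(fit)
  expect_true(all(c("z", "noise") %in% ph$covariate))
  expect_true(all(ph$p >= 0 & ph$p <= 1))
  # raw Schoenfeld residuals sum to ~0 per covariate
  rs <- colSums(stats::resid(fit$fit, type = "schoenfeld"))
  expect_lt(max(abs(rs)), 1e-6)

  # a sign-flipping effect violates proportional hazards detectably
  hits <- vapply(1:10, function(s) {
    set.seed(900 + s)
    n <- 500
    z <- rnorm(n)
    # piecewise hazard: covariate effect +1 before t0, -1 after
    t0 <- 0.5
    t1 <- rexp(n, 0.9 * exp(z))
    t <- ifelse(t1 <= t0, t1, t0 + rexp(n, 0.9 * exp(-z)))
    dd <- data.frame(survival_time_years = t, event = TRUE, z = z)
    f <- cox_fit(dd, "z")
    schoenfeld_ph_check(f)$p[1] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("the model comparison table orders models sensibly", {
  d <- sim_records(400, beta = 1, seed = 10)
  base <- cox_fit(d, "noise")
  full <- cox_fit(d, c("noise", "z"))
  tab <- model_comparison_table(list(base = base, full = full),
    baseline = "base", n_boot = 200, seed = 11
  )
  expect_equal(tab$lrt_p_vs_baseline[1], 1)
  expect_lt(tab$lrt_p_vs_baseline[2], 0.05)
  expect_gt(tab$c_index[2], tab$c_index[1])
  expect_lt(tab$aic[2], tab$aic[1])
  # bootstrap CI brackets the point estimate
  expect_true(all(tab$c_lower <= tab$c_index & tab$c_index <= tab$c_upper))

  # baseline against itself: identical rows
  tab2 <- model_comparison_table(list(a = base, b = base), baseline = "a", n_boot = 50)
  expect_equal(tab2$c_index[1], tab2$c_index[2])
  expect_equal(tab2$aic[1], tab2$aic[2])
  expect_equal(tab2$lrt_p_vs_baseline[2], 1)

  d2 <- d[1:300, ]
  other <- cox_fit(d2, "z")
  expect_error(
    model_comparison_table(list(a = base, b = other), baseline = "a", n_boot = 10),
    "different records"
  )
})
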