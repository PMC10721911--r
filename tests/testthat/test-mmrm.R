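test_that("the analysis dataset derives changes, weights and exclusions", {
  totals <- list(
    c(32, 30, 24, 18), # change -6, -12
    c(28, 28, NA, 20), # change at week 8 only
    c(30, 30, NA, NA) # no post-baseline -> dropped
  )
  data <- make_long_data(totals, arms = c("placebo", "active", "active"))
  long <- prepare_long_dataset(data)
  expect_equal(attr(long, "n_dropped"), 1)
  s1 <- long[long$subject_id == "S001", ]
  expect_equal(s1$change, c(-6, -12))
  expect_equal(s1$baseline, c(30, 30))
  expect_true(all(long$weight == 1))

  sc <- pswtrial:::propensity_scores(
    c("S001", "S002"), c("placebo", "active"), c(0.5, 0.25)
  )
  long_w <- prepare_long_dataset(data, sc)
  expect_equal(unique(long_w$weight[long_w$subject_id == "S002"]),
    sc$w[2])
  # ITT completeness: a retained subject without a score is an error
  sc_partial <- pswtrial:::propensity_scores("S001", "placebo", 0.5)
  expect_error(prepare_long_dataset(data, sc_partial), "full coverage")
})

test_that("single-visit weighted fit equals closed-form weighted ANCOVA", {
  for (seed in c(1, 2)) {
    long <- make_ancova_data(n = 30, seed = seed, n_arms = 3)
    fit <- fit_mmrm(long)
    # oracle: weighted least squares on the same design, placebo reference
    long$arm <- relevel(factor(long$arm), "placebo")
    lmfit <- lm(change ~ baseline + arm, data = long, weights = weight)
    te_lm <- -coef(lmfit)[c("armarm1", "armarm2")]
    cmp <- treatment_effects(fit, 8)
    expect_equal(cmp$te, unname(te_lm), tolerance = 1e-8)
    se_lm <- summary(lmfit)$coefficients[c("armarm1", "armarm2"), 2]
    expect_equal(cmp$std_err, unname(se_lm), tolerance = 1e-8)
    expect_equal(cmp$df, rep(nrow(long) - 4, 2), tolerance = 1e-4)
  }
})

test_that("weight rescaling leaves every reported quantity unchanged", {
  long <- make_ancova_data(n = 25, seed = 3)
  long10 <- long
  long10$weight <- long10$weight * 10
  f1 <- treatment_effects(fit_mmrm(long), 8)
  f10 <- treatment_effects(fit_mmrm(long10), 8)
  expect_equal(f1$te, f10$te, tolerance = 1e-8)
  expect_equal(f1$std_err, f10$std_err, tolerance = 1e-8)
  expect_equal(f1$pooled_sd, f10$pooled_sd, tolerance = 1e-8)
  expect_equal(f1$effect_size, f10$effect_size, tolerance = 1e-8)
  expect_equal(f1$p_adjusted, f10$p_adjusted, tolerance = 1e-8)
})

test_that("unit weights reproduce the reference analysis bit for bit", {
  d <- small_design()
  trial <- generate_trial(d, scale_definition("MADRS"), 21)
  ids <- unique(trial$data$subject_id)
  sc <- pswtrial:::propensity_scores(
    ids, trial$truth$arm[match(ids, trial$truth$subject_id)],
    rep(0.5, length(ids))
  )
  ref <- fit_mmrm(prepare_long_dataset(trial$data))
  wt <- fit_mmrm(prepare_long_dataset(trial$data, sc))
  expect_identical(ref$beta, wt$beta)
  expect_identical(ref$Sigma, wt$Sigma)
})

test_that("LS means are translation-equivariant and match raw means when balanced", {
  d <- small_design(dropout_rate = 0)
  trial <- generate_trial(d, scale_definition("MADRS"), 31)
  long <- prepare_long_dataset(trial$data)
  fit <- fit_mmrm(long)
  shifted <- long
  shifted$change <- shifted$change + 5
  fit_s <- fit_mmrm(shifted)
  lm0 <- ls_means(fit)
  lm5 <- ls_means(fit_s)
  expect_equal(lm5$lsmean, lm0$lsmean + 5, tolerance = 1e-6)
  expect_equal(
    treatment_effects(fit_s, 6)$te, treatment_effects(fit, 6)$te,
    tolerance = 1e-6
  )
  # shape contract: arms x visits rows
  expect_equal(nrow(lm0), length(fit$arms) * length(fit$visits))

  # balanced complete data with identical baseline sets across arms:
  # LS means collapse to raw arm-by-visit means
  base_vals <- rep(c(24, 26, 28, 30), 5)
  totals <- lapply(seq_len(40), function(i) {
    b <- base_vals[(i - 1) %% 20 + 1]
    c(b, b, b - 3 - (i > 20), b - 6 - 2 * (i > 20))
  })
  dat <- make_long_data(totals, arms = rep(c("placebo", "active"), each = 20))
  fitb <- fit_mmrm(prepare_long_dataset(dat))
  lsb <- ls_means(fitb, visits = 8)
  raw <- tapply(
    dat$total_score[dat$visit_week == 8] - base_vals[((seq_len(40) - 1) %% 20 + 1)],
    rep(c("placebo", "active"), each = 20), mean
  )
  expect_equal(lsb$lsmean, as.numeric(raw[lsb$arm]), tolerance = 1e-6)
})

test_that("identical arms give a zero treatment effect", {
  totals <- lapply(1:20, function(i) {
    b <- 24 + (i - 1) %% 10
    c(b + 1, b, b - 4, b - 7)
  })
  # same response vectors in both arms
  dat <- make_long_data(c(totals, totals), arms = rep(c("placebo", "active"), each = 20))
  fit <- fit_mmrm(prepare_long_dataset(dat))
  expect_equal(treatment_effects(fit, 8)$te, 0, tolerance = 1e-8)
})

test_that("REML objective is a local minimum against random perturbations", {
  d <- small_design()
  trial <- generate_trial(d, scale_definition("MADRS"), 41)
  long <- prepare_long_dataset(trial$data)
  fit <- fit_mmrm(long)
  T <- length(fit$visits)
  p <- fit$p
  obj_hat <- pswtrial:::mmrm_objective(fit$theta, fit$patterns, T, p)
  set.seed(99)
  worse <- vapply(1:50, function(i) {
    pswtrial:::mmrm_objective(
      fit$theta + rnorm(length(fit$theta), 0, 0.05 * (1 + abs(fit$theta))),
      fit$patterns, T, p
    )
  }, numeric(1))
  expect_true(all(worse >= obj_hat - 1e-6))
})

test_that("the unweighted fit agrees with generalized least squares (nlme)", {
  d <- small_design(dropout_rate = 0)
  trial <- generate_trial(d, scale_definition("MADRS"), 51)
  long <- prepare_long_dataset(trial$data)
  fit <- fit_mmrm(long)
  long$visit_f <- factor(long$visit_week)
  long$vidx <- as.integer(long$visit_f)
  gls_fit <- nlme::gls(
    change ~ 0 + visit_f + visit_f:baseline + visit_f:arm,
    data = long,
    correlation = nlme::corSymm(form = ~ vidx | subject_id),
    weights = nlme::varIdent(form = ~ 1 | visit_f),
    method = "REML", control = nlme::glsControl(tolerance = 1e-8)
  )
  # same EOS contrast: gls codes the placebo dummy against the active
  # reference, so its week-6 arm coefficient is placebo minus active = TE
  cf <- coef(gls_fit)
  te_gls <- unname(cf[grepl("visit_f6", names(cf)) & grepl("arm", names(cf))])
  expect_equal(treatment_effects(fit, 6)$te, te_gls, tolerance = 1e-4)
  # fitted covariance matches
  v_gls <- nlme::getVarCov(gls_fit)
  expect_equal(unclass(fit$Sigma), unclass(v_gls),
    tolerance = 1e-3, ignore_attr = TRUE
  )
})

test_that("Tukey adjustment matches quadrature of the studentized-range law", {
  # k = 2 reduces to the plain two-sided t-test (ptukey quadrature ~1e-8)
  expect_equal(tukey_adjust(2.1, 50, 2), 2 * pt(-2.1, 50), tolerance = 1e-7)
  # monotone: adjusted never below unadjusted
  for (tval in c(0.5, 1.5, 2.5, 3.5)) {
    for (k in 2:5) {
      expect_gte(tukey_adjust(tval, 80, k) + 1e-8, 2 * pt(-tval, 80))
    }
  }
  # independent quadrature oracle
  expect_equal(
    tukey_adjust(2.5, 100, 4),
    tukey_p_quadrature(sqrt(2) * 2.5, 4, 100),
    tolerance = 1e-4
  )
})

test_that("effect size reproduces the ratio convention", {
  expect_equal(effect_size(0, 5), 0)
  expect_equal(effect_size(-3, 6), 0.5)
  expect_error(effect_size(1, 0), "positive")
})

test_that("empirical covariance widens weighted standard errors", {
  set.seed(12)
  long <- make_ancova_data(n = 60, seed = 8, weights = runif(120, 0.1, 4))
  fit_m <- fit_mmrm(long, vcov_method = "model")
  fit_e <- fit_mmrm(long, vcov_method = "empirical")
  expect_equal(fit_m$beta, fit_e$beta) # point estimates unaffected
  # weights are noise here, so the sandwich SE should exceed the model SE
  expect_gt(
    treatment_effects(fit_e, 8)$std_err,
    treatment_effects(fit_m, 8)$std_err
  )
})
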