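test_that("exact noncentral-t sizing reproduces the textbook cases", {
  expect_equal(two_sample_n(3, 7.5, 0.80, 0.05), 100)
  expect_equal(two_sample_n(0.5, 1, 0.80, 0.05), 64)
  # returned n is minimal: power holds at n, not at n - 1
  for (n_d in list(c(3, 7.5), c(0.5, 1), c(2, 6))) {
    n <- two_sample_n(n_d[1], n_d[2])
    expect_gte(two_sample_power(n, n_d[1], n_d[2]), 0.80)
    expect_lt(two_sample_power(n - 1, n_d[1], n_d[2]), 0.80)
  }
})

test_that("required n is monotone in effect, power and dispersion", {
  deltas <- c(2, 3, 4, 6)
  ns <- vapply(deltas, two_sample_n, numeric(1), sd = 7.5)
  expect_true(all(diff(ns) < 0))
  powers <- c(0.7, 0.8, 0.9)
  np <- vapply(powers, function(p) two_sample_n(3, 7.5, power = p), numeric(1))
  expect_true(all(diff(np) > 0))
  sds <- c(6, 7.5, 9)
  nsd <- vapply(sds, function(s) two_sample_n(3, s), numeric(1))
  expect_true(all(diff(nsd) > 0))
  alphas <- c(0.01, 0.05, 0.1)
  na <- vapply(alphas, function(a) two_sample_n(3, 7.5, alpha = a), numeric(1))
  expect_true(all(diff(na) < 0))
})

test_that("truncated Hochberg interpolates between Hochberg and Bonferroni", {
  # gamma = 1: Hochberg step-up; both p <= alpha
  expect_equal(truncated_hochberg(c(0.03, 0.04), gamma = 1), c(TRUE, TRUE))
  # gamma = 0: Bonferroni; min p > alpha/2
  expect_equal(truncated_hochberg(c(0.03, 0.04), gamma = 0), c(FALSE, FALSE))
  expect_equal(truncated_hochberg(c(0.02, 0.04), gamma = 0), c(TRUE, FALSE))
  # gamma = 0.9: c_2 = (0.9 + 0.05) * 0.05 = 0.0475
  expect_equal(truncated_hochberg(c(0.02, 0.046), gamma = 0.9), c(TRUE, TRUE))
  expect_equal(truncated_hochberg(c(0.02, 0.048), gamma = 0.9), c(TRUE, FALSE))
  expect_equal(truncated_hochberg(numeric(0)), logical(0))
  expect_error(truncated_hochberg(c(0.5, 1.2)), "0, 1")
})

test_that("rejections are monotone in gamma and closed downward in p", {
  set.seed(14)
  for (r in 1:30) {
    m <- sample(2:6, 1)
    p <- round(runif(m, 0, 0.2), 3)
    gammas <- c(0, 0.3, 0.6, 0.9, 1)
    rej <- vapply(gammas, function(g) sum(truncated_hochberg(p, g)), numeric(1))
    expect_true(all(diff(rej) >= 0))
    # closed downward: if p_i rejected, every smaller p is rejected
    r9 <- truncated_hochberg(p, 0.9)
    if (any(r9)) expect_true(all(r9[p <= max(p[r9])]))
  }
})

test_that("power simulation behaves at the null and at large effects", {
  null_sim <- hochberg_power_sim(50, 0, gamma = 0.9, n_sims = 20000, seed = 3)
  expect_lte(null_sim$power_at_least_one,
    0.05 + 3 * null_sim$mc_se_at_least_one + 3 * 0.0016)
  big <- hochberg_power_sim(93, 2.0, gamma = 0.9, n_sims = 2000, seed = 4)
  expect_gt(big$power_both, 0.999)
  # reproducibility
  s1 <- hochberg_power_sim(30, 0.4, n_sims = 5000, seed = 9)
  s2 <- hochberg_power_sim(30, 0.4, n_sims = 5000, seed = 9)
  expect_identical(s1, s2)
})

test_that("simulated single-comparison power matches the noncentral-t closed form", {
  sim <- hochberg_power_sim(93, 0.44, gamma = 0.9, n_sims = 40000, seed = 5)
  exact <- two_sample_power(93, 0.44, 1, 0.05)
  mc_se <- sqrt(exact * (1 - exact) / 40000)
  expect_lt(abs(sim$power_per_comparison_unadjusted - exact), 3 * mc_se)
})
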