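#' Two-sample sample size from exact noncentral-t power
#'
#' Smallest per-group n such that the two-sided two-sample t-test at level
#' `alpha` attains the target power for a mean difference `delta` with
#' common SD `sd` (the fractional noncentral-t solution rounded up). A
#' standardized effect can be given directly via `delta = d, sd = 1`.
#'
#' @param delta mean difference in outcome units.
#' @param sd common standard deviation.
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @return integer n per group.
#' @examples
#' two_sample_n(3, 7.5) # 100
#' @export
two_sample_n <- function(delta, sd = 1, power = 0.80, alpha = 0.05) {
  stopifnot(sd > 0, power > 0, power < 1, alpha > 0, alpha < 1, delta != 0)
  frac <- stats::power.t.test(
    delta = delta, sd = sd, power = power, sig.level = alpha,
    type = "two.sample", alternative = "two.sided"
  )$n
  ceiling(frac - 1e-9)
}

#' @rdname two_sample_n
#' @param n per-group sample size.
#' @return `two_sample_power()`: exact noncentral-t power.
#' @export
two_sample_power <- function(n, delta, sd = 1, alpha = 0.05) {
  stats::power.t.test(
    n = n, delta = delta, sd = sd, sig.level = alpha,
    type = "two.sample", alternative = "two.sided"
  )$power
}

#' Truncated Hochberg step-up procedure
#'
#' Step-up multiple testing over `m` hypotheses with critical constants
#' `c_i = (gamma / (m - i + 1) + (1 - gamma) / m) * alpha` for the i-th
#' smallest p-value: `gamma = 1` is the Hochberg procedure, `gamma = 0` is
#' Bonferroni, intermediate `gamma` interpolates (the truncated family used
#' in gatekeeping designs).
#'
#' @param p vector of p-values in \[0, 1\].
#' @param gamma truncation parameter in \[0, 1\].
#' @param alpha global significance level.
#' @return logical vector (same order as `p`): `TRUE` = rejected.
#' @examples
#' truncated_hochberg(c(0.02, 0.046), gamma = 0.9) # both TRUE (c_2 = 0.0475)
#' @export
truncated_hochberg <- function(p, gamma = 0.9, alpha = 0.05) {
  stopifnot(gamma >= 0, gamma <= 1, alpha > 0, alpha < 1)
  m <- length(p)
  if (m == 0) return(logical(0))
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  ord <- order(p)
  crit <- (gamma / (m - seq_len(m) + 1) + (1 - gamma) / m) * alpha
  ok <- p[ord] <= crit
  reject <- logical(m)
  if (any(ok)) {
    i_star <- max(which(ok))
    reject[ord[seq_len(i_star)]] <- TRUE
  }
  reject
}

#' Simulated power of the truncated Hochberg procedure in a three-arm trial
#'
#' Simulates a trial with one shared control arm and two active arms, both
#' shifted by the standardized effect `d`; per replicate, computes the two
#' pooled-variance two-sided t-tests of active versus control and applies
#' [truncated_hochberg()]. Reports the probability of rejecting at least one
#' comparison and of rejecting both, with binomial Monte-Carlo standard
#' errors. Fully vectorized; replicates are processed in chunks to bound
#' memory.
#'
#' @param n_per_arm subjects per arm.
#' @param d true standardized effect of both active arms.
#' @param gamma truncation parameter.
#' @param alpha global two-sided level.
#' @param n_sims number of simulated trials.
#' @param seed integer seed.
#' @param chunk replicates per vectorized block.
#' @return list with `power_at_least_one`, `power_both`,
#'   `power_per_comparison_unadjusted` (single comparison at the unadjusted
#'   two-sided `alpha`, for checking against the noncentral-t closed form),
#'   the Monte-Carlo standard errors, and `n_sims`.
#' @export
hochberg_power_sim <- function(n_per_arm, d, gamma = 0.9, alpha = 0.05,
                               n_sims = 100000, seed = 1, chunk = 10000) {
  stopifnot(n_per_arm >= 2, n_sims >= 1)
  n <- n_per_arm
  df <- 2 * n - 2
  with_seed(seed, {
    n_one <- 0
    n_both <- 0
    n_unadj <- 0
    done <- 0
    while (done < n_sims) {
      b <- min(chunk, n_sims - done)
      x0 <- matrix(stats::rnorm(n * b), n)
      x1 <- matrix(stats::rnorm(n * b, mean = d), n)
      x2 <- matrix(stats::rnorm(n * b, mean = d), n)
      m0 <- colMeans(x0)
      m1 <- colMeans(x1)
      m2 <- colMeans(x2)
      ss0 <- colSums(x0^2) - n * m0^2
      ss1 <- colSums(x1^2) - n * m1^2
      ss2 <- colSums(x2^2) - n * m2^2
      t1 <- (m1 - m0) / sqrt((ss0 + ss1) / df * 2 / n)
      t2 <- (m2 - m0) / sqrt((ss0 + ss2) / df * 2 / n)
      p1 <- 2 * stats::pt(-abs(t1), df)
      p2 <- 2 * stats::pt(-abs(t2), df)
      # truncated Hochberg with m = 2, vectorized over replicates
      c_hi <- (gamma / 1 + (1 - gamma) / 2) * alpha # largest p
      c_lo <- (gamma / 2 + (1 - gamma) / 2) * alpha # smallest p
      both <- pmax(p1, p2) <= c_hi
      one <- both | (pmin(p1, p2) <= c_lo)
      n_one <- n_one + sum(one)
      n_both <- n_both + sum(both)
      n_unadj <- n_unadj + sum(p1 <= alpha)
      done <- done + b
    }
    p_one <- n_one / n_sims
    p_both <- n_both / n_sims
    list(
      power_at_least_one = p_one,
      power_both = p_both,
      power_per_comparison_unadjusted = n_unadj / n_sims,
      mc_se_at_least_one = sqrt(p_one * (1 - p_one) / n_sims),
      mc_se_both = sqrt(p_both * (1 - p_both) / n_sims),
      n_sims = n_sims
    )
  })
}

#' Trial-design report
#'
#' Convenience summary used by the command-line `design` subcommand: the
#' exact per-group sample size for a two-arm comparison and the simulated
#' truncated-Hochberg operating characteristics of a three-arm design.
#'
#' @param delta,sd,power,alpha sizing inputs (see [two_sample_n()]).
#' @param n_per_arm,d,gamma,n_sims,seed simulation inputs (see
#'   [hochberg_power_sim()]).
#' @return data frame of labeled design quantities.
#' @export
design_report <- function(delta = 3, sd = 7.5, power = 0.80, alpha = 0.05,
                          n_per_arm = 93, d = 0.44, gamma = 0.9,
                          n_sims = 100000, seed = 1) {
  n_req <- two_sample_n(delta, sd, power, alpha)
  sim <- hochberg_power_sim(n_per_arm, d, gamma, alpha, n_sims, seed)
  data.frame(
    quantity = c(
      "n_per_group_required", "power_at_n_required",
      "hochberg_power_at_least_one", "hochberg_power_both",
      "mc_se_at_least_one", "mc_se_both"
    ),
    value = c(
      n_req, two_sample_power(n_req, delta, sd, alpha),
      sim$power_at_least_one, sim$power_both,
      sim$mc_se_at_least_one, sim$mc_se_both
    )
  )
}
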