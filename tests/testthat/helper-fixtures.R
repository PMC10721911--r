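# fixtures built in code: tiny deterministic trials and hand-made tables

# minimal long-format table: one placebo + one active arm, explicit totals
# per visit; items are filled so that total_score = sum(items)
make_long_data <- function(totals, arms, visit_weeks = c(-1, 0, 4, 8),
                           n_items = 10) {
  rows <- list()
  for (i in seq_along(totals)) {
    for (v in seq_along(visit_weeks)) {
      tot <- totals[[i]][v]
      if (is.na(tot)) next
      items <- rep(tot %/% n_items, n_items)
      rem <- tot - sum(items)
      if (rem > 0) items[seq_len(rem)] <- items[seq_len(rem)] + 1
      row <- data.frame(
        subject_id = sprintf("S%03d", i), arm = arms[i],
        visit_week = visit_weeks[v], stringsAsFactors = FALSE
      )
      for (j in seq_len(n_items)) row[[sprintf("item_%02d", j)]] <- items[j]
      row$total_score <- sum(items)
      rows[[length(rows) + 1]] <- row
    }
  }
  do.call(rbind, rows)
}

# small two-arm design for fast simulator-based tests
small_design <- function(...) {
  defaults <- list(
    arms = c(placebo = 0, active = 5),
    n_per_arm = 40,
    visit_weeks = c(-1, 0, 2, 4, 6),
    eos_week = 6,
    dropout_rate = 0.1
  )
  do.call(trial_design, utils::modifyList(defaults, list(...)))
}

# single-visit complete weighted dataset for closed-form ANCOVA checks
make_ancova_data <- function(n = 40, seed = 1, n_arms = 2, weights = NULL) {
  set.seed(seed)
  arm <- rep(paste0("arm", seq_len(n_arms) - 1), each = n)
  arm[arm == "arm0"] <- "placebo"
  baseline <- round(rnorm(n * n_arms, 25, 4))
  change <- -5 - 2 * (arm != "placebo") + 0.3 * (baseline - 25) +
    rnorm(n * n_arms, 0, 3)
  w <- if (is.null(weights)) runif(n * n_arms, 0.2, 3) else weights
  structure(
    data.frame(
      subject_id = sprintf("S%03d", seq_len(n * n_arms)), arm = arm,
      visit_week = 8, change = change, baseline = baseline, weight = w,
      stringsAsFactors = FALSE
    ),
    n_dropped = 0L
  )
}

# independent studentized-range tail probability by direct quadrature:
# P(range of k studentized means > q) via the classical double integral
tukey_p_quadrature <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) {
      k * stats::dnorm(z) *
        (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  # density of s = chi_df / sqrt(df)
  dens_s <- function(s) {
    exp(
      log(2) + df / 2 * log(df / 2) - lgamma(df / 2) +
        (df - 1) * log(s) - df * s^2 / 2
    )
  }
  p_less <- stats::integrate(function(s) {
    vapply(s, function(si) dens_s(si) * inner(si), numeric(1))
  }, 0, Inf, rel.tol = 1e-8)$value
  1 - p_less
}
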