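#' Define a synthetic trial design
#'
#' Specifies a randomized, placebo-controlled trial whose subjects belong to
#' one of three latent placebo-propensity classes: `DminusPminus` (responds
#' to neither drug nor placebo), `DplusPplus` (responds to any treatment,
#' i.e. the placebo-type responders), and `DplusPminus` (responds to active
#' drug only — the informative class). The class mixture, together with the
#' outcome noise, determines the end-of-study placebo response rate and hence
#' how strongly an unweighted analysis is confounded.
#'
#' @param arms named numeric vector of true drug-specific end-of-study
#'   effects in total-score points; exactly one element must be named
#'   `placebo_label` and it must be 0. Only `DplusPminus` subjects in active
#'   arms receive the drug-specific effect; `DplusPplus` subjects improve by
#'   the non-specific (placebo-type) amount in every arm.
#' @param n_per_arm subjects randomized per arm (>= 2).
#' @param visit_weeks ordered numeric visit schedule, containing one
#'   screening week (< 0), baseline (0), and at least one post-baseline week.
#' @param eos_week the end-of-study (primary endpoint) week; must be one of
#'   the post-baseline `visit_weeks`.
#' @param class_mix named probabilities for
#'   `c(DminusPminus=, DplusPplus=, DplusPminus=)`; must sum to 1.
#' @param propensity_signal non-negative scalar: mean per-item screening-to-
#'   baseline improvement of `DplusPplus` subjects, in item-score points.
#'   0 means the pre-randomization item changes carry no information about
#'   the latent class.
#' @param noise_sd residual SD of the latent total score at each
#'   post-baseline visit (split between a subject-level and a visit-level
#'   component, see Details).
#' @param dropout_rate probability that a subject drops out before the last
#'   scheduled visit; dropout is monotone and never removes screening or
#'   baseline.
#' @param placebo_label arm label identifying placebo.
#' @param placebo_response_frac mean fractional end-of-study improvement of
#'   `DplusPplus` subjects (any arm).
#' @param nonspecific_frac mean fractional improvement of the other classes
#'   absent a drug effect (regression to the mean and rater drift).
#' @param item_delta_sd SD of the per-item pre-randomization change noise.
#' @param icc intra-subject correlation share of `noise_sd^2` carried by the
#'   subject-level component.
#' @param entry_severity mean screening total score; `NULL` uses the scale
#'   default ([default_entry_severity()]).
#' @param mnar if `TRUE`, `DminusPminus` subjects drop out at twice the
#'   hazard (a missing-not-at-random stress switch; default is monotone MAR).
#' @return an object of class `trial_design` (a validated list).
#' @seealso [generate_trial()], [design_preset()]
#' @export
trial_design <- function(arms,
                         n_per_arm,
                         visit_weeks,
                         eos_week,
                         class_mix = c(
                           DminusPminus = 0.25,
                           DplusPplus = 0.55,
                           DplusPminus = 0.20
                         ),
                         propensity_signal = 0.5,
                         noise_sd = 6,
                         dropout_rate = 0.15,
                         placebo_label = "placebo",
                         placebo_response_frac = 0.70,
                         nonspecific_frac = 0.10,
                         item_delta_sd = 1.0,
                         icc = 0.5,
                         entry_severity = NULL,
                         mnar = FALSE) {
  if (is.null(names(arms)) || any(!nzchar(names(arms)))) {
    stop("`arms` must be a named numeric vector of true effects")
  }
  if (sum(names(arms) == placebo_label) != 1L) {
    stop("exactly one arm must be labeled '", placebo_label, "'")
  }
  if (arms[[placebo_label]] != 0) {
    stop("the placebo arm must have a true drug-specific effect of 0")
  }
  if (n_per_arm < 2) stop("n_per_arm must be >= 2")
  visit_weeks <- sort(unique(as.numeric(visit_weeks)))
  if (sum(visit_weeks < 0) != 1L || !any(visit_weeks == 0)) {
    stop("visit_weeks must contain exactly one screening week (< 0) and baseline (0)")
  }
  post <- visit_weeks[visit_weeks > 0]
  if (length(post) < 1) stop("at least one post-baseline visit is required")
  if (!eos_week %in% post) {
    stop("eos_week must be one of the scheduled post-baseline visits")
  }
  classes <- c("DminusPminus", "DplusPplus", "DplusPminus")
  if (!setequal(names(class_mix), classes)) {
    stop("class_mix must be named DminusPminus, DplusPplus, DplusPminus")
  }
  class_mix <- class_mix[classes]
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-8) {
    stop("class_mix must be non-negative and sum to 1")
  }
  if (propensity_signal < 0) stop("propensity_signal must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(
    list(
      arms = arms, n_per_arm = as.integer(n_per_arm),
      visit_weeks = visit_weeks, eos_week = eos_week,
      class_mix = class_mix, propensity_signal = propensity_signal,
      noise_sd = noise_sd, dropout_rate = dropout_rate,
      placebo_label = placebo_label,
      placebo_response_frac = placebo_response_frac,
      nonspecific_frac = nonspecific_frac,
      item_delta_sd = item_delta_sd, icc = icc,
      entry_severity = entry_severity, mnar = mnar
    ),
    class = "trial_design"
  )
}

#' @export
print.trial_design <- function(x, ...) {
  cat(sprintf(
    "<trial_design> %d arms x %d subjects, visits %s (EOS week %g)\n",
    length(x$arms), x$n_per_arm,
    paste(x$visit_weeks, collapse = "/"), x$eos_week
  ))
  cat(sprintf(
    "  class mix: %s; signal %.2f; noise SD %.1f; dropout %.0f%%\n",
    paste(sprintf("%s=%.2f", names(x$class_mix), x$class_mix), collapse = " "),
    x$propensity_signal, x$noise_sd, 100 * x$dropout_rate
  ))
  invisible(x)
}

#' Ready-made trial designs
#'
#' Two presets mirroring common depression-trial layouts: `"hamd17_4arm"`,
#' a four-arm HAMD-17 trial (placebo, two inactive doses, one active
#' comparator) with end of study at week 8; and `"madrs_3arm"`, a three-arm
#' MADRS trial (placebo and two active doses) with end of study at week 6.
#' Both use a placebo-type responder (`DplusPplus`) majority, so the placebo
#' response rate is high enough to confound an unweighted analysis.
#'
#' Active-arm effects are scaled so that drug-only responders improve by
#' about 0.6 of a typical baseline in active arms — i.e. they respond about
#' as strongly as the placebo-type responders do (0.70 of baseline) — which
#' is what membership in the drug-responsive class means. In the four-arm
#' preset only the comparator arm is active (two inactive dose arms).
#'
#' @param name preset name.
#' @param n_per_arm subjects per arm.
#' @param ... overrides passed on to [trial_design()].
#' @return a list with elements `design` ([trial_design()]) and `scale`
#'   ([scale_definition()]).
#' @export
design_preset <- function(name = c("hamd17_4arm", "madrs_3arm"),
                          n_per_arm = 120, ...) {
  name <- match.arg(name)
  if (name == "hamd17_4arm") {
    args <- list(
      arms = c(placebo = 0, dose_low = 0, dose_high = 0, comparator = 13),
      n_per_arm = n_per_arm,
      visit_weeks = c(-1, 0, 1, 2, 4, 6, 8),
      eos_week = 8
    )
    scale <- scale_definition("HAMD17")
  } else {
    args <- list(
      arms = c(placebo = 0, dose_200 = 18, dose_400 = 18),
      n_per_arm = n_per_arm,
      visit_weeks = c(-1, 0, 1, 2, 4, 6),
      eos_week = 6
    )
    scale <- scale_definition("MADRS")
  }
  args <- utils::modifyList(args, list(...))
  list(design = do.call(trial_design, args), scale = scale)
}

# fraction of the full EOS improvement realized by a given week
# (concave time course: most of the change happens early, as in
# antidepressant trials)
improvement_fraction <- function(week, eos_week) {
  log1p(pmax(week, 0)) / log1p(eos_week)
}

# class x arm mean fractional improvement and drug-specific points at EOS
class_eos_improvement <- function(class, arm_effect, design) {
  frac <- ifelse(class == "DplusPplus",
    design$placebo_response_frac, design$nonspecific_frac
  )
  points <- ifelse(class == "DplusPminus", arm_effect, 0)
  list(frac = frac, points = points)
}

#' Generate a synthetic depression trial
#'
#' Simulates item-level rating-scale trajectories for every randomized
#' subject. Each subject draws a latent class from the design's mixture;
#' screening items are drawn from per-item binomials matched to the entry
#' severity; screening-to-baseline item changes are multivariate normal with
#' a class-dependent mean shift (scaled by `propensity_signal`) and are
#' clamp-rounded to the instrument bounds; post-baseline totals follow a
#' concave improvement curve whose end-of-study magnitude depends on class
#' and arm, plus correlated Gaussian noise, and are spread back over items
#' proportionally to the baseline item profile. Dropout is monotone and
#' never removes screening or baseline.
#'
#' @param design a [trial_design()].
#' @param scale a [scale_definition()].
#' @param seed integer seed; the same design, scale and seed reproduce the
#'   dataset exactly.
#' @return an object of class `psw_trial`: a list with
#'   \describe{
#'     \item{data}{long-format data frame, one row per subject x observed
#'       visit, with `subject_id`, `arm`, `visit_week`, `item_01..item_NN`,
#'       `total_score`.}
#'     \item{truth}{subject-level ground truth (`latent_class`,
#'       `true_propensity`) kept separate so the analysis pipeline never
#'       sees it.}
#'     \item{design, scale, seed}{the inputs.}
#'   }
#' @export
generate_trial <- function(design, scale, seed) {
  stopifnot(inherits(design, "trial_design"), inherits(scale, "scale_definition"))
  with_seed(seed, {
    arms <- names(design$arms)
    n <- design$n_per_arm * length(arms)
    arm <- rep(arms, each = design$n_per_arm)
    subject_id <- sprintf("S%04d", seq_len(n))
    classes <- names(design$class_mix)
    latent <- sample(classes, n, replace = TRUE, prob = design$class_mix)

    severity <- design$entry_severity %||% default_entry_severity(scale)
    q <- severity / scale$max_total
    n_items <- scale$n_items
    imax <- scale$item_max

    # screening items: independent binomials matched to entry severity
    scr <- sapply(imax, function(m) stats::rbinom(n, m, q))
    # pre-randomization change: class-shifted MVN deltas, clamp-rounded
    mu_delta <- ifelse(latent == "DplusPplus", -design$propensity_signal, 0)
    delta <- matrix(stats::rnorm(n * n_items, sd = design$item_delta_sd),
      n, n_items
    ) + mu_delta
    bsl <- clamp_round(scr + delta, 0, rep(imax, each = n))
    # the labeling denominator must be positive
    zero_b <- rowSums(bsl) == 0
    if (any(zero_b)) bsl[zero_b, 1] <- 1L
    baseline_total <- rowSums(bsl)

    eos <- class_eos_improvement(latent, design$arms[arm], design)
    delta_eos <- eos$frac * baseline_total + eos$points

    post <- design$visit_weeks[design$visit_weeks > 0]
    tpost <- length(post)
    sd_b <- design$noise_sd * sqrt(design$icc)
    sd_e <- design$noise_sd * sqrt(1 - design$icc)
    b_i <- stats::rnorm(n, sd = sd_b)

    # monotone dropout: per-visit hazard from the per-subject rate
    haz <- 1 - (1 - design$dropout_rate)^(1 / tpost)
    haz_i <- rep(haz, n)
    if (design$mnar) {
      haz_i <- ifelse(latent == "DminusPminus", pmin(2 * haz, 0.95), haz)
    }
    drop_u <- matrix(stats::runif(n * tpost), n, tpost)
    dropped <- drop_u < haz_i
    if (tpost > 1) {
      for (k in 2:tpost) dropped[, k] <- dropped[, k] | dropped[, k - 1]
    }

    rows <- vector("list", 2 + tpost)
    mk_row <- function(week, items) {
      df <- data.frame(
        subject_id = subject_id, arm = arm, visit_week = week,
        stringsAsFactors = FALSE
      )
      items <- as.data.frame(items)
      names(items) <- item_columns(scale)
      df <- cbind(df, items)
      df$total_score <- rowSums(items)
      df
    }
    rows[[1]] <- mk_row(design$visit_weeks[design$visit_weeks < 0], scr)
    rows[[2]] <- mk_row(0, bsl)
    for (k in seq_len(tpost)) {
      g <- improvement_fraction(post[k], design$eos_week)
      mu_t <- baseline_total - g * delta_eos
      y <- mu_t + g * b_i + stats::rnorm(n, sd = sd_e)
      y <- pmin(pmax(y, 0), scale$max_total)
      ratio <- y / baseline_total
      items_t <- clamp_round(bsl * ratio, 0, rep(imax, each = n))
      r <- mk_row(post[k], items_t)
      rows[[2 + k]] <- r[!dropped[, k], , drop = FALSE]
    }
    data <- do.call(rbind, rows)
    data <- data[order(data$subject_id, data$visit_week), ]
    rownames(data) <- NULL

    truth <- data.frame(
      subject_id = subject_id, arm = arm, latent_class = latent,
      baseline_total = baseline_total,
      true_propensity = true_propensity(baseline_total, latent, design),
      stringsAsFactors = FALSE
    )
    structure(
      list(data = data, truth = truth, design = design, scale = scale, seed = seed),
      class = "psw_trial"
    )
  })
}

#' @export
print.psw_trial <- function(x, ...) {
  cat(sprintf(
    "<psw_trial> %s, %d subjects in %d arms, %d rows (seed %d)\n",
    x$scale$name, nrow(x$truth), length(x$design$arms), nrow(x$data), x$seed
  ))
  invisible(x)
}

#' Generative probability of placebo response
#'
#' The probability, under the simulator's own generative model, that a
#' subject of the given latent class and baseline severity shows a >= 50
#' percent end-of-study improvement when assigned to placebo. On the latent
#' (pre-rounding) total-score scale the end-of-study value is
#' `B(1 - m) + e` with `e ~ N(0, noise_sd)`, so the probability is
#' `pnorm(B (m - 1/2) / noise_sd)` where `m` is the class's mean fractional
#' improvement. Used only as an oracle in parameter-recovery tests; the
#' analysis pipeline never sees it.
#'
#' @param baseline_total numeric vector of baseline total scores.
#' @param latent_class character vector of class labels.
#' @param design the generating [trial_design()].
#' @return numeric vector of probabilities.
#' @export
true_propensity <- function(baseline_total, latent_class, design) {
  m <- ifelse(latent_class == "DplusPplus",
    design$placebo_response_frac, design$nonspecific_frac
  )
  margin <- baseline_total * (m - 0.5)
  if (design$noise_sd == 0) {
    as.numeric(margin > 0)
  } else {
    stats::pnorm(margin / design$noise_sd)
  }
}

#' Write / read a simulated trial as CSV
#'
#' `write_trial()` writes the long-format observation table and the
#' subject-level truth table as two separate CSV files (`data.csv`,
#' `truth.csv`) so that an analysis reading `data.csv` cannot see the latent
#' class. `read_trial_data()` reads a long-format observation table.
#'
#' @param trial a [generate_trial()] result.
#' @param dir output directory (created if needed).
#' @return `write_trial()`: the paths, invisibly. `read_trial_data()`: a
#'   data frame.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "psw_trial"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    data = file.path(dir, "data.csv"),
    truth = file.path(dir, "truth.csv")
  )
  utils::write.csv(trial$data, paths["data"], row.names = FALSE)
  utils::write.csv(trial$truth, paths["truth"], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_trial
#' @param path path to a long-format observation CSV.
#' @export
read_trial_data <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
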