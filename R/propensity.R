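#' Build the item-change matrix
#'
#' Extracts, per subject, the signed per-item change between the two
#' pre-randomization visits (baseline minus screening by default) — the
#' predictor matrix of the propensity model. Subjects missing either visit
#' are excluded with a message and reported in an attribute.
#'
#' @param data long-format observation data frame (`subject_id`, `arm`,
#'   `visit_week`, `item_01..item_NN`).
#' @param scale a [scale_definition()].
#' @param direction `"baseline_minus_screening"` (default) or the reverse;
#'   a labeled constant rather than a hidden sign convention.
#' @return a numeric matrix with one row per subject (rownames =
#'   `subject_id`), one column per item; attributes `subject_ids`, `arm`,
#'   `n_excluded`, `excluded_ids`.
#' @export
item_delta_matrix <- function(data, scale,
                              direction = c(
                                "baseline_minus_screening",
                                "screening_minus_baseline"
                              )) {
  direction <- match.arg(direction)
  cols <- item_columns(scale)
  if (!all(cols %in% names(data))) stop("data lacks the ", scale$name, " item columns")
  scr <- data[data$visit_week < 0, c("subject_id", cols)]
  bsl <- data[data$visit_week == 0, c("subject_id", cols)]
  ids <- unique(data$subject_id)
  ok <- intersect(scr$subject_id, bsl$subject_id)
  excluded <- setdiff(ids, ok)
  if (length(excluded)) {
    message(
      length(excluded),
      " subject(s) lack screening or baseline and were excluded"
    )
  }
  scr <- scr[match(ok, scr$subject_id), cols, drop = FALSE]
  bsl <- bsl[match(ok, bsl$subject_id), cols, drop = FALSE]
  d <- as.matrix(bsl) - as.matrix(scr)
  if (direction == "screening_minus_baseline") d <- -d
  rownames(d) <- ok
  arm_of <- data$arm[match(ok, data$subject_id)]
  structure(d,
    subject_ids = ok, arm = arm_of,
    n_excluded = length(excluded), excluded_ids = excluded
  )
}

#' Split labeled placebo subjects into training and validation sets
#'
#' Random split stratified by responder label, with 75 percent of the
#' placebo arm (by default) reserved for model development and the rest for
#' held-out validation. Both response classes appear in both partitions
#' whenever the class sizes allow it.
#'
#' @param labels a [label_placebo_responders()] result.
#' @param fraction_train training fraction.
#' @param seed integer seed.
#' @return list with character vectors `train_ids` and `validation_ids`
#'   (disjoint, exhaustive).
#' @export
split_placebo <- function(labels, fraction_train = 0.75, seed = 1) {
  if (nrow(labels) < 8) stop("need at least 8 labeled placebo subjects")
  if (length(unique(labels$responder)) < 2) {
    stop("degenerate labels: both response classes are required to train")
  }
  idx <- with_seed(seed, stratified_sample(labels$responder, fraction_train))
  list(
    train_ids = labels$subject_id[idx],
    validation_ids = labels$subject_id[-idx]
  )
}

#' Area under the ROC curve (Mann-Whitney)
#'
#' Rank-based AUC: the probability that a randomly chosen responder scores
#' above a randomly chosen non-responder, with ties counted one half.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (1 = positive).
#' @return AUC in \[0, 1\].
#' @export
auc_mw <- function(scores, labels) {
  pos <- labels == 1
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Grid search over network architectures
#'
#' Evaluates each candidate architecture by stratified k-fold
#' cross-validated AUC on the training partition and returns the winner.
#' Ties are broken toward fewer total nodes, then fewer layers. Candidates
#' that fail to train on some fold are skipped with a warning.
#'
#' @param x training item-change matrix.
#' @param y binary responder labels.
#' @param grid list of [ann_spec()] candidates.
#' @param seed seed controlling fold assignment and fits.
#' @param k number of CV folds.
#' @return list with `best` (the winning [ann_spec()], its seed set from
#'   `seed`) and `results` (a data frame of per-candidate CV AUCs).
#' @export
grid_search_ann <- function(x, y, grid = default_ann_grid(), seed = 1, k = 5) {
  if (length(grid) == 0) stop("empty architecture grid")
  x <- as.matrix(x)
  if (length(grid) == 1) {
    # nothing to select: skip the cross-validation entirely
    best <- grid[[1]]
    best$seed <- derive_seed(seed, "final_fit")
    return(list(
      best = best,
      results = data.frame(
        candidate = 1L, layers = length(best$hidden),
        nodes = sum(best$hidden), cv_auc = NA_real_
      )
    ))
  }
  k <- min(k, min(table(y)))
  if (k < 2) stop("too few subjects in one class for cross-validation")
  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      ids <- which(y == cls)
      f[ids] <- sample(rep_len(seq_len(k), length(ids)))
    }
    f
  })
  res <- data.frame(
    candidate = seq_along(grid),
    layers = vapply(grid, function(g) length(g$hidden), 1L),
    nodes = vapply(grid, function(g) sum(g$hidden), 1L),
    cv_auc = NA_real_,
    p_spread = NA_real_
  )
  for (j in seq_along(grid)) {
    spec <- grid[[j]]
    spec$seed <- derive_seed(seed, "grid", j)
    aucs <- rep(NA_real_, k)
    p_oof <- rep(NA_real_, length(y))
    ok <- TRUE
    for (fold in seq_len(k)) {
      tr <- folds != fold
      fit <- tryCatch(suppressWarnings(ann_train(x[tr, , drop = FALSE], y[tr], spec)),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        ok <- FALSE
        break
      }
      p <- predict(fit, x[!tr, , drop = FALSE])
      p_oof[!tr] <- p
      aucs[fold] <- auc_mw(p, y[!tr])
    }
    if (ok) {
      res$cv_auc[j] <- mean(aucs)
      res$p_spread[j] <- diff(range(p_oof))
    } else {
      warning("grid candidate ", j, " failed to train and was skipped")
    }
  }
  if (all(is.na(res$cv_auc))) stop("every grid candidate failed to train")
  # a propensity model must express a probability *scale*, not just a
  # ranking: candidates whose out-of-fold probabilities are essentially
  # constant (a saturated local optimum of narrow nets) cannot produce
  # usable inverse-probability weights and are set aside unless nothing
  # else trained
  usable <- !is.na(res$cv_auc) & res$p_spread >= 0.05
  if (!any(usable)) usable <- !is.na(res$cv_auc)
  ord <- order(!usable, -res$cv_auc, res$nodes, res$layers)
  best_j <- ord[1]
  best <- grid[[best_j]]
  best$seed <- derive_seed(seed, "final_fit")
  list(best = best, results = res)
}

#' Default architecture grid
#'
#' One to three hidden layers with 1, 3, 5 or 7 nodes per layer (the same
#' width in every layer), matching the scale of networks selected in small
#' depression trials.
#'
#' @param decay L2 penalty shared by all candidates.
#' @return list of [ann_spec()] objects.
#' @export
default_ann_grid <- function(decay = 1e-3) {
  grid <- list()
  for (L in 1:3) {
    for (nodes in c(1, 3, 5, 7)) {
      grid[[length(grid) + 1]] <- ann_spec(hidden = rep(nodes, L), decay = decay)
    }
  }
  grid
}

#' Bootstrap ROC of a validated propensity model
#'
#' AUC on the held-out validation predictions, with a percentile 95 percent
#' confidence interval over stratified bootstrap resamples of the validation
#' set. The model is not refit per resample: predictions are resampled
#' (refitting can be supplied via `refit_fun` for sensitivity analysis).
#'
#' @param scores validation-set predicted probabilities.
#' @param labels validation-set binary labels (both classes required).
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @param refit_fun optional `function(idx)` returning resample scores from
#'   a model refit on the bootstrap indices.
#' @return an object of class `roc_result`: list with `auc`, `ci_lower`,
#'   `ci_upper`, `n_boot`, `level`.
#' @export
bootstrap_roc <- function(scores, labels, n_boot = 2000, seed = 1,
                          level = 0.95, refit_fun = NULL) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  if (length(pos) == 0 || length(neg) == 0) {
    stop("validation set must contain both classes")
  }
  auc <- auc_mw(scores, labels)
  boots <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(
        sample(pos, length(pos), replace = TRUE),
        sample(neg, length(neg), replace = TRUE)
      )
      if (is.null(refit_fun)) {
        auc_mw(scores[idx], labels[idx])
      } else {
        auc_mw(refit_fun(idx), labels[idx])
      }
    }, numeric(1))
  })
  qs <- stats::quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2),
    names = FALSE, type = 7
  )
  structure(
    list(
      auc = auc, ci_lower = qs[1], ci_upper = qs[2],
      n_boot = n_boot, level = level
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC %.3f, %g%% CI [%.3f, %.3f] (%d resamples)\n",
    x$auc, 100 * x$level, x$ci_lower, x$ci_upper, x$n_boot
  ))
  invisible(x)
}

#' Qualify a propensity model for use as an analysis weight
#'
#' The model passes only when the lower bootstrap confidence bound of the
#' validation AUC is strictly above the non-informative 0.5; a failed
#' validation blocks the weighted analysis (the reference analysis still
#' runs).
#'
#' @param roc a [bootstrap_roc()] result.
#' @return `TRUE` (pass) or `FALSE`.
#' @export
validate_model <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  isTRUE(roc$ci_lower > 0.5)
}

#' Predict propensity scores and analysis weights for all arms
#'
#' Applies the qualified model to the pre-randomization item changes of
#' every randomized subject (the working dataset) and converts the predicted
#' placebo-response probability `p` to a weight `1 / max(p, p_floor)`. The
#' floor keeps near-zero predictions from producing unstable weights;
#' optional renormalization scales weights to mean 1 (a pure rescaling that
#' leaves the weighted model fit unchanged).
#'
#' @param model a validated [ann_train()] fit.
#' @param deltas an [item_delta_matrix()] covering all arms.
#' @param p_floor probability floor for weighting (default 0.05); use 0 for
#'   raw inverse-probability weights.
#' @param renormalize scale weights to mean 1 (default `TRUE`).
#' @return an object of class `propensity_scores`: data frame with
#'   `subject_id`, `arm`, `p`, `w_raw`, `w`; attribute `p_floor`.
#' @export
predict_propensity <- function(model, deltas, p_floor = 0.05,
                               renormalize = TRUE) {
  p <- predict(model, deltas)
  propensity_scores(
    attr(deltas, "subject_ids"), attr(deltas, "arm"), p,
    p_floor = p_floor, renormalize = renormalize
  )
}

#' Load a persisted propensity model for use with a given scale
#'
#' Propensity models do not transfer across trials or instruments: the
#' individual propensity to respond to placebo is tied to the trial's own
#' population and conduct, so a model must be developed, qualified and
#' validated within each trial. This loader therefore refuses a model whose
#' stored instrument differs from the target scale unless the caller
#' explicitly accepts an unsafe transfer.
#'
#' @param path JSON artifact written by [ann_to_json()].
#' @param scale the target [scale_definition()].
#' @param allow_scale_mismatch set `TRUE` to override the refusal
#'   (explicitly unsafe).
#' @return a `psw_ann` model.
#' @export
load_propensity_model <- function(path, scale, allow_scale_mismatch = FALSE) {
  model <- ann_from_json(path)
  stored <- attr(model, "scale_name")
  if (!isTRUE(allow_scale_mismatch) &&
    (is.null(stored) || is.na(stored) || !identical(stored, scale$name))) {
    stop(
      "persisted model was developed for scale '", stored %||% "<unknown>",
      "', not '", scale$name, "'; propensity models are trial-specific ",
      "(set allow_scale_mismatch = TRUE to override)"
    )
  }
  model
}

#' Out-of-fold propensity predictions for the training subjects
#'
#' Refits the selected architecture on k-fold subsets of the training
#' partition (folds stratified by label) and predicts each training subject
#' from the fold model that did not see it. Used by the pipeline so that no
#' subject's analysis weight is a function of its own observed outcome — a
#' network flexible enough to fit the training labels would otherwise leak
#' placebo-arm outcomes into the placebo-arm weights and bias the weighted
#' treatment-effect estimate.
#'
#' @param x training item-change matrix (rownames = subject ids).
#' @param y binary responder labels.
#' @param spec the selected [ann_spec()].
#' @param seed integer seed (fold assignment and fold-model fits).
#' @param k number of folds (capped at the minority-class count).
#' @return named numeric vector of out-of-fold probabilities, one per row
#'   of `x`.
#' @export
crossfit_predictions <- function(x, y, spec, seed = 1, k = 5) {
  x <- as.matrix(x)
  k <- max(2, min(k, min(table(y))))
  fold <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in unique(y)) {
      ids <- which(y == cls)
      f[ids] <- sample(rep_len(seq_len(k), length(ids)))
    }
    f
  })
  p <- numeric(length(y))
  for (f in seq_len(k)) {
    spec_f <- spec
    spec_f$seed <- derive_seed(seed, "crossfit", f)
    fit <- ann_train(x[fold != f, , drop = FALSE], y[fold != f], spec_f)
    p[fold == f] <- predict(fit, x[fold == f, , drop = FALSE])
  }
  stats::setNames(p, rownames(x))
}

#' Convert propensity probabilities to analysis weights
#'
#' @param subject_id,arm,p parallel vectors of ids, arm labels and
#'   probabilities.
#' @param p_floor probability floor (see [predict_propensity()]).
#' @param renormalize scale weights to mean 1.
#' @return a `propensity_scores` data frame.
#' @keywords internal
propensity_scores <- function(subject_id, arm, p, p_floor = 0.05,
                              renormalize = TRUE) {
  w_raw <- 1 / pmax(p, p_floor)
  w <- if (renormalize) w_raw / mean(w_raw) else w_raw
  structure(
    data.frame(
      subject_id = subject_id, arm = arm, p = p, w_raw = w_raw, w = w,
      stringsAsFactors = FALSE
    ),
    class = c("propensity_scores", "data.frame"),
    p_floor = p_floor, renormalized = renormalize
  )
}

#' Binned propensity distribution by arm
#'
#' Proportion of each arm's subjects with predicted placebo-response
#' propensity in the bins \[0, 0.2), \[0.2, 0.4), \[0.4, 0.6), \[0.6, 0.8),
#' \[0.8, 1\] — the display used to compare the propensity balance across
#' arms.
#'
#' @param scores a [predict_propensity()] result (or any data frame with
#'   `arm` and `p`).
#' @return data frame with one row per arm and one column per bin;
#'   proportions sum to 1 within each row. Arms with no subjects are omitted
#'   with a warning.
#' @export
propensity_distribution <- function(scores) {
  if (nrow(scores) == 0) stop("no propensity scores")
  breaks <- c(0, 0.2, 0.4, 0.6, 0.8, 1)
  bin_labels <- c("[0,0.2)", "[0.2,0.4)", "[0.4,0.6)", "[0.6,0.8)", "[0.8,1]")
  arms <- unique(scores$arm)
  empty <- arms[!arms %in% scores$arm[!is.na(scores$p)]]
  if (length(empty)) warning("arm(s) with no scores omitted: ", paste(empty, collapse = ", "))
  out <- lapply(setdiff(arms, empty), function(a) {
    p <- scores$p[scores$arm == a & !is.na(scores$p)]
    bin <- findInterval(p, breaks, rightmost.closed = TRUE)
    props <- tabulate(bin, nbins = 5) / length(p)
    stats::setNames(
      data.frame(arm = a, t(props), n = length(p), check.names = FALSE),
      c("arm", bin_labels, "n")
    )
  })
  do.call(rbind, out)
}
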