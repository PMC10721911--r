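#' Percent change from baseline
#'
#' `100 * (baseline - eos) / baseline`: positive values are improvement
#' (score reduction). The denominator is the randomization-visit (week 0)
#' total, not screening.
#'
#' @param baseline_total baseline total score(s), must be > 0.
#' @param eos_total end-of-study total score(s).
#' @return percent reduction from baseline.
#' @examples
#' percent_change(30, 15) # 50
#' @export
percent_change <- function(baseline_total, eos_total) {
  if (any(baseline_total <= 0)) {
    stop("percent change is undefined for baseline total <= 0")
  }
  100 * (baseline_total - eos_total) / baseline_total
}

#' Label placebo-arm subjects as placebo responders
#'
#' A placebo-arm subject is a responder (label 1) when the end-of-study
#' total score shows a clinically relevant improvement of at least 50 percent
#' from baseline; otherwise 0. This binary label is the training target of
#' the propensity model. Subjects with no observation at the end-of-study
#' visit are excluded (no imputation) and counted.
#'
#' @param data long-format observation data frame with columns
#'   `subject_id`, `arm`, `visit_week`, `total_score`.
#' @param eos_week the end-of-study visit week.
#' @param placebo_label arm label identifying placebo.
#' @param threshold percent-improvement cutoff; the default 50 is inclusive
#'   (>= 50 counts as response).
#' @return an object of class `response_labels`: a data frame with columns
#'   `subject_id`, `percent_change`, `responder`, plus attributes
#'   `n_excluded` (missing end-of-study), `excluded_ids`, and
#'   `n_undefined` (baseline total 0, flagged and excluded).
#' @export
label_placebo_responders <- function(data, eos_week,
                                     placebo_label = "placebo",
                                     threshold = 50) {
  pbo <- data[data$arm == placebo_label, , drop = FALSE]
  if (nrow(pbo) == 0) stop("no subjects in arm '", placebo_label, "'")
  bsl <- pbo[pbo$visit_week == 0, c("subject_id", "total_score")]
  if (anyDuplicated(bsl$subject_id)) stop("duplicate baseline rows")
  eos <- pbo[pbo$visit_week == eos_week, c("subject_id", "total_score")]
  if (!all(pbo$subject_id %in% bsl$subject_id)) {
    stop("every placebo subject must have an observed baseline")
  }
  undefined <- bsl$subject_id[bsl$total_score <= 0]
  if (length(undefined)) {
    warning(length(undefined), " subject(s) with baseline total 0 excluded from labeling")
    bsl <- bsl[!bsl$subject_id %in% undefined, , drop = FALSE]
  }
  merged <- merge(bsl, eos, by = "subject_id", suffixes = c("_bsl", "_eos"))
  excluded <- setdiff(bsl$subject_id, merged$subject_id)
  pc <- percent_change(merged$total_score_bsl, merged$total_score_eos)
  labels <- data.frame(
    subject_id = merged$subject_id,
    percent_change = pc,
    responder = as.integer(pc >= threshold),
    stringsAsFactors = FALSE
  )
  if (nrow(labels) > 0 && length(unique(labels$responder)) < 2) {
    warning("degenerate labels: all placebo subjects are in one response class")
  }
  structure(labels,
    class = c("response_labels", "data.frame"),
    n_excluded = length(excluded),
    excluded_ids = excluded,
    n_undefined = length(undefined)
  )
}
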