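make_labels <- function(responder) {
  structure(
    data.frame(
      subject_id = sprintf("S%03d", seq_along(responder)),
      percent_change = ifelse(responder == 1, 60, 10),
      responder = responder, stringsAsFactors = FALSE
    ),
    class = c("response_labels", "data.frame")
  )
}

test_that("the 75/25 split is stratified, disjoint and exhaustive", {
  labels <- make_labels(rep(c(1, 0), c(40, 60)))
  sp <- split_placebo(labels, 0.75, seed = 2)
  expect_length(sp$train_ids, 75)
  expect_length(sp$validation_ids, 25)
  expect_length(intersect(sp$train_ids, sp$validation_ids), 0)
  expect_setequal(c(sp$train_ids, sp$validation_ids), labels$subject_id)
  resp_tr <- labels$responder[labels$subject_id %in% sp$train_ids]
  expect_equal(sum(resp_tr == 1), 30)
  expect_equal(sum(resp_tr == 0), 45)
  # deterministic given seed
  expect_identical(sp, split_placebo(labels, 0.75, seed = 2))
  expect_error(split_placebo(make_labels(rep(0, 20))), "degenerate")
  expect_error(split_placebo(make_labels(c(1, 0, 1))), "at least 8")
})

test_that("AUC matches hand-evaluated and brute-force pairwise concordance", {
  expect_equal(auc_mw(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_mw(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0)), 0.75)
  brute <- function(s, y) {
    pos <- s[y == 1]
    neg <- s[y == 0]
    g <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(g)
  }
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:50, 1)
    s <- round(runif(n), 2) # ties likely
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(auc_mw(s, y), brute(s, y))
  }
})

test_that("bootstrap ROC gives ordered percentile bounds and detects separation", {
  set.seed(7)
  y <- rep(c(1, 0), each = 30)
  s_perfect <- c(runif(30, 0.7, 1), runif(30, 0, 0.3))
  roc <- bootstrap_roc(s_perfect, y, n_boot = 300, seed = 1)
  expect_equal(roc$auc, 1.0)
  expect_true(roc$ci_lower <= roc$ci_upper)
  expect_true(roc$auc >= 0 && roc$auc <= 1)
  # reproducible
  roc2 <- bootstrap_roc(s_perfect, y, n_boot = 300, seed = 1)
  expect_identical(roc, roc2)
  expect_error(bootstrap_roc(runif(5), rep(1, 5), 100, 1), "both classes")
})

test_that("bootstrap CI covers 0.5 at roughly the nominal rate under no signal", {
  hits <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    s <- runif(200)
    y <- rbinom(200, 1, 0.5)
    roc <- bootstrap_roc(s, y, n_boot = 400, seed = r)
    if (roc$ci_lower <= 0.5 && roc$ci_upper >= 0.5) hits <- hits + 1
  }
  # 95% nominal; allow generous MC slack at 60 repetitions
  expect_gte(hits / n_rep, 0.85)
})

test_that("model qualification requires the CI lower bound strictly above 0.5", {
  mk <- function(lo) structure(
    list(auc = 0.9, ci_lower = lo, ci_upper = 0.99, n_boot = 100, level = .95),
    class = "roc_result"
  )
  expect_true(validate_model(mk(0.81)))
  expect_true(validate_model(mk(0.73)))
  expect_false(validate_model(mk(0.50)))
  expect_false(validate_model(mk(0.45)))
})

test_that("inverse-probability weights obey the floor and renormalization rules", {
  sc <- pswtrial:::propensity_scores(
    c("a", "b", "c"), rep("placebo", 3), c(0.5, 0.5, 0.125),
    p_floor = 0.05, renormalize = FALSE
  )
  expect_equal(sc$w_raw, c(2, 2, 8))
  expect_equal(sc$w, c(2, 2, 8))
  sc2 <- pswtrial:::propensity_scores(
    c("a", "b", "c"), rep("placebo", 3), c(0.5, 0.5, 0.125),
    p_floor = 0.05, renormalize = TRUE
  )
  expect_equal(sc2$w, c(0.5, 0.5, 2.0))
  # clipping
  sc3 <- pswtrial:::propensity_scores("a", "placebo", 0.001,
    p_floor = 0.05, renormalize = FALSE
  )
  expect_equal(sc3$w_raw, 20)
  expect_equal(sc2$w * pmax(sc2$p, 0.05) * mean(sc2$w_raw), rep(1, 3))
})

test_that("propensity bins partition subjects and sum to one per arm", {
  sc <- data.frame(
    arm = "placebo", p = c(0.1, 0.25, 0.5, 0.7, 0.9),
    subject_id = letters[1:5]
  )
  bins <- propensity_distribution(sc)
  expect_equal(unlist(bins[1, 2:6], use.names = FALSE), rep(0.2, 5))
  expect_equal(bins$n, 5)
  sc_hi <- data.frame(arm = "a", p = c(0.85, 0.9, 1.0), subject_id = 1:3)
  bins_hi <- propensity_distribution(sc_hi)
  expect_equal(unlist(bins_hi[1, 2:6], use.names = FALSE), c(0, 0, 0, 0, 1))
  expect_equal(sum(bins_hi[1, 2:6]), 1)
})

test_that("grid search returns the singleton and prefers smaller ties", {
  # perfectly separable single-item signal: every net reaches CV-AUC 1
  set.seed(9)
  x <- cbind(c(rnorm(30, -2, 0.3), rnorm(30, 2, 0.3)), rnorm(60, 0, 0.05))
  y <- rep(c(0, 1), each = 30)
  single <- list(ann_spec(hidden = 5))
  gs1 <- grid_search_ann(x, y, grid = single, seed = 1, k = 3)
  expect_equal(gs1$best$hidden, 5L)

  grid <- list(ann_spec(hidden = c(7, 7)), ann_spec(hidden = 1), ann_spec(hidden = 3))
  gs <- grid_search_ann(x, y, grid = grid, seed = 1, k = 3)
  expect_true(all(gs$results$cv_auc == 1))
  expect_equal(gs$best$hidden, 1L) # tie-break toward the smallest network
})

test_that("cross-fit predictions cover every training subject and carry signal", {
  set.seed(10)
  x <- matrix(rnorm(80 * 3), 80)
  rownames(x) <- sprintf("S%03d", 1:80)
  y <- as.integer(x[, 1] + rnorm(80, 0, 0.4) > 0)
  p <- crossfit_predictions(x, y, ann_spec(hidden = 2), seed = 4, k = 4)
  expect_length(p, 80)
  expect_named(p)
  expect_gt(auc_mw(p, y), 0.7)
  expect_identical(p, crossfit_predictions(x, y, ann_spec(hidden = 2), seed = 4, k = 4))
})
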