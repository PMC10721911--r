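test_that("design validation rejects malformed trials", {
  expect_error(
    trial_design(
      arms = c(a = 0, b = 1), n_per_arm = 10,
      visit_weeks = c(-1, 0, 4), eos_week = 4
    ),
    "placebo"
  )
  expect_error(
    trial_design(
      arms = c(placebo = 0, b = 1), n_per_arm = 10,
      visit_weeks = c(-1, 0, 4), eos_week = 8
    ),
    "eos_week"
  )
  expect_error(
    trial_design(
      arms = c(placebo = 0.5, b = 1), n_per_arm = 10,
      visit_weeks = c(-1, 0, 4), eos_week = 4
    ),
    "effect of 0"
  )
})

test_that("generation is reproducible and respects instrument bounds", {
  preset <- design_preset("hamd17_4arm", n_per_arm = 30)
  t1 <- generate_trial(preset$design, preset$scale, 7)
  t2 <- generate_trial(preset$design, preset$scale, 7)
  expect_identical(t1$data, t2$data)
  expect_identical(t1$truth, t2$truth)

  items <- as.matrix(t1$data[, item_columns(preset$scale)])
  expect_true(all(items >= 0))
  expect_true(all(sweep(items, 2, preset$scale$item_max, "<=")))
  expect_equal(rowSums(items), t1$data$total_score)
  expect_true(all(items == round(items)))
})

test_that("latent classes follow the design mixture", {
  mix <- c(DminusPminus = 0.4, DplusPplus = 0.4, DplusPminus = 0.2)
  d <- trial_design(
    arms = c(placebo = 0, a1 = 3, a2 = 3), n_per_arm = 2000,
    visit_weeks = c(-1, 0, 4, 8), eos_week = 8, class_mix = mix
  )
  trial <- generate_trial(d, scale_definition("MADRS"), 11)
  freq <- table(trial$truth$latent_class) / nrow(trial$truth)
  expect_true(all(abs(freq[names(mix)] - mix) < 0.02))
})

test_that("screening and baseline are always observed; dropout is monotone", {
  d <- small_design(dropout_rate = 0.4)
  trial <- generate_trial(d, scale_definition("MADRS"), 3)
  per_subj <- split(trial$data$visit_week, trial$data$subject_id)
  expect_true(all(vapply(per_subj, function(v) all(c(-1, 0) %in% v), logical(1))))
  post <- d$visit_weeks[d$visit_weeks > 0]
  gap_free <- vapply(per_subj, function(v) {
    obs <- post %in% v
    # once missing, missing thereafter
    all(diff(obs) <= 0) || all(obs)
  }, logical(1))
  expect_true(all(gap_free))
})

test_that("true propensity matches class definitions and a Monte-Carlo oracle", {
  noiseless <- small_design(noise_sd = 0)
  expect_equal(true_propensity(30, "DminusPminus", noiseless), 0)
  expect_equal(true_propensity(30, "DplusPplus", noiseless), 1)

  d <- small_design(noise_sd = 6)
  p <- true_propensity(28, "DplusPplus", d)
  expect_gt(p, 0)
  expect_lt(p, 1)
  # MC oracle: EOS latent total = B(1 - m) + e, responder iff <= B/2
  set.seed(42)
  e <- rnorm(2e5, 0, d$noise_sd)
  eos <- 28 * (1 - d$placebo_response_frac) + e
  expect_equal(p, mean(eos <= 14), tolerance = 0.01)
})

test_that("placebo-arm response rate converges to the mixture-implied rate", {
  d <- trial_design(
    arms = c(placebo = 0, active = 5), n_per_arm = 4000,
    visit_weeks = c(-1, 0, 3, 6), eos_week = 6, dropout_rate = 0
  )
  trial <- generate_trial(d, scale_definition("MADRS"), 5)
  labels <- suppressWarnings(label_placebo_responders(trial$data, 6))
  implied <- mean(trial$truth$true_propensity[trial$truth$arm == "placebo"])
  # item rounding adds a little noise around the latent-scale rate
  expect_equal(mean(labels$responder), implied, tolerance = 0.03)
})

test_that("written CSVs round-trip and keep truth separate", {
  d <- small_design()
  trial <- generate_trial(d, scale_definition("MADRS"), 9)
  dir <- withr::local_tempdir()
  paths <- write_trial(trial, dir)
  back <- read_trial_data(paths[["data"]])
  expect_equal(nrow(back), nrow(trial$data))
  expect_false("latent_class" %in% names(back))
  truth <- utils::read.csv(paths[["truth"]])
  expect_true(all(c("latent_class", "true_propensity") %in% names(truth)))
})
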