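test_that("training is deterministic given the architecture seed", {
  set.seed(1)
  x <- matrix(rnorm(60 * 4), 60)
  y <- as.integer(x[, 1] + rnorm(60, 0, 0.5) > 0)
  m1 <- ann_train(x, y, ann_spec(hidden = 3, seed = 5))
  m2 <- ann_train(x, y, ann_spec(hidden = 3, seed = 5))
  expect_identical(m1$par, m2$par)
  expect_identical(predict(m1, x), predict(m2, x))
})

test_that("constant input columns are dropped before fitting", {
  set.seed(2)
  x <- cbind(rnorm(50), 7, rnorm(50))
  y <- as.integer(x[, 1] > 0)
  m <- ann_train(x, y, ann_spec(hidden = 2, seed = 1))
  expect_equal(m$keep, c(TRUE, FALSE, TRUE))
  expect_length(predict(m, x), 50)
  expect_error(ann_train(matrix(1, 20, 3), rep(0:1, 10), ann_spec()), "constant")
})

test_that("a single informative item yields monotone predictions", {
  set.seed(3)
  x <- cbind(seq(-3, 3, length.out = 120), rnorm(120, 0, 0.1))
  y <- as.integer(x[, 1] > 0)
  m <- ann_train(x, y, ann_spec(hidden = 2, seed = 4, max_iterations = 1000))
  grid <- cbind(seq(-3, 3, length.out = 41), 0)
  p <- predict(m, grid)
  expect_true(all(diff(p) > -1e-8))
  expect_gt(p[41], 0.9)
  expect_lt(p[1], 0.1)
})

test_that("probabilities stay in (0, 1) under extrapolation", {
  set.seed(4)
  x <- matrix(rnorm(40 * 3), 40)
  y <- rep(0:1, 20)
  m <- ann_train(x, y, ann_spec(hidden = c(3, 2), seed = 2))
  p <- predict(m, matrix(rnorm(200 * 3, 0, 10), 200))
  expect_true(all(p > 0 & p < 1))
})

test_that("a persisted model reproduces its predictions exactly", {
  set.seed(5)
  x <- matrix(rnorm(50 * 5), 50)
  colnames(x) <- sprintf("item_%02d", 1:5)
  y <- as.integer(rowSums(x[, 1:2]) > 0)
  m <- ann_train(x, y, ann_spec(hidden = c(4, 2), seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  ann_to_json(m, path, scale_name = "MADRS")
  m2 <- ann_from_json(path)
  expect_equal(predict(m2, x), predict(m, x), tolerance = 1e-12)
  expect_equal(attr(m2, "scale_name"), "MADRS")
})

test_that("persisted models refuse to cross instruments", {
  set.seed(6)
  x <- matrix(rnorm(40 * 3), 40)
  y <- rep(0:1, 20)
  m <- ann_train(x, y, ann_spec(hidden = 2, seed = 1))
  path <- withr::local_tempfile(fileext = ".json")
  ann_to_json(m, path, scale_name = "MADRS")
  expect_error(
    load_propensity_model(path, scale_definition("HAMD17")),
    "trial-specific"
  )
  expect_s3_class(
    load_propensity_model(path, scale_definition("HAMD17"),
      allow_scale_mismatch = TRUE
    ),
    "psw_ann"
  )
  expect_s3_class(load_propensity_model(path, scale_definition("MADRS")), "psw_ann")
})
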