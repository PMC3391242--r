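test_that("splits partition the cells at the stated fractions", {
  ids <- seq_len(1000)
  s <- makeSplits(ids, frac = 0.7, reps = 10, seed = 4)
  expect_length(s, 10)
  for (r in seq_along(s)) {
    expect_length(s[[r]]$calibration, 700)
    expect_length(s[[r]]$validation, 300)
    expect_length(intersect(s[[r]]$calibration, s[[r]]$validation), 0)
    expect_setequal(c(s[[r]]$calibration, s[[r]]$validation), ids)
  }
  expect_identical(s, makeSplits(ids, frac = 0.7, reps = 10, seed = 4))
  # repetitions differ from each other and across seeds
  expect_false(identical(s[[1]], s[[2]]))
  for (k in 1:10)
    expect_false(identical(makeSplits(ids, seed = k)[[1]],
                           makeSplits(ids, seed = k + 1)[[1]]))
  expect_error(makeSplits(ids, frac = 1.2), "frac")
  expect_error(makeSplits(1:5), "at least 10")
})

test_that("threshold choice equalises sensitivity and specificity", {
  out <- chooseThreshold(c(0.2, 0.3, 0.7, 0.8), c(0, 0, 1, 1))
  expect_equal(out$threshold, 0.7)
  expect_equal(out$sensitivity, 100)
  expect_equal(out$specificity, 100)

  # min(sens, spec) = 0.5 at t in {0.4, 0.6, 0.9}; only 0.6 balances them
  out2 <- chooseThreshold(c(0.1, 0.6, 0.4, 0.9), c(0, 0, 1, 1))
  expect_equal(out2$threshold, 0.6)
  expect_equal(out2$sensitivity, 50)
  expect_equal(out2$specificity, 50)

  expect_warning(out3 <- chooseThreshold(rep(0.4, 6), c(0, 1, 0, 1, 0, 1)),
                 "degenerate")
  expect_equal(out3$threshold, 0.4)
  expect_error(chooseThreshold(runif(5), rep(1, 5)), "both classes")
})

test_that("threshold choice matches the exhaustive scan oracle", {
  set.seed(31)
  for (i in 1:500) {
    n <- sample(6:60, 1)
    p <- round(runif(n), sample(1:3, 1))   # induce ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_identical(chooseThreshold(p, y)$threshold, scanThreshold(p, y))
  }
})

test_that("achieved min(sens, spec) is maximal among all thresholds", {
  w <- tinyWorld()
  y <- occurrenceMatrix(w$occ)[, "Thermexpa"]
  m <- fitGLM(w$grid, y, cellIds(w$grid), c("AnnTMean", "CumLenkm"), seed = 1)
  m <- calibrateThreshold(m, w$grid, y, cellIds(w$grid))
  p <- predictProbabilities(m, w$grid)$p
  achieved <- min(m@fit$calibration$sensitivity,
                  m@fit$calibration$specificity)
  for (t in sort(unique(p))[seq(1, length(unique(p)), length.out = 50)]) {
    sens <- 100 * mean(p[y == 1] >= t)
    spec <- 100 * mean(p[y == 0] < t)
    expect_lte(min(sens, spec), achieved + 1e-9)
  }
})

test_that("binary metrics count the confusion matrix in percent", {
  expect_equal(binaryMetrics(c(1, 0, 1), c(1, 0, 1)),
               c(sensitivity = 100, specificity = 100))
  expect_equal(binaryMetrics(c(0, 1, 0), c(1, 0, 1)),
               c(sensitivity = 0, specificity = 0))
  expect_equal(binaryMetrics(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               c(sensitivity = 50, specificity = 50))
  expect_error(binaryMetrics(c(1, 0), c(1, 0, 1)), "lengths differ")
})

test_that("ROC score equals Mann-Whitney pair counting to machine precision", {
  set.seed(17)
  for (i in 1:300) {
    n <- sample(6:50, 1)
    p <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_lt(abs(rocScore(p, y) - pairCountAUC(p, y)), 1e-12)
  }
})

test_that("ROC score agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(18)
  for (i in 1:10) {
    p <- runif(80)
    y <- rbinom(80, 1, 0.4)
    if (length(unique(y)) < 2) next
    ref <- as.numeric(suppressMessages(pROC::auc(y, p, direction = "<")))
    expect_equal(rocScore(p, y), ref, tolerance = 1e-12)
  }
})

test_that("performance bands split at the conventional cut points", {
  expect_equal(classifyPerformance(c(0.55, 0.65, 0.75, 0.85, 0.95)),
               c("fail", "poor", "fair", "good", "excellent"))
  # left-closed intervals; the last one closed at 1
  expect_equal(classifyPerformance(c(0.5, 0.6, 0.7, 0.8, 0.9, 1.0)),
               c("fail", "poor", "fair", "good", "excellent", "excellent"))
  expect_error(classifyPerformance(0.3), "0.5")
})

test_that("permutation importance respects model structure", {
  w <- tinyWorld()
  y <- occurrenceMatrix(w$occ)[, "Frigusten"]
  m <- fitGLM(w$grid, y, cellIds(w$grid), "AnnTMean", seed = 1)
  pi1 <- permutationImportance(m, w$grid, nPerm = 5, seed = 2)
  expect_equal(unname(pi1[["AnnTMean"]]), 100)

  # a predictor the stepwise search never saw gets exactly zero
  pi2 <- permutationImportance(m, w$grid,
                               predictors = c("AnnTMean", "Popmean"),
                               nPerm = 5, seed = 2)
  expect_identical(unname(pi2[["Popmean"]]), 0)
  expect_equal(sum(pi2), 100, tolerance = 1e-6)

  # constant predictions make the profile undefined
  set.seed(3)
  yc <- rbinom(600, 1, 0.4)
  m0 <- fitGLM(w$grid, yc, cellIds(w$grid), "Popmean", seed = 1)
  if (!length(selectedPredictors(m0)))
    expect_warning(permutationImportance(m0, w$grid,
                                         predictors = "Popmean",
                                         nPerm = 3, seed = 1),
                   "undefined")
})
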