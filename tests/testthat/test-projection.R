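test_that("loss and gain are ratios over currently occupied cells", {
  cur <- data.frame(cell_id = 1:40,
                    presence = c(rep(1, 20), rep(0, 20)))
  fut <- data.frame(cell_id = 1:40,
                    presence = c(rep(0, 8), rep(1, 12), rep(1, 10),
                                 rep(0, 10)))
  lg <- lossGain(cur, fut)
  expect_equal(lg$loss, 40)   # 8 of 20 vacated
  expect_equal(lg$gain, 50)   # 10 newly occupied / 20 current
  expect_equal(lg$nCurrent, 20)

  same <- lossGain(cur, cur)
  expect_equal(same$loss, 0)
  expect_equal(same$gain, 0)
  expect_equal(same$coincidence, 1)

  gone <- data.frame(cell_id = 1:40, presence = rep(0, 40))
  lg2 <- lossGain(cur, gone)
  expect_equal(lg2$loss, 100)
  expect_equal(lg2$gain, 0)

  empty <- data.frame(cell_id = 1:40, presence = 0)
  expect_error(lossGain(empty, fut), "undefined")
  expect_error(lossGain(cur, fut[1:10, ]), "aligned")
})

test_that("loss, gain and coincidence match cell-by-cell counting", {
  set.seed(41)
  for (i in 1:200) {
    n <- 200
    a <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (!sum(a)) a[1] <- 1
    b <- rbinom(n, 1, runif(1, 0.2, 0.8))
    cur <- data.frame(cell_id = 1:n, presence = a)
    fut <- data.frame(cell_id = 1:n, presence = b)
    lg <- lossGain(cur, fut)
    lost <- 0; gained <- 0; agree <- 0
    for (cell in 1:n) {
      if (a[cell] == 1 && b[cell] == 0) lost <- lost + 1
      if (a[cell] == 0 && b[cell] == 1) gained <- gained + 1
      if (a[cell] == b[cell]) agree <- agree + 1
    }
    expect_equal(lg$loss, 100 * lost / sum(a))
    expect_equal(lg$gain, 100 * gained / sum(a))
    expect_equal(lg$coincidence, agree / n)
    # conservation: lost + retained = all currently occupied
    expect_equal(lg$loss + 100 * sum(a == 1 & b == 1) / sum(a), 100)
  }
})

test_that("range mismatch counts out-of-range cells and their union", {
  w <- tinyWorld()
  g <- w$grid
  y <- occurrenceMatrix(w$occ)[, "Frigusten"]
  m <- fitGLM(g, y, cellIds(g), c("AnnTMean", "AnnPMean"), seed = 1)

  # identity scenario: nothing is out of range
  mm0 <- rangeMismatch(list(m), g)
  expect_true(all(mm0$perPredictor == 0))
  expect_equal(mm0$total, 0)

  # push a known fraction of cells above the calibration maximum
  v <- g@data$AnnTMean
  q60 <- unname(stats::quantile(v, 0.6))
  delta <- max(v) - q60 + 1e-9
  shifted <- applyClimateShift(g, shiftSpec("s", delta = c(AnnTMean = delta)))
  mm1 <- rangeMismatch(list(m), shifted)
  expected <- 100 * sum(v + delta > max(v)) / nCells(g)
  expect_equal(mm1$perPredictor[["AnnTMean"]], expected)
  expect_gte(mm1$total, max(mm1$perPredictor))

  # disjoint out-of-range sets add up in the union
  gg <- predictorGrid(
    data.frame(cell_id = 1:100, x = 1, y = 1:100,
               p1 = c(rep(5, 10), rep(0.5, 90)),
               p2 = c(rep(0.5, 10), rep(5, 10), rep(0.5, 80))),
    data.frame(name = c("p1", "p2"), category = "climate",
               kind = "continuous", units = "-"))
  mFake <- new("FittedSDM", engine = "GLM", species_code = "sp",
               selected_predictors = c("p1", "p2"),
               fit = list(kind = "glm"), threshold = NA_real_,
               repetition_id = 1L, seed = 1L,
               calibration_ranges = list(p1 = c(0, 1), p2 = c(0, 1)))
  mm2 <- rangeMismatch(list(mFake), gg)
  expect_equal(unname(mm2$perPredictor), c(10, 10))
  expect_equal(mm2$total, 20)

  # monotone in the predictor set considered
  mOne <- mFake; mOne@selected_predictors <- "p1"
  mOne@calibration_ranges <- list(p1 = c(0, 1))
  mm3 <- rangeMismatch(list(mOne), gg)
  expect_lte(mm3$total, mm2$total)
})

test_that("union calibration ranges pool repetitions", {
  mA <- new("FittedSDM", engine = "GLM", species_code = "sp",
            selected_predictors = "p", fit = list(kind = "glm"),
            threshold = NA_real_, repetition_id = 1L, seed = 1L,
            calibration_ranges = list(p = c(0, 4)))
  mB <- mA; mB@calibration_ranges <- list(p = c(-2, 3))
  gg <- predictorGrid(
    data.frame(cell_id = 1:10, x = 1, y = 1:10,
               p = c(-3, -1, 0, 1, 2, 3, 3.5, 4.5, 5, 6)),
    data.frame(name = "p", category = "climate", kind = "continuous",
               units = "-"))
  mm <- rangeMismatch(list(mA, mB), gg)
  # union range is [-2, 4]: cells at -3, 4.5, 5, 6 fall outside
  expect_equal(mm$ranges$p, c(-2, 4))
  expect_equal(mm$perPredictor[["p"]], 40)
})

test_that("projection consensus over scenarios books members correctly", {
  w <- tinyWorld()
  g <- w$grid
  y <- occurrenceMatrix(w$occ)[, "Thermexpa"]
  splits <- makeSplits(cellIds(g), seed = 6, reps = 2)
  models <- list()
  for (r in 1:2) {
    m <- fitGLM(g, y, splits[[r]]$calibration,
                c("AnnTMean", "CumLenkm"), seed = r, repetition = r)
    models[[r]] <- calibrateThreshold(m, g, y, splits[[r]]$calibration)
  }
  noShift <- shiftSpec("none", delta = c(AnnTMean = 0))
  grids <- list(A = applyClimateShift(g, noShift),
                B = applyClimateShift(g, noShift),
                C = applyClimateShift(g, noShift))
  proj <- projectFuture(models, grids)
  expect_length(proj$members, 2 * 3)
  expect_named(proj$perScenario, c("A", "B", "C"))

  # identity scenarios reproduce the current consensus exactly
  current <- consensusVote(lapply(models, predictBinary, grid = g))
  expect_identical(presence(proj$joint), presence(current))

  # a warming shift cannot reduce the true occupancy of a warm-adapted niche
  warmTruth <- nicheProbability(w$niches$Thermexpa, g)
  shifted <- applyClimateShift(g, defaultScenarios()$ECHAM5)
  warmFuture <- nicheProbability(w$niches$Thermexpa, shifted)
  expect_true(all(warmFuture >= warmTruth - 1e-12))
})
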