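test_that("stepwise GLM recovers known logistic coefficients and prunes noise", {
  g <- gaussianGrid(n = 3000, seed = 42)
  set.seed(9)
  p <- plogis(-1 + 1.5 * g@data$temp)
  y <- rbinom(3000, 1, p)
  m <- fitGLM(g, y, cellIds(g), c("temp", "noise"), seed = 1)
  expect_s4_class(m, "FittedSDM")
  expect_true("temp" %in% selectedPredictors(m))
  cf <- summary(m@fit$model)$coefficients
  expect_lt(abs(cf["(Intercept)", "Estimate"] - (-1)),
            3 * cf["(Intercept)", "Std. Error"])
  expect_lt(abs(cf["temp", "Estimate"] - 1.5), 3 * cf["temp", "Std. Error"])
  # calibration ranges recorded for used predictors
  expect_equal(calibrationRanges(m)$temp, range(g@data$temp))

  # pure-noise predictor is pruned by AIC in most replicates
  excluded <- 0L
  for (i in 1:50) {
    gi <- gaussianGrid(n = 400, seed = 100 + i)
    set.seed(200 + i)
    yi <- rbinom(400, 1, plogis(-1 + 1.5 * gi@data$temp))
    mi <- fitGLM(gi, yi, cellIds(gi), c("temp", "noise"), seed = i)
    if (!"noise" %in% selectedPredictors(mi)) excluded <- excluded + 1L
  }
  expect_gte(excluded, 40L)
})

test_that("intercept-only truth yields the closed-form constant model", {
  g <- gaussianGrid(n = 1000, seed = 1)
  set.seed(2)
  y <- rbinom(1000, 1, 0.3)
  m <- fitGLM(g, y, cellIds(g), c("temp", "noise"), seed = 1)
  expect_length(selectedPredictors(m), 0)
  pm <- predictProbabilities(m, g)
  expect_equal(unique(round(pm$p, 12)), round(mean(y), 12))
})

test_that("spline GAM uses 4-df bases and beats the GLM on curved truth", {
  # basis contract: one continuous predictor expands to exactly 4 columns
  x <- rnorm(100)
  expect_equal(ncol(splines::ns(x, df = 4)), 4)

  g <- gaussianGrid(n = 1200, seed = 7)
  wins <- 0L
  deltasLinear <- numeric(10)
  for (r in 1:10) {
    splits <- makeSplits(cellIds(g), seed = 50 + r, reps = 1)
    cal <- splits[[1]]$calibration
    val <- splits[[1]]$validation
    set.seed(300 + r)
    yQ <- rbinom(1200, 1, plogis(1.5 - 2 * g@data$temp^2))
    mGam <- fitGAM(g, yQ, cal, "temp", seed = r)
    mGlm <- fitGLM(g, yQ, cal, "temp", seed = r)
    iv <- match(val, cellIds(g))
    pG <- predictProbabilities(mGam, g)$p[iv]
    pL <- predictProbabilities(mGlm, g)$p[iv]
    if (rocScore(pG, yQ[iv]) > rocScore(pL, yQ[iv])) wins <- wins + 1L

    set.seed(400 + r)
    yL <- rbinom(1200, 1, plogis(-0.5 + 1.2 * g@data$temp))
    mGam2 <- fitGAM(g, yL, cal, "temp", seed = r)
    mGlm2 <- fitGLM(g, yL, cal, "temp", seed = r)
    p2G <- predictProbabilities(mGam2, g)$p[iv]
    p2L <- predictProbabilities(mGlm2, g)$p[iv]
    deltasLinear[r] <- rocScore(p2G, yL[iv]) - rocScore(p2L, yL[iv])
  }
  expect_gte(wins, 9L)                       # unimodal truth favours splines
  expect_lte(mean(abs(deltasLinear)), 0.02)  # linear truth: no advantage

  # too few distinct values demotes the spline term
  gd <- predictorGrid(
    data.frame(cell_id = 1:200, x = 1, y = 1:200,
               coarse = rep(c(0, 1, 2, 3), 50), fine = rnorm(200)),
    data.frame(name = c("coarse", "fine"), category = "climate",
               kind = "continuous", units = "-"))
  set.seed(5)
  yd <- rbinom(200, 1, plogis(gd@data$coarse - 1.5))
  expect_warning(fitGAM(gd, yd, cellIds(gd), c("coarse", "fine"), seed = 1),
                 "too few distinct")
})

test_that("bagged-tree engine is deterministic, overfits calibration, and separates", {
  w <- tinyWorld()
  y <- occurrenceMatrix(w$occ)[, "Neutrstra"]
  splits <- makeSplits(cellIds(w$grid), seed = 5, reps = 1)
  cal <- splits[[1]]$calibration
  offered <- c("AnnTMean", "AltMean", "Strahler", "CumLenkm")
  m1 <- fitRF(w$grid, y, cal, offered, seed = 3, nTrees = 100,
              nTreesSelect = 50)
  m2 <- fitRF(w$grid, y, cal, offered, seed = 3, nTrees = 100,
              nTreesSelect = 50)
  expect_identical(predictProbabilities(m1, w$grid)$p,
                   predictProbabilities(m2, w$grid)$p)
  expect_error(fitRF(w$grid, y, cal, offered, nTrees = 0), "nTrees")

  # calibration >= validation ROC in >= 9 of 10 repetitions (overfitting
  # gap of the bagged trees; predictor selection off so the forest has
  # continuous predictors to memorise with)
  reps <- makeSplits(cellIds(w$grid), seed = 11, reps = 10)
  gap <- 0L
  for (r in seq_along(reps)) {
    mr <- fitRF(w$grid, y, reps[[r]]$calibration, offered, seed = r,
                nTrees = 150, selectPredictors = FALSE)
    pm <- predictProbabilities(mr, w$grid)
    ic <- match(reps[[r]]$calibration, pm$cell_id)
    iv <- match(reps[[r]]$validation, pm$cell_id)
    yc <- y[match(reps[[r]]$calibration, cellIds(w$grid))]
    yv <- y[match(reps[[r]]$validation, cellIds(w$grid))]
    if (rocScore(pm$p[ic], yc) >= rocScore(pm$p[iv], yv)) gap <- gap + 1L
  }
  expect_gte(gap, 9L)

  # a perfectly separating predictor gives calibration AUC 1
  gs <- predictorGrid(
    data.frame(cell_id = 1:200, x = 1, y = 1:200,
               sep = c(rnorm(100, -3), rnorm(100, 3))),
    data.frame(name = "sep", category = "climate", kind = "continuous",
               units = "-"))
  ys <- rep(c(0L, 1L), each = 100)
  ms <- fitRF(gs, ys, cellIds(gs), "sep", seed = 1, nTrees = 100,
              selectPredictors = FALSE)
  ps <- predictProbabilities(ms, gs)$p
  expect_equal(rocScore(ps, ys), 1.0)
})

test_that("maximum-entropy engine honours its variational contracts", {
  w <- tinyWorld()
  g <- w$grid

  # uniform presences: no constraint binds, the Gibbs weights stay uniform
  set.seed(8)
  pres <- sample(cellIds(g), 200)
  mU <- fitMaxent(g, pres, c("AnnTMean", "AltMean"), seed = 1, reg = 1)
  pU <- predictProbabilities(mU, g)$p
  expect_lt(stats::sd(pU) / mean(pU), 0.25)

  # infinite shrinkage: all weights zero, exactly uniform suitability
  mInf <- fitMaxent(g, pres, c("AnnTMean", "AltMean"), seed = 1, reg = 1e9)
  expect_true(all(mInf@fit$lambda == 0))
  expect_equal(unique(predictProbabilities(mInf, g)$p), 1)

  # strong thermal niche: KKT residual of every feature within the L1
  # tolerance reg / n_presences
  warm <- order(g@data$AnnTMean, decreasing = TRUE)[1:150]
  presW <- cellIds(g)[warm]
  mW <- fitMaxent(g, presW, c("AnnTMean", "AltMean"), seed = 1, reg = 1)
  eta <- gridsdm:::.meFeatures(g@data, mW@fit$features) %*% mW@fit$lambda
  q <- exp(eta - max(eta)); q <- q / sum(q)
  Fbg <- gridsdm:::.meFeatures(g@data, mW@fit$features)
  gibbsExp <- as.numeric(crossprod(Fbg, q))
  presMean <- colMeans(Fbg[match(presW, cellIds(g)), ])
  expect_lt(max(abs(gibbsExp - presMean)),
            mW@fit$regEffective + 1e-4)
  # the niche actually got learned (rank correlation: the [0,1] cap on
  # suitability flattens the warm end)
  expect_gt(stats::cor(predictProbabilities(mW, g)$p, g@data$AnnTMean,
                       method = "spearman"), 0.5)

  expect_error(fitMaxent(g, cellIds(g)[1:5], "AnnTMean"), "at least 10")
})

test_that("maxent output is invariant to affine predictor rescaling", {
  w <- tinyWorld()
  g <- w$grid
  set.seed(3)
  pres <- cellIds(g)[order(g@data$AnnTMean)[1:120]]
  m1 <- fitMaxent(g, pres, c("AnnTMean", "AnnPMean"), seed = 1, reg = 1)
  g2 <- g
  g2@data$AnnTMean <- g2@data$AnnTMean * 1.8 + 32  # Fahrenheit
  m2 <- fitMaxent(g2, pres, c("AnnTMean", "AnnPMean"), seed = 1, reg = 1)
  expect_equal(predictProbabilities(m1, g)$p,
               predictProbabilities(m2, g2)$p, tolerance = 1e-6)
})

test_that("prediction is a pure function with positional and level safety", {
  w <- tinyWorld()
  y <- occurrenceMatrix(w$occ)[, "Frigusten"]
  m <- fitGLM(w$grid, y, cellIds(w$grid),
              c("AnnTMean", "AltMean", "RtypMost"), seed = 1)
  pm <- predictProbabilities(m, w$grid)
  expect_true(all(pm$p >= 0 & pm$p <= 1))

  # hand-computed logistic values on a 3-cell table (single predictor so
  # the linear predictor can be written out explicitly)
  gg <- gaussianGrid(n = 500, seed = 21)
  set.seed(22)
  yy <- rbinom(500, 1, plogis(0.5 + 1.2 * gg@data$temp))
  mm <- fitGLM(gg, yy, cellIds(gg), "temp", seed = 1)
  cf <- stats::coef(mm@fit$model)
  g3 <- new("PredictorGrid", data = gg@data[1:3, ], meta = gg@meta)
  byHand <- 1 / (1 + exp(-(cf[["(Intercept)"]] +
                             cf[["temp"]] * g3@data$temp)))
  expect_equal(predictProbabilities(mm, g3)$p, byHand, tolerance = 1e-12)

  # permuting cell order permutes output identically
  perm <- sample(nCells(w$grid))
  gp <- new("PredictorGrid", data = w$grid@data[perm, ], meta = w$grid@meta)
  expect_equal(predictProbabilities(m, gp)$p, pm$p[perm], tolerance = 1e-12)

  # missing predictor column and unseen categorical level are errors
  gMiss <- new("PredictorGrid",
               data = w$grid@data[setdiff(names(w$grid@data), "AltMean")],
               meta = w$grid@meta[w$grid@meta$name != "AltMean", ])
  expect_error(predictProbabilities(m, gMiss), "lacks predictor")

  seen <- calibrationRanges(m)$RtypMost
  if (length(seen) == 10) {
    mSub <- fitGLM(w$grid, y,
                   cellIds(w$grid)[w$grid@data$RtypMost != "marsh"],
                   c("AnnTMean", "RtypMost"), seed = 1)
    expect_error(predictProbabilities(mSub, w$grid), "unseen")
  }
})

test_that("adding an informative predictor never hurts calibration likelihood", {
  g <- gaussianGrid(n = 800, seed = 13)
  set.seed(14)
  y <- rbinom(800, 1, plogis(-0.5 + 1.3 * g@data$temp))
  df <- data.frame(y = y, temp = g@data$temp)
  m0 <- stats::glm(y ~ 1, binomial, df)
  m1 <- stats::glm(y ~ temp, binomial, df)
  expect_gte(as.numeric(stats::logLik(m1)), as.numeric(stats::logLik(m0)))
})
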