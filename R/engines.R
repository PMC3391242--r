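# The four niche-model engines. All fits record the calibration range of
# every predictor they use, so projections can be audited for extrapolation.

.calibrationRanges <- function(df, predictors) {
  out <- list()
  for (p in predictors) {
    col <- df[[p]]
    out[[p]] <- if (is.factor(col)) levels(droplevels(col))
                else range(as.numeric(col))
  }
  out
}

.calibFrame <- function(grid, cells, offered) {
  idx <- match(cells, cellIds(grid))
  if (anyNA(idx)) stop("calibration cells not found in grid")
  df <- grid@data[idx, offered, drop = FALSE]
  df[] <- lapply(df, function(col) if (is.factor(col)) droplevels(col) else col)
  df
}

.checkCalibClasses <- function(y) {
  if (length(unique(y)) < 2L)
    stop("calibration set must contain both presences and absences")
}

# glm.fit emits a warning whenever a fitted probability touches 0/1; with
# flexible bases that is routine and not itself separation (which we detect
# by deviance), so it is muffled during the stepwise search.
.quietBinomial <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fitted probabilities numerically", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

# predictors actually appearing in a fitted formula's terms
.termPredictors <- function(mod, offered) {
  used <- attr(stats::terms(mod), "term.labels")
  offered[vapply(offered, function(p)
    any(grepl(paste0("\\b", p, "\\b"), used)), logical(1))]
}

#' Fit a stepwise logistic regression (GLM engine)
#'
#' Binomial generalised linear model, additive-linear on the logit scale,
#' with categorical predictors one-hot encoded against a reference level.
#' Predictors are chosen by bidirectional stepwise search minimising AIC,
#' starting from the intercept-only model. Complete separation (deviance
#' collapsing to zero) triggers a warning and a ridge-penalised fallback fit
#' (penalty 1e-4 on the standardised scale), flagged in the model blob.
#'
#' @param grid a [PredictorGrid-class].
#' @param y full-length binary 0/1 occurrence vector aligned with `grid`.
#' @param cells calibration cell ids.
#' @param offered predictor names offered to the stepwise search.
#' @param seed integer seed stored for provenance (the search itself is
#'   deterministic).
#' @param species,repetition provenance labels.
#' @return a [FittedSDM-class] (threshold unset until calibration).
#' @export
fitGLM <- function(grid, y, cells, offered, seed = 1,
                   species = "species", repetition = 1L) {
  df <- .calibFrame(grid, cells, offered)
  yc <- y[match(cells, cellIds(grid))]
  .checkCalibClasses(yc)
  df$.y <- yc
  base <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  upper <- stats::as.formula(paste("~", paste(offered, collapse = " + ")))
  mod <- .quietBinomial(
    stats::step(base, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0))
  sel <- .termPredictors(mod, offered)
  fit <- list(kind = "glm", model = mod, ridge = FALSE)
  if (mod$deviance < 1e-6 && length(sel)) {
    warning("complete separation in GLM fit; using ridge-penalised fallback")
    X <- stats::model.matrix(
      stats::as.formula(paste("~", paste(sel, collapse = " + "))), df)[, -1,
                                                                      drop = FALSE]
    ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
    Xs <- scale(X, ctr, scl)
    rf <- glmnet::glmnet(Xs, yc, family = "binomial", alpha = 0,
                         lambda = 1e-4, standardize = FALSE)
    fit <- list(kind = "glm", model = NULL, ridge = TRUE,
                beta = as.numeric(rf$beta), a0 = as.numeric(rf$a0),
                center = ctr, scale = scl, selected = sel,
                formula = paste("~", paste(sel, collapse = " + ")),
                xlev = lapply(df[intersect(sel, names(df))], function(c)
                  if (is.factor(c)) levels(c) else NULL))
  }
  new("FittedSDM", engine = "GLM", species_code = species,
      selected_predictors = sel, fit = fit, threshold = NA_real_,
      repetition_id = as.integer(repetition), seed = as.integer(seed),
      calibration_ranges = .calibrationRanges(df, sel))
}

#' Fit a fixed-df spline additive model (GAM engine)
#'
#' Binomial additive model in which every continuous predictor enters
#' through a cubic regression-spline basis with exactly four degrees of
#' freedom (knots at quantiles of the calibration values, no smoothing
#' parameter search); ordinal and categorical predictors enter as in the
#' GLM engine. Whole spline blocks are added/removed by bidirectional
#' stepwise AIC, the AIC df being the basis columns used. A continuous
#' predictor with fewer than 8 distinct calibration values is demoted to a
#' linear term with a warning.
#'
#' @inheritParams fitGLM
#' @return a [FittedSDM-class].
#' @export
fitGAM <- function(grid, y, cells, offered, seed = 1,
                   species = "species", repetition = 1L) {
  df <- .calibFrame(grid, cells, offered)
  yc <- y[match(cells, cellIds(grid))]
  .checkCalibClasses(yc)
  meta <- predictorMeta(grid)
  kinds <- stats::setNames(meta$kind, meta$name)
  terms <- vapply(offered, function(p) {
    if (kinds[[p]] == "continuous") {
      if (length(unique(df[[p]])) < 8L) {
        warning(sprintf("predictor '%s' has too few distinct values for a spline; using a linear term", p))
        p
      } else sprintf("splines::ns(%s, df = 4)", p)
    } else p
  }, character(1))
  df$.y <- yc
  base <- stats::glm(.y ~ 1, family = stats::binomial(), data = df)
  upper <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  mod <- .quietBinomial(
    stats::step(base, scope = list(lower = ~1, upper = upper),
                direction = "both", trace = 0))
  sel <- .termPredictors(mod, offered)
  new("FittedSDM", engine = "GAM", species_code = species,
      selected_predictors = sel,
      fit = list(kind = "gam", model = mod, terms = terms),
      threshold = NA_real_, repetition_id = as.integer(repetition),
      seed = as.integer(seed),
      calibration_ranges = .calibrationRanges(df, sel))
}

# Greedy forward path on out-of-bag misclassification, then the
# one-standard-error pick: the smallest model whose OOB error is within one
# binomial standard error of the path minimum.
.rfForwardSelect <- function(df, yf, offered, seed, numTrees) {
  n <- length(yf)
  sel <- character()
  remaining <- offered
  pathErr <- numeric()
  repeat {
    if (!length(remaining)) break
    errs <- vapply(remaining, function(p) {
      r <- ranger::ranger(y = yf, x = df[c(sel, p)], num.trees = numTrees,
                          seed = deriveSeed(seed, "fsel", length(sel), p),
                          num.threads = 1,
                          respect.unordered.factors = "order")
      r$prediction.error
    }, numeric(1))
    best <- names(errs)[order(errs, names(errs), method = "radix")][1]
    errNew <- errs[[best]]
    if (length(pathErr) && errNew >= pathErr[length(pathErr)]) break
    sel <- c(sel, best)
    remaining <- setdiff(remaining, best)
    pathErr <- c(pathErr, errNew)
  }
  if (!length(sel)) return(offered[1])
  eMin <- min(pathErr)
  se <- sqrt(eMin * (1 - eMin) / n)
  k <- which(pathErr <= eMin + se)[1]
  sel[seq_len(k)]
}

#' Fit a bagged classification-tree ensemble (RF engine)
#'
#' Random-forest-style ensemble of classification trees (default 500), each
#' grown on a bootstrap sample of the calibration cells; the occurrence
#' probability of a cell is the fraction of trees voting presence. Because
#' AIC is undefined for bagged trees, the parsimonious-model search is a
#' forward selection on out-of-bag misclassification error with a
#' one-standard-error stopping rule. Deterministic given `seed`.
#'
#' @inheritParams fitGLM
#' @param nTrees trees in the final ensemble (>= 1).
#' @param nTreesSelect trees per candidate fit during forward selection.
#' @param selectPredictors set `FALSE` to skip forward selection and use all
#'   offered predictors.
#' @return a [FittedSDM-class].
#' @export
fitRF <- function(grid, y, cells, offered, seed = 1, nTrees = 500,
                  nTreesSelect = 100, selectPredictors = TRUE,
                  species = "species", repetition = 1L) {
  if (nTrees < 1) stop("nTrees must be at least 1")
  df <- .calibFrame(grid, cells, offered)
  yc <- y[match(cells, cellIds(grid))]
  .checkCalibClasses(yc)
  yf <- factor(yc, levels = c(0, 1))
  sel <- if (selectPredictors)
    .rfForwardSelect(df, yf, offered, seed, nTreesSelect) else offered
  forest <- ranger::ranger(y = yf, x = df[sel], num.trees = nTrees,
                           seed = deriveSeed(seed, "forest"),
                           num.threads = 1,
                           respect.unordered.factors = "order")
  new("FittedSDM", engine = "RF", species_code = species,
      selected_predictors = sel,
      fit = list(kind = "rf", forest = forest, nTrees = nTrees),
      threshold = NA_real_, repetition_id = as.integer(repetition),
      seed = as.integer(seed),
      calibration_ranges = .calibrationRanges(df, sel))
}

# Maxent feature matrix from stored transforms.
.meFeatures <- function(data, spec) {
  cols <- list()
  for (p in spec$continuous) {
    z <- (as.numeric(data[[p]]) - spec$center[[p]]) / spec$scale[[p]]
    cols[[p]] <- z
    z2 <- (z^2 - spec$center2[[p]]) / spec$scale2[[p]]
    cols[[paste0(p, "^2")]] <- z2
  }
  for (p in names(spec$levels)) {
    lev <- as.character(data[[p]])
    for (l in spec$levels[[p]])
      cols[[paste0(p, "=", l)]] <- as.numeric(lev == l)
  }
  do.call(cbind, cols)
}

#' Fit a presence-only maximum-entropy model (ME engine)
#'
#' Estimates a Gibbs distribution over the background (all grid cells)
#' whose feature expectations match the presence sample: among all
#' distributions consistent with the data it is the one with maximum
#' entropy. Features are standardised linear and quadratic terms of the
#' offered continuous/ordinal predictors plus level indicators for
#' categorical ones; weights are fitted by maximising the presence
#' log-likelihood with an L1 penalty `reg * sum(|lambda|)` via proximal
#' gradient descent. Cell suitabilities are rescaled by the maximum
#' background Gibbs weight so the output lies in [0, 1] and can be
#' thresholded like the other engines.
#'
#' @param grid [PredictorGrid-class]; all its cells form the background.
#' @param presenceCells cell ids with observed presence (>= 10 distinct).
#' @param offered predictor names.
#' @param seed stored for provenance (the optimisation is deterministic).
#' @param reg L1 regularisation weight (>= 0) on the total presence
#'   log-likelihood, so feature-expectation residuals are bounded by
#'   `reg / n_presences` at stationarity.
#' @param maxIter,tol optimiser controls.
#' @param species,repetition provenance labels.
#' @return a [FittedSDM-class].
#' @export
fitMaxent <- function(grid, presenceCells, offered, seed = 1, reg = 1.0,
                      maxIter = 500, tol = 1e-7,
                      species = "species", repetition = 1L) {
  presenceCells <- unique(presenceCells)
  if (length(presenceCells) < 10)
    stop("maximum-entropy fit needs at least 10 distinct presence cells")
  idx <- match(presenceCells, cellIds(grid))
  if (anyNA(idx)) stop("presence cells not found in grid")
  meta <- predictorMeta(grid)
  kinds <- stats::setNames(meta$kind, meta$name)[offered]
  numPreds <- offered[kinds != "categorical"]
  catPreds <- offered[kinds == "categorical"]
  bg <- grid@data
  spec <- list(continuous = numPreds, center = list(), scale = list(),
               center2 = list(), scale2 = list(), levels = list())
  for (p in numPreds) {
    x <- as.numeric(bg[[p]])
    spec$center[[p]] <- mean(x)
    s <- stats::sd(x); spec$scale[[p]] <- if (s > 0) s else 1
    z <- (x - spec$center[[p]]) / spec$scale[[p]]
    spec$center2[[p]] <- mean(z^2)
    s2 <- stats::sd(z^2); spec$scale2[[p]] <- if (s2 > 0) s2 else 1
  }
  for (p in catPreds) spec$levels[[p]] <- levels(bg[[p]])
  Fbg <- .meFeatures(bg, spec)
  fPres <- colMeans(Fbg[idx, , drop = FALSE])
  k <- ncol(Fbg)
  # penalty applies to the total presence log-likelihood, so on the mean
  # log-likelihood scale it enters as reg / n_presences
  regTot <- reg
  reg <- reg / length(presenceCells)
  lambda <- numeric(k)
  eta <- Fbg %*% lambda
  obj <- function(eta, lambda) {
    m <- max(eta)
    (m + log(mean(exp(eta - m)))) - sum(fPres * lambda) + reg * sum(abs(lambda))
  }
  step <- 1
  objOld <- obj(eta, lambda)
  for (it in seq_len(maxIter)) {
    m <- max(eta)
    w <- exp(eta - m); q <- w / sum(w)
    gr <- as.numeric(crossprod(Fbg, q)) - fPres
    repeat {
      lamNew <- lambda - step * gr
      lamNew <- sign(lamNew) * pmax(abs(lamNew) - step * reg, 0)
      etaNew <- Fbg %*% lamNew
      objNew <- obj(etaNew, lamNew)
      if (objNew <= objOld + 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    delta <- max(abs(lamNew - lambda))
    lambda <- lamNew; eta <- etaNew; objOld <- objNew
    step <- min(step * 1.5, 10)
    if (delta < tol) break
  }
  normConst <- max(eta)
  used <- offered[vapply(offered, function(p) {
    ix <- if (p %in% numPreds) which(colnames(Fbg) %in% c(p, paste0(p, "^2")))
          else grep(paste0("^", p, "="), colnames(Fbg))
    any(lambda[ix] != 0)
  }, logical(1))]
  idxAll <- match(cellIds(grid), cellIds(grid))
  new("FittedSDM", engine = "ME", species_code = species,
      selected_predictors = if (length(used)) used else character(),
      fit = list(kind = "maxent", lambda = stats::setNames(lambda, colnames(Fbg)),
                 features = spec, normConst = normConst, reg = regTot,
                 regEffective = reg, offered = offered),
      threshold = NA_real_, repetition_id = as.integer(repetition),
      seed = as.integer(seed),
      calibration_ranges = .calibrationRanges(bg, offered))
}

#' Fit one of the four engines by name
#'
#' Convenience dispatcher. For the presence-only ME engine the calibration
#' cells' presences are extracted from `y` and the whole grid serves as
#' background.
#'
#' @inheritParams fitGLM
#' @param engine one of "GLM", "GAM", "RF", "ME".
#' @param ... passed to the engine-specific fitter.
#' @export
fitSDM <- function(engine, grid, y, cells, offered, seed = 1, ...) {
  engine <- match.arg(engine, c("GLM", "GAM", "RF", "ME"))
  switch(engine,
    GLM = fitGLM(grid, y, cells, offered, seed, ...),
    GAM = fitGAM(grid, y, cells, offered, seed, ...),
    RF = fitRF(grid, y, cells, offered, seed, ...),
    ME = fitMaxent(grid,
                   presenceCells = cells[y[match(cells, cellIds(grid))] == 1],
                   offered = offered, seed = seed, ...))
}

#' Predict per-cell occurrence probabilities from a fitted model
#'
#' A pure function of the fitted model and the predictor table: no
#' refitting. Extrapolation beyond the stored calibration ranges is allowed
#' (and accounted for separately by [rangeMismatch()]), but a categorical
#' level never seen in calibration is an error.
#'
#' @param model a [FittedSDM-class].
#' @param grid a [PredictorGrid-class] containing all selected predictors.
#' @return data.frame with `cell_id` and `p` (in [0, 1]); provenance
#'   attached as attribute `provenance`.
#' @export
predictProbabilities <- function(model, grid) {
  stopifnot(is(model, "FittedSDM"), is(grid, "PredictorGrid"))
  need <- selectedPredictors(model)
  missing <- setdiff(need, predictorNames(grid))
  if (length(missing))
    stop("grid lacks predictor(s): ", paste(missing, collapse = ", "))
  ranges <- calibrationRanges(model)
  for (p in need) {
    if (is.factor(grid@data[[p]])) {
      seen <- ranges[[p]]
      if (!is.null(seen)) {
        bad <- setdiff(unique(as.character(grid@data[[p]])), seen)
        if (length(bad))
          stop(sprintf("categorical level(s) unseen in calibration for '%s': %s",
                       p, paste(bad, collapse = ", ")))
      }
    }
  }
  fit <- model@fit
  p <- switch(fit$kind,
    glm = if (isTRUE(fit$ridge)) {
      mm <- stats::model.matrix(stats::as.formula(fit$formula),
                                data = grid@data, xlev = fit$xlev)[, -1,
                                                                   drop = FALSE]
      Xs <- scale(mm, fit$center, fit$scale)
      as.numeric(stats::plogis(fit$a0 + Xs %*% fit$beta))
    } else
      as.numeric(stats::predict(fit$model, newdata = grid@data,
                                type = "response")),
    gam = as.numeric(stats::predict(fit$model, newdata = grid@data,
                                    type = "response")),
    rf = {
      pr <- stats::predict(fit$forest, data = grid@data, predict.all = TRUE,
                           num.threads = 1)$predictions
      rowMeans(pr == 2L)  # per-tree factor level index; 2 = presence
    },
    maxent = {
      eta <- .meFeatures(grid@data, fit$features) %*% fit$lambda
      pmin(as.numeric(exp(eta - fit$normConst)), 1)
    },
    stop("unknown model kind"))
  out <- data.frame(cell_id = cellIds(grid), p = p)
  attr(out, "provenance") <- list(engine = model@engine,
                                  species = model@species_code,
                                  repetition = model@repetition_id)
  out
}

#' Calibrate a model's decision threshold on its calibration cells
#'
#' Predicts on the calibration cells and stores the
#' sensitivity/specificity-equalising threshold of [chooseThreshold()] in
#' the model.
#'
#' @param model a [FittedSDM-class].
#' @param grid the [PredictorGrid-class] used for fitting.
#' @param y full-length binary occurrence vector aligned with `grid`.
#' @param cells calibration cell ids.
#' @return the model with its `threshold` slot set; the achieved calibration
#'   sensitivity/specificity are attached to `model@fit$calibration`.
#' @export
calibrateThreshold <- function(model, grid, y, cells) {
  pm <- predictProbabilities(model, grid)
  i <- match(cells, pm$cell_id)
  ct <- chooseThreshold(pm$p[i], y[match(cells, cellIds(grid))])
  model@fit$calibration <- ct
  model@threshold <- if (ct$threshold <= 0) 1e-12 else ct$threshold
  model
}

#' Binary presence map from a calibrated model
#'
#' Applies the model's stored threshold (`p >= t` is presence).
#'
#' @param model a calibrated [FittedSDM-class].
#' @param grid a [PredictorGrid-class].
#' @return data.frame with `cell_id` and `presence` (0/1).
#' @export
predictBinary <- function(model, grid) {
  if (is.na(threshold(model)))
    stop("model threshold has not been calibrated")
  pm <- predictProbabilities(model, grid)
  out <- data.frame(cell_id = pm$cell_id,
                    presence = as.integer(pm$p >= threshold(model)))
  attr(out, "provenance") <- attr(pm, "provenance")
  out
}
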