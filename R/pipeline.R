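# End-to-end orchestration: simulate -> filter -> select -> fit ->
# evaluate -> consensus -> cluster -> project -> report.

#' Pipeline configuration
#'
#' Assembles and validates the configuration of [runPipeline()]. Defaults
#' reproduce the reference study conditions: a 2,935-cell grid, six virtual
#' species, 70/30 splits repeated 10 times, a 0.75 correlation cap, the
#' 0.65/5%/half relevance thresholds, a strict >50% consensus rule, a
#' strict >50-presence species filter, and a 0.8 mean-validation-ROC gate
#' for projection.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param nCells,dims grid size passed to [generatePredictorGrid()].
#' @param engines engines to fit and evaluate.
#' @param consensusEngines engines merged into consensus maps and
#'   projections (the presence-only ME engine is excluded by default, its
#'   performance being too dependent on occurrence frequency to support
#'   projection).
#' @param splitFrac,reps calibration fraction and number of repetitions.
#' @param corrCap pairwise association cap for predictor screening.
#' @param rocMin,piMin,countFrac relevance-rule thresholds.
#' @param minPresences species inclusion filter (strictly more than this
#'   many presences).
#' @param projectionROCMin minimum mean validation ROC (over
#'   `consensusEngines`) for a species to be projected.
#' @param scenarios named list of [ShiftSpec-class]; default
#'   [defaultScenarios()].
#' @param nPerm permutations per predictor for importance profiles.
#' @param piCells cells subsampled for importance profiling (keeps the
#'   permutation loop affordable at atlas scale).
#' @param nClusters,fuzzifier fuzzy c-means settings.
#' @param rfTrees,rfTreesSelect RF ensemble sizes (final / selection).
#' @param grid,occurrences,niches optional pre-built inputs; when NULL the
#'   synthetic module generates them.
#' @return a list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(seed = 1, nCells = 2935, dims = NULL,
                           engines = c("GLM", "GAM", "RF", "ME"),
                           consensusEngines = c("GLM", "GAM", "RF"),
                           splitFrac = 0.7, reps = 10, corrCap = 0.75,
                           rocMin = 0.65, piMin = 5, countFrac = 0.5,
                           minPresences = 50, projectionROCMin = 0.8,
                           scenarios = defaultScenarios(), nPerm = 20,
                           piCells = 1000, nClusters = 4, fuzzifier = 2,
                           rfTrees = 500, rfTreesSelect = 100,
                           grid = NULL, occurrences = NULL, niches = NULL) {
  if (!length(engines)) stop("at least one engine must be enabled")
  engines <- match.arg(engines, c("GLM", "GAM", "RF", "ME"),
                       several.ok = TRUE)
  if (!all(consensusEngines %in% engines))
    stop("consensusEngines must be a subset of engines")
  if (splitFrac <= 0 || splitFrac >= 1) stop("splitFrac must lie in (0,1)")
  if (corrCap <= 0 || corrCap > 1) stop("corrCap must lie in (0,1]")
  if (projectionROCMin < 0.5 || projectionROCMin > 1)
    stop("projectionROCMin must lie in [0.5,1]")
  structure(as.list(environment()), class = "pipelineConfig")
}

# mean validation ROC per species over the given engines
.gateTable <- function(evalTab, engines) {
  sub <- evalTab[evalTab$engine %in% engines, ]
  stats::aggregate(roc_validation ~ species, data = sub, FUN = mean)
}

#' Species inclusion filter
#'
#' Retains species with strictly more than `minPresences` positive
#' occurrences.
#'
#' @param occ an [OccurrenceTable-class].
#' @param minPresences inclusion threshold (strict).
#' @return the filtered [OccurrenceTable-class].
#' @export
filterSpecies <- function(occ, minPresences = 50) {
  keep <- presenceCount(occ) > minPresences
  if (!any(keep))
    stop("no species retained by the >", minPresences, " presence filter")
  occurrenceTable(cellIds(occ),
                  occurrenceMatrix(occ)[, keep, drop = FALSE])
}

#' Run the full ensemble-modelling pipeline
#'
#' Executes, deterministically given `config$seed`: synthetic data
#' generation (unless inputs are supplied), the species inclusion filter,
#' predictor screening (univariate AUC ranking + correlation capping),
#' engine fitting over all split repetitions with
#' sensitivity/specificity-equalising thresholds, evaluation
#' (calibration/validation ROC with performance bands, sensitivity,
#' specificity, coincidence), permutation-importance profiles and the
#' three-criteria relevance report, current consensus maps, grouped
#' response profiles with per-engine fuzzy c-means clustering, and -- for
#' species passing the validation-ROC gate -- scenario projection with
#' loss/gain summaries and calibration-range mismatch reports.
#'
#' @param config a [pipelineConfig()] list.
#' @param verbose print stage progress.
#' @return a report bundle (list) with elements `grid`, `occurrences`,
#'   `truth`, `splits`, `selection`, `models`, `evaluation`, `importance`,
#'   `relevance`, `consensusCurrent`, `responseTables`, `clusterings`,
#'   `projection`, `changeSummaries`, `mismatchReports`, `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  say <- function(...) if (verbose) message(...)
  seed <- config$seed

  # --- data ---------------------------------------------------------------
  say("stage: simulate")
  grid <- config$grid
  if (is.null(grid))
    grid <- generatePredictorGrid(nCells = config$nCells, dims = config$dims,
                                  corrCap = config$corrCap,
                                  seed = deriveSeed(seed, "grid"))
  occ <- config$occurrences
  truth <- NULL
  niches <- config$niches
  if (is.null(occ)) {
    if (is.null(niches)) niches <- defaultNiches(grid)
    sim <- simulateSpecies(grid, niches, seed = deriveSeed(seed, "species"))
    occ <- sim$occurrences
    truth <- sim$truth
  }
  occ <- filterSpecies(occ, config$minPresences)
  species <- speciesCodes(occ)

  # --- predictor screening ------------------------------------------------
  say("stage: select")
  screen <- univariateScreen(grid, occ)
  ranking <- rowMeans(screen)
  cf <- correlationFilter(grid, ranking, cap = config$corrCap)
  offered <- cf$kept
  selection <- list(univariateAUC = screen, ranking = ranking,
                    kept = offered, dropped = cf$dropped)

  # --- fit + evaluate -----------------------------------------------------
  say("stage: fit/evaluate")
  splits <- makeSplits(cellIds(grid), frac = config$splitFrac,
                       reps = config$reps, seed = deriveSeed(seed, "splits"))
  models <- list()
  evalRows <- list()
  for (sp in species) {
    y <- occurrenceMatrix(occ)[, sp]
    for (eng in config$engines) {
      for (r in seq_len(config$reps)) {
        cal <- splits[[r]]$calibration
        val <- splits[[r]]$validation
        sdm <- if (eng == "RF")
          fitRF(grid, y, cal, offered,
                seed = deriveSeed(seed, eng, sp, r),
                nTrees = config$rfTrees,
                nTreesSelect = config$rfTreesSelect,
                species = sp, repetition = r)
        else
          fitSDM(eng, grid, y, cal, offered,
                 seed = deriveSeed(seed, eng, sp, r),
                 species = sp, repetition = r)
        sdm <- calibrateThreshold(sdm, grid, y, cal)
        pm <- predictProbabilities(sdm, grid)
        iCal <- match(cal, pm$cell_id)
        iVal <- match(val, pm$cell_id)
        yCal <- y[match(cal, cellIds(grid))]
        yVal <- y[match(val, cellIds(grid))]
        rocCal <- rocScore(pm$p[iCal], yCal)
        rocVal <- rocScore(pm$p[iVal], yVal)
        bm <- binaryMetrics(as.integer(pm$p[iVal] >= threshold(sdm)), yVal)
        coin <- mean(as.integer(pm$p >= threshold(sdm)) == y)
        models[[sp]][[eng]][[r]] <- sdm
        evalRows[[length(evalRows) + 1L]] <- data.frame(
          species = sp, engine = eng, repetition = r,
          roc_calibration = rocCal, roc_validation = rocVal,
          sensitivity = bm[["sensitivity"]],
          specificity = bm[["specificity"]],
          coincidence = coin,
          band = classifyPerformance(max(rocVal, 0.5)))
      }
    }
  }
  evaluation <- do.call(rbind, evalRows)

  # --- importance + relevance report --------------------------------------
  say("stage: importance")
  set.seed(deriveSeed(seed, "picells"))
  piIdx <- sort(sample.int(nCells(grid), min(config$piCells, nCells(grid))))
  piGrid <- new("PredictorGrid", data = grid@data[piIdx, , drop = FALSE],
                meta = grid@meta)
  importance <- list()
  for (sp in species) for (eng in config$engines) {
    mod <- models[[sp]][[eng]][[1L]]
    importance[[sp]][[eng]] <- permutationImportance(
      mod, piGrid, predictors = offered, nPerm = config$nPerm,
      seed = deriveSeed(seed, "pi", eng, sp))
  }
  piMat <- sapply(species, function(sp)
    rowMeans(sapply(config$engines, function(eng)
      importance[[sp]][[eng]][offered])))
  rownames(piMat) <- offered
  nSelected <- vapply(offered, function(p) sum(vapply(species, function(sp)
    any(vapply(config$engines, function(eng) p %in% selectedPredictors(
      models[[sp]][[eng]][[1L]]), logical(1))), logical(1))), numeric(1))
  relevance <- selectRelevantPredictors(
    data.frame(predictor = offered,
               roc = ranking[offered],
               pi = rowMeans(piMat),
               n_selected = nSelected),
    nSpecies = length(species), rocMin = config$rocMin,
    piMin = config$piMin, countFrac = config$countFrac)

  # --- current consensus --------------------------------------------------
  say("stage: consensus")
  consensusCurrent <- list()
  binCurrent <- list()
  for (sp in species) {
    maps <- list()
    for (eng in config$consensusEngines) for (r in seq_len(config$reps))
      maps[[length(maps) + 1L]] <- predictBinary(models[[sp]][[eng]][[r]],
                                                 grid)
    consensusCurrent[[sp]] <- consensusVote(maps)
    binCurrent[[sp]] <- maps
  }

  # --- response clustering ------------------------------------------------
  say("stage: cluster")
  grouping <- defaultPredictorGroups()
  responseTables <- list()
  clusterings <- list()
  if (length(species) >= config$nClusters) {
    groups <- unique(unname(grouping))
    for (eng in config$engines) {
      # anthropogenic predictors carry no response group; shares are taken
      # over the grouped (climate/altitude/hydromorphology) predictors
      # only. A species whose first-repetition model carries no grouped
      # importance at all has an undefined profile and sits out the
      # clustering for this engine.
      prof <- t(vapply(species, function(sp) {
        pi <- importance[[sp]][[eng]]
        pi <- pi[names(pi) %in% names(grouping)]
        if (sum(pi) <= 0) stats::setNames(rep(NA_real_, length(groups)),
                                          groups)
        else groupResponseProfile(pi, grouping)
      }, numeric(length(groups))))
      rownames(prof) <- species
      ok <- stats::complete.cases(prof)
      if (sum(ok) < config$nClusters) next
      cl <- fuzzyCMeans(prof[ok, , drop = FALSE], c = config$nClusters,
                        m = config$fuzzifier,
                        seed = deriveSeed(seed, "fcm", eng))
      clusterings[[eng]] <- cl
      responseTables[[eng]] <- responseTable(prof[ok, , drop = FALSE], cl)
    }
  }

  # --- projection ---------------------------------------------------------
  say("stage: project")
  gate <- .gateTable(evaluation, config$consensusEngines)
  projected <- gate$species[gate$roc_validation >= config$projectionROCMin]
  scenarioGrids <- lapply(config$scenarios, function(s)
    applyClimateShift(grid, s))
  names(scenarioGrids) <- names(config$scenarios)
  projection <- list()
  changeSummaries <- list()
  mismatchReports <- list()
  for (sp in projected) {
    mods <- unlist(lapply(config$consensusEngines, function(eng)
      models[[sp]][[eng]]), recursive = FALSE)
    proj <- projectFuture(mods, scenarioGrids)
    projection[[sp]] <- proj
    cur <- consensusCurrent[[sp]]
    # Table-7-style marginal means: engine rows average over scenarios,
    # scenario rows average over engines, "Mean" is joint vs current.
    rows <- list()
    for (eng in config$consensusEngines) {
      lg <- sapply(names(scenarioGrids), function(sc) {
        maps <- lapply(models[[sp]][[eng]], predictBinary,
                       grid = scenarioGrids[[sc]])
        unlist(lossGain(cur, consensusVote(maps))[c("loss", "gain")])
      })
      rows[[eng]] <- data.frame(comparison = eng, loss = mean(lg["loss", ]),
                                gain = mean(lg["gain", ]))
    }
    for (sc in names(scenarioGrids)) {
      lg <- lossGain(cur, proj$perScenario[[sc]])
      rows[[sc]] <- data.frame(comparison = sc, loss = lg$loss,
                               gain = lg$gain)
    }
    lgJoint <- lossGain(cur, proj$joint)
    rows[["Mean"]] <- data.frame(comparison = "Mean", loss = lgJoint$loss,
                                 gain = lgJoint$gain)
    changeSummaries[[sp]] <- do.call(rbind, c(rows,
                                              list(make.row.names = FALSE)))
    mm <- lapply(scenarioGrids, function(sg) rangeMismatch(mods, sg))
    perPred <- t(vapply(mm, function(m) m$perPredictor,
                        numeric(length(mm[[1]]$perPredictor))))
    mmTab <- data.frame(scenario = names(mm), perPred,
                        total = vapply(mm, function(m) m$total, numeric(1)),
                        row.names = NULL, check.names = FALSE)
    mmTab <- rbind(mmTab, data.frame(scenario = "mean",
                                     t(colMeans(perPred)),
                                     total = mean(mmTab$total),
                                     check.names = FALSE))
    mismatchReports[[sp]] <- mmTab
  }

  manifest <- list(seed = seed,
                   stageSeeds = list(grid = deriveSeed(seed, "grid"),
                                     species = deriveSeed(seed, "species"),
                                     splits = deriveSeed(seed, "splits")),
                   engines = config$engines,
                   consensusEngines = config$consensusEngines,
                   reps = config$reps, splitFrac = config$splitFrac,
                   offered = offered, species = species,
                   projected = projected,
                   scenarios = names(config$scenarios),
                   thresholds = list(corrCap = config$corrCap,
                                     rocMin = config$rocMin,
                                     piMin = config$piMin,
                                     countFrac = config$countFrac,
                                     minPresences = config$minPresences,
                                     projectionROCMin = config$projectionROCMin))

  list(grid = grid, occurrences = occ, truth = truth, niches = niches,
       splits = splits, selection = selection, models = models,
       evaluation = evaluation, importance = importance,
       relevance = relevance, consensusCurrent = consensusCurrent,
       responseTables = responseTables, clusterings = clusterings,
       projection = projection, changeSummaries = changeSummaries,
       mismatchReports = mismatchReports, manifest = manifest,
       config = config)
}

#' Compare a full-predictor run with a restricted-predictor run
#'
#' Computes, per species and engine, the change in mean validation ROC when
#' only a restricted predictor set (e.g. climate only) is offered, and
#' flags species as climate-sensitive when the restricted run still reaches
#' the validation-ROC threshold. Both runs must share splits (same master
#' seed, fraction and repetitions).
#'
#' @param full,restricted report bundles from [runPipeline()].
#' @param threshold validation-ROC threshold for the sensitivity flag.
#' @return data.frame with mean validation ROC of both runs, `delta`
#'   (restricted minus full) and `climate_sensitive` per species x engine.
#' @export
compareVariants <- function(full, restricted, threshold = 0.8) {
  mf <- full$manifest; mr <- restricted$manifest
  if (mf$seed != mr$seed || mf$reps != mr$reps ||
      mf$splitFrac != mr$splitFrac)
    stop("runs do not share the same split scheme; comparison refused")
  agg <- function(b) stats::aggregate(
    roc_validation ~ species + engine, data = b$evaluation, FUN = mean)
  af <- agg(full); ar <- agg(restricted)
  m <- merge(af, ar, by = c("species", "engine"),
             suffixes = c("_full", "_restricted"))
  m$delta <- m$roc_validation_restricted - m$roc_validation_full
  gate <- stats::aggregate(roc_validation ~ species, data =
    restricted$evaluation[restricted$evaluation$engine %in%
                            mr$consensusEngines, ], FUN = mean)
  m$climate_sensitive <- gate$roc_validation[
    match(m$species, gate$species)] >= threshold
  m
}
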