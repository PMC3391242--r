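# Scenario projection, range loss/gain and extrapolation accounting.

#' Project a fitted ensemble onto climate-shift scenarios
#'
#' Every (model, scenario) pair yields a binary map through the model's
#' stored threshold; members are merged by [consensusVote()] per scenario
#' and jointly over all pairwise combinations of models and scenarios.
#'
#' @param models list of calibrated [FittedSDM-class] objects (one species).
#' @param scenarioGrids named list of shifted [PredictorGrid-class] tables.
#' @return list with `perScenario` (named list of [ConsensusMap-class]),
#'   `joint` (consensus over all model x scenario members) and `members`
#'   (list of all member binary maps).
#' @export
projectFuture <- function(models, scenarioGrids) {
  stopifnot(length(models) >= 1, length(scenarioGrids) >= 1)
  if (is.null(names(scenarioGrids)))
    names(scenarioGrids) <- paste0("scenario", seq_along(scenarioGrids))
  perScenario <- list()
  allMaps <- list()
  for (sc in names(scenarioGrids)) {
    maps <- lapply(models, function(mod) {
      b <- predictBinary(mod, scenarioGrids[[sc]])
      pr <- attr(b, "provenance"); pr$scenario <- sc
      attr(b, "provenance") <- pr
      b
    })
    perScenario[[sc]] <- consensusVote(maps)
    allMaps <- c(allMaps, maps)
  }
  list(perScenario = perScenario, joint = consensusVote(allMaps),
       members = allMaps)
}

#' Range loss and gain between two binary maps
#'
#' Loss is the percentage of currently occupied cells predicted to be
#' vacated; gain is the percentage of currently occupied cells matched by
#' newly occupied ones (so gain can exceed 100 when a range more than
#' doubles). Both are relative to the number of currently occupied cells.
#'
#' @param current,future aligned binary maps ([ConsensusMap-class],
#'   data.frame, or 0/1 vector).
#' @return list with `loss`, `gain` (percent), `coincidence` (fraction of
#'   agreeing cells) and `nCurrent`.
#' @export
lossGain <- function(current, future) {
  pc <- .mapPresence(current); pf <- .mapPresence(future)
  ic <- .mapIds(current); jf <- .mapIds(future)
  if (length(ic) != length(jf) || any(ic != jf))
    stop("maps are not aligned to the same cell set")
  nCur <- sum(pc == 1)
  if (nCur == 0) stop("no currently occupied cells; loss/gain undefined")
  list(loss = 100 * sum(pc == 1 & pf == 0) / nCur,
       gain = 100 * sum(pc == 0 & pf == 1) / nCur,
       coincidence = mean(pc == pf),
       nCurrent = nCur)
}

#' Calibration-range mismatch of a projected scenario (novel climate)
#'
#' For every continuous/ordinal predictor used by the species' models, the
#' percentage of cells whose projected value falls outside the union of the
#' models' calibration ranges (below the observed minimum or above the
#' observed maximum), plus the total percentage of cells where at least one
#' such predictor is out of range. Predictions in those cells are
#' extrapolations. The union range (min of mins, max of maxes across
#' repetitions) is the least conservative consistent choice.
#'
#' @param models list of [FittedSDM-class] objects for one species.
#' @param scenarioGrid a shifted [PredictorGrid-class].
#' @return list with `perPredictor` (named percentages), `total` (percent
#'   of cells with >= 1 out-of-range predictor) and `ranges` (the union
#'   calibration ranges used).
#' @export
rangeMismatch <- function(models, scenarioGrid) {
  stopifnot(length(models) >= 1)
  meta <- predictorMeta(scenarioGrid)
  kinds <- stats::setNames(meta$kind, meta$name)
  ranges <- list()
  for (mod in models) {
    cr <- calibrationRanges(mod)
    for (p in names(cr)) {
      if (!p %in% names(kinds))
        stop("predictor absent from scenario grid: ", p)
      if (kinds[[p]] == "categorical") next
      ranges[[p]] <- if (is.null(ranges[[p]])) cr[[p]]
                     else c(min(ranges[[p]][1], cr[[p]][1]),
                            max(ranges[[p]][2], cr[[p]][2]))
    }
  }
  if (!length(ranges))
    return(list(perPredictor = numeric(), total = 0, ranges = ranges))
  n <- nCells(scenarioGrid)
  outAny <- rep(FALSE, n)
  perPredictor <- numeric()
  for (p in names(ranges)) {
    v <- as.numeric(scenarioGrid@data[[p]])
    out <- v < ranges[[p]][1] | v > ranges[[p]][2]
    perPredictor[[p]] <- 100 * sum(out) / n
    outAny <- outAny | out
  }
  list(perPredictor = perPredictor, total = 100 * sum(outAny) / n,
       ranges = ranges)
}
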