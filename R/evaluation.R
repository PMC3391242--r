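# Split/threshold/score machinery of the validation scheme.

# midrank (tie-corrected) Mann-Whitney AUC
.midrankAUC <- function(p, truth) {
  r <- rank(p)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Random calibration/validation splits
#'
#' Partitions the cell ids into a calibration fraction (default 70%) and a
#' validation remainder, independently for each repetition (default 10), as
#' used for repetition-based model validation.
#'
#' @param cell_ids vector of cell ids (n >= 10).
#' @param frac calibration fraction in (0, 1).
#' @param reps number of repetitions.
#' @param seed integer master seed; each repetition draws from a seed
#'   derived from it.
#' @return list of `reps` elements, each `list(calibration=, validation=)`
#'   of cell ids, with the arguments stored as attributes.
#' @export
makeSplits <- function(cell_ids, frac = 0.7, reps = 10, seed = 1) {
  if (frac <= 0 || frac >= 1) stop("frac must lie in (0, 1)")
  n <- length(cell_ids)
  if (n < 10) stop("need at least 10 cells to split")
  nCal <- round(frac * n)
  splits <- lapply(seq_len(reps), function(r) {
    set.seed(deriveSeed(seed, "split", r))
    cal <- sort(sample(cell_ids, nCal))
    list(calibration = cal, validation = sort(setdiff(cell_ids, cal)))
  })
  attributes(splits) <- c(attributes(splits),
                          list(frac = frac, reps = reps, seed = seed))
  splits
}

#' Sensitivity/specificity-equalising decision threshold
#'
#' Scans all unique predicted probabilities as candidate thresholds for the
#' rule `p >= t -> presence` and returns the one maximising
#' `min(sensitivity, specificity)`; ties are broken by minimal
#' `|sensitivity - specificity|`, then by the smallest threshold. This
#' implements the common thresholding scheme that maximises sensitivity and
#' specificity simultaneously, typically yielding near-equal values of both.
#'
#' @param p numeric vector of predicted probabilities.
#' @param truth binary 0/1 vector of observed presence.
#' @return list with `threshold`, `sensitivity` and `specificity` (percent).
#' @export
chooseThreshold <- function(p, truth) {
  stopifnot(length(p) == length(truth))
  .checkBinary(truth)
  cand <- sort(unique(p))
  if (length(cand) == 1L) {
    warning("all predicted probabilities are equal; threshold is degenerate")
    m <- binaryMetrics(as.integer(p >= cand), truth)
    return(list(threshold = cand, sensitivity = m[["sensitivity"]],
                specificity = m[["specificity"]]))
  }
  nPos <- sum(truth == 1)
  nNeg <- sum(truth == 0)
  # at threshold t = cand[k], predicted present iff p >= t:
  # TP = nPos - (#positives below t), TN = #negatives below t
  o <- order(p)
  grp <- cumsum(!duplicated(p[o]))
  posPer <- rowsum(as.numeric(truth[o] == 1), grp)[, 1]
  negPer <- rowsum(as.numeric(truth[o] == 0), grp)[, 1]
  posBelow <- c(0, cumsum(posPer)[-length(posPer)])
  negBelow <- c(0, cumsum(negPer)[-length(negPer)])
  sens <- (nPos - posBelow) / nPos
  spec <- negBelow / nNeg
  lo <- pmin(sens, spec)
  best <- which(lo == max(lo))
  gap <- abs(sens - spec)[best]
  best <- best[gap == min(gap)]
  i <- best[which.min(cand[best])]
  list(threshold = unname(cand[i]), sensitivity = unname(100 * sens[i]),
       specificity = unname(100 * spec[i]))
}

#' Sensitivity and specificity of a binary prediction
#'
#' @param pred binary 0/1 predicted presence.
#' @param truth binary 0/1 observed presence (both classes required).
#' @return named numeric: `sensitivity` = 100 TP/(TP+FN), `specificity` =
#'   100 TN/(TN+FP).
#' @export
binaryMetrics <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("pred and truth lengths differ")
  .checkBinary(truth)
  c(sensitivity = 100 * sum(pred == 1 & truth == 1) / sum(truth == 1),
    specificity = 100 * sum(pred == 0 & truth == 0) / sum(truth == 0))
}

#' ROC score (area under the ROC curve)
#'
#' Rank-based AUC with midrank tie correction, equal to the normalised
#' Mann-Whitney U statistic: the probability that a random presence cell is
#' scored above a random absence cell, with ties counted one half.
#'
#' @param p numeric score/probability vector.
#' @param truth binary 0/1 vector with both classes present.
#' @return AUC in [0, 1].
#' @export
rocScore <- function(p, truth) {
  stopifnot(length(p) == length(truth))
  .checkBinary(truth)
  .midrankAUC(p, truth)
}

#' Qualitative performance band of a ROC score
#'
#' Maps an AUC to the conventional five bands: 0.5-0.6 "fail", 0.6-0.7
#' "poor", 0.7-0.8 "fair", 0.8-0.9 "good", 0.9-1 "excellent" (left-closed,
#' right-open; the last interval is closed).
#'
#' @param roc numeric vector of ROC scores in [0.5, 1].
#' @return character vector of bands.
#' @export
classifyPerformance <- function(roc) {
  if (any(roc < 0.5 - 1e-12 | roc > 1 + 1e-12))
    stop("roc must lie in [0.5, 1]")
  bands <- c("fail", "poor", "fair", "good", "excellent")
  idx <- findInterval(roc, c(0.5, 0.6, 0.7, 0.8, 0.9), rightmost.closed = FALSE)
  idx[roc >= 1] <- 5L
  bands[idx]
}

#' Permutation importance of a fitted model's predictors
#'
#' For each predictor used by the model, predictions on `grid` are compared
#' with predictions on copies of `grid` in which that predictor's values are
#' randomly permuted: `r_v` is the mean Pearson correlation between original
#' and permuted predictions over `nPerm` permutations, the raw importance is
#' `max(0, 1 - r_v)`, and the reported PI is the raw importance normalised
#' to percentages summing to 100 across predictors. Predictors offered to
#' but not retained by the model get PI = 0 exactly.
#'
#' @param model a calibrated [FittedSDM-class].
#' @param grid [PredictorGrid-class] to evaluate on.
#' @param predictors predictors to profile; defaults to the model's selected
#'   set. Extra names get PI 0.
#' @param nPerm permutations per predictor.
#' @param seed integer seed for the permutations.
#' @return named numeric vector of PI percentages (attribute `raw` holds the
#'   unnormalised `1 - r` values; attribute `undefined` flags a constant
#'   prediction vector).
#' @export
permutationImportance <- function(model, grid, predictors = NULL,
                                  nPerm = 20, seed = 1) {
  stopifnot(is(model, "FittedSDM"))
  if (is.null(predictors))
    predictors <- selectedPredictors(model)
  orig <- predictProbabilities(model, grid)$p
  used <- selectedPredictors(model)
  raw <- stats::setNames(numeric(length(predictors)), predictors)
  if (stats::sd(orig) == 0) {
    warning("constant prediction vector; importance profile is undefined")
    out <- raw
    attr(out, "raw") <- raw
    attr(out, "undefined") <- TRUE
    return(out)
  }
  n <- nCells(grid)
  for (v in intersect(predictors, used)) {
    set.seed(deriveSeed(seed, "pi", model@engine, model@species_code, v))
    rs <- numeric(nPerm)
    for (k in seq_len(nPerm)) {
      g2 <- grid
      g2@data[[v]] <- grid@data[[v]][sample.int(n)]
      pk <- predictProbabilities(model, g2)$p
      rs[k] <- if (stats::sd(pk) == 0) 0 else stats::cor(orig, pk)
    }
    raw[v] <- max(0, 1 - mean(rs))
  }
  pi <- if (sum(raw) > 0) 100 * raw / sum(raw) else raw
  attr(pi, "raw") <- raw
  attr(pi, "undefined") <- FALSE
  pi
}
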