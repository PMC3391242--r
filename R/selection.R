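# Predictor screening and the explicit selection rules.

#' Orientation-corrected univariate AUC
#'
#' Rank-based AUC of a single predictor against a binary response, with
#' midrank tie handling, folded as `max(AUC, 1 - AUC)` so predictors that
#' decrease with presence score symmetrically. Categorical predictors are
#' scored by their per-level presence frequency before ranking.
#'
#' @param values numeric (or factor) predictor vector.
#' @param truth binary 0/1 vector with both classes present.
#' @return AUC in [0.5, 1].
#' @export
univariateAUC <- function(values, truth) {
  .checkBinary(truth)
  if (is.factor(values) || is.character(values)) {
    rate <- tapply(truth, values, mean)
    values <- as.numeric(rate[as.character(values)])
  }
  a <- .midrankAUC(values, truth)
  max(a, 1 - a)
}

#' Univariate discrimination screen over all predictors and species
#'
#' @param grid a [PredictorGrid-class].
#' @param occ an [OccurrenceTable-class] aligned with `grid`.
#' @return predictors x species matrix of orientation-corrected AUCs.
#' @export
univariateScreen <- function(grid, occ) {
  stopifnot(all(cellIds(grid) == cellIds(occ)))
  preds <- predictorNames(grid)
  out <- matrix(NA_real_, length(preds), length(speciesCodes(occ)),
                dimnames = list(preds, speciesCodes(occ)))
  for (sp in speciesCodes(occ)) {
    y <- occurrenceMatrix(occ)[, sp]
    for (p in preds) out[p, sp] <- univariateAUC(grid@data[[p]], y)
  }
  out
}

# Cramer's V between two factors.
.cramersV <- function(a, b) {
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (min(dim(tab)) < 2) return(0)
  chi2 <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$statistic
  sqrt(as.numeric(chi2) / (sum(tab) * (min(dim(tab)) - 1)))
}

# Correlation ratio (eta) of a numeric variable across factor groups.
.corRatio <- function(num, fac) {
  mu <- mean(num)
  ssb <- sum(tapply(num, fac, function(v) length(v) * (mean(v) - mu)^2))
  sst <- sum((num - mu)^2)
  if (sst == 0) return(0)
  sqrt(ssb / sst)
}

#' Pairwise association matrix for mixed-type predictors
#'
#' Pearson correlation between continuous/ordinal pairs, Cramer's V between
#' categorical pairs, and the correlation ratio (eta) for mixed pairs --
#' the standard mixed-type analogues of |r| on a common [0, 1] scale.
#'
#' @param grid a [PredictorGrid-class].
#' @param predictors predictor names (default: all).
#' @return symmetric matrix of association magnitudes with unit diagonal.
#' @export
associationMatrix <- function(grid, predictors = predictorNames(grid)) {
  meta <- predictorMeta(grid)
  kinds <- stats::setNames(meta$kind, meta$name)[predictors]
  k <- length(predictors)
  m <- diag(1, k)
  dimnames(m) <- list(predictors, predictors)
  for (i in seq_len(k - 1)) for (j in seq((i + 1), k)) {
    a <- grid@data[[predictors[i]]]
    b <- grid@data[[predictors[j]]]
    catA <- kinds[[i]] == "categorical"
    catB <- kinds[[j]] == "categorical"
    v <- if (catA && catB) .cramersV(a, b)
         else if (catA) .corRatio(as.numeric(b), a)
         else if (catB) .corRatio(as.numeric(a), b)
         else abs(stats::cor(as.numeric(a), as.numeric(b)))
    m[i, j] <- m[j, i] <- v
  }
  m
}

#' Greedy correlation capping of a predictor set
#'
#' Eliminates predictors until all retained pairwise associations are below
#' `cap` (default 0.75). While any pair violates the cap, the
#' violation-involved predictor with the lowest ranking (typically its mean
#' univariate AUC) is dropped; ranking ties are broken alphabetically, the
#' alphabetically first name being kept.
#'
#' @param grid a [PredictorGrid-class].
#' @param ranking named numeric, predictor -> ranking score covering all
#'   candidates.
#' @param cap association cap in (0, 1].
#' @param assoc optional precomputed association matrix (for testing);
#'   defaults to [associationMatrix()] over `names(ranking)`.
#' @return list with `kept` (character), `dropped` (data.frame kept/dropped/r
#'   triples, the kept column naming the strongest retained partner of each
#'   dropped predictor).
#' @export
correlationFilter <- function(grid, ranking, cap = 0.75, assoc = NULL) {
  if (cap <= 0 || cap > 1) stop("cap must lie in (0, 1]")
  if (is.null(names(ranking))) stop("ranking must be named by predictor")
  cand <- names(ranking)
  if (is.null(assoc)) assoc <- associationMatrix(grid, cand)
  assoc <- assoc[cand, cand, drop = FALSE]
  kept <- cand
  dropped <- list()
  repeat {
    a <- assoc[kept, kept, drop = FALSE]
    diag(a) <- 0
    viol <- which(a >= cap, arr.ind = TRUE)
    if (!nrow(viol)) break
    involved <- unique(kept[viol])
    # lowest-ranked violator goes; alphabetical order keeps ties stable
    involved <- involved[order(ranking[involved], involved,
                               decreasing = c(FALSE, TRUE), method = "radix")]
    worst <- involved[1]
    keptAfter <- setdiff(kept, worst)
    partners <- keptAfter[assoc[worst, keptAfter] >= cap]
    partner <- if (length(partners))
      partners[which.max(assoc[worst, partners])] else NA_character_
    dropped[[worst]] <- data.frame(kept = partner, dropped = worst,
                                   r = if (is.na(partner)) NA_real_
                                       else assoc[worst, partner])
    kept <- keptAfter
  }
  list(kept = kept,
       dropped = if (length(dropped)) do.call(rbind, unname(dropped))
                 else data.frame(kept = character(), dropped = character(),
                                 r = numeric()))
}

#' PCA representatives of a predictor group
#'
#' Standardises the group's columns, decomposes them by principal component
#' analysis and returns, for each of the first `nComponents` components, the
#' predictor most correlated (in absolute value) with that component's
#' scores, together with the components' explained-variance fractions. Used
#' to pick one representative per block of redundant predictors (e.g. a
#' precipitation block represented by its annual mean and seasonality).
#'
#' @param grid a [PredictorGrid-class].
#' @param group character vector of continuous/ordinal predictor names.
#' @param nComponents number of leading components to represent.
#' @return list with `representatives` (character) and `varianceFraction`
#'   (numeric).
#' @export
pcaRepresentatives <- function(grid, group, nComponents = 2) {
  X <- predictorData(grid, group)
  X <- as.data.frame(lapply(X, as.numeric))
  sds <- vapply(X, stats::sd, numeric(1))
  if (any(sds == 0))
    stop("constant predictor column(s): ",
         paste(group[sds == 0], collapse = ", "))
  if (length(group) == 1L)
    return(list(representatives = group, varianceFraction = 1.0))
  nComponents <- min(nComponents, length(group))
  pc <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  varFrac <- pc$sdev^2 / sum(pc$sdev^2)
  reps <- vapply(seq_len(nComponents), function(k) {
    cors <- abs(stats::cor(X, pc$x[, k]))
    group[which.max(cors)]
  }, character(1))
  list(representatives = reps, varianceFraction = varFrac[seq_len(nComponents)])
}

#' Three-criteria predictor relevance rule
#'
#' A predictor is relevant when at least two of three criteria hold:
#' (1) mean univariate ROC score >= `rocMin`; (2) mean permutation
#' importance >= `piMin` percent; (3) the predictor was selected by the
#' fitted models for at least half of the species
#' (`n_selected >= ceiling(nSpecies / 2)`).
#'
#' @param stats data.frame with columns `predictor`, `roc`, `pi`,
#'   `n_selected`.
#' @param nSpecies total number of species considered.
#' @param rocMin,piMin,countFrac criterion thresholds.
#' @return the input with added columns `criteria_passed` (0-3) and
#'   `relevant` (logical).
#' @export
selectRelevantPredictors <- function(stats, nSpecies, rocMin = 0.65,
                                     piMin = 5, countFrac = 0.5) {
  need <- c("predictor", "roc", "pi", "n_selected")
  if (!all(need %in% names(stats)))
    stop("stats must have columns ", paste(need, collapse = ", "))
  nMin <- ceiling(countFrac * nSpecies)
  c1 <- stats$roc >= rocMin
  c2 <- stats$pi >= piMin
  c3 <- stats$n_selected >= nMin
  stats$criteria_passed <- c1 + c2 + c3
  stats$relevant <- stats$criteria_passed >= 2L
  stats
}
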