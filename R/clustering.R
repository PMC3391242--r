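# Grouped environmental-response shares and fuzzy c-means species grouping.

#' Default thematic grouping of the basic predictor set
#'
#' Maps each predictor of the standard basic set to one of the three
#' response groups used for profiling species: climate (C), altitude (H)
#' and hydromorphology (HY).
#'
#' @return named character vector predictor -> group.
#' @export
defaultPredictorGroups <- function() {
  c(AnnTMean = "C", DiuTRange = "C", Isotherm = "C", TSeason = "C",
    Tmax = "C", TWetQuar = "C", TDryQuar = "C", AnnPMean = "C",
    PSeason = "C",
    AltMean = "H",
    CumLenkm = "HY", Strahler = "HY", RtypMost = "HY")
}

#' Grouped environmental-response profile of a species
#'
#' Collapses a permutation-importance profile into per-group shares: each
#' group's share is the sum of the PI values of its member predictors
#' divided by the sum over all predictors, so the shares sum to one.
#'
#' @param pi named numeric of permutation importances (percent or raw).
#' @param grouping named character predictor -> group label; defaults to
#'   [defaultPredictorGroups()]. Every predictor carrying importance must be
#'   covered.
#' @return named numeric of shares, one per group level (C, H, HY by
#'   default), summing to 1.
#' @export
groupResponseProfile <- function(pi, grouping = defaultPredictorGroups()) {
  if (sum(pi) <= 0) stop("all-zero importance profile; shares are undefined")
  uncovered <- names(pi)[pi > 0 & !names(pi) %in% names(grouping)]
  if (length(uncovered))
    stop("no group assigned for predictor(s): ",
         paste(uncovered, collapse = ", "))
  groups <- unique(unname(grouping))
  shares <- vapply(groups, function(g) {
    memb <- names(grouping)[grouping == g]
    sum(pi[names(pi) %in% memb]) / sum(pi)
  }, numeric(1))
  stats::setNames(shares, groups)
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means (Bezdek): alternating updates of the membership
#' matrix (`u_ik` proportional to `d_ik^(-2/(m-1))`) and the centers
#' (membership^m-weighted means), minimising the objective
#' `J_m = sum_ik u_ik^m ||x_i - v_k||^2`. The best of `restarts` random
#' initialisations (by final objective) is returned; convergence is reached
#' when the largest membership change falls below `tol`. An item coinciding
#' with a center receives membership 1 for that center.
#'
#' @param x numeric matrix, items x features (e.g. species x response
#'   shares).
#' @param c number of clusters (items >= c).
#' @param m fuzzifier (> 1); 2 is the conventional default.
#' @param tol convergence tolerance on memberships.
#' @param maxIter maximum iterations per restart.
#' @param restarts random initialisations.
#' @param seed integer seed; the result is deterministic given it.
#' @return list of class `fcmResult`: `memberships` (items x c, rows sum to
#'   1), `centers` (c x features), `cluster` (argmax cluster per item),
#'   `membershipGrade` (max membership per item), `objective` (final J_m),
#'   `objectiveTrace` (per-iteration J_m of the winning restart).
#' @export
fuzzyCMeans <- function(x, c = 4, m = 2, tol = 1e-6, maxIter = 300,
                        restarts = 20, seed = 1) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < c) stop("need at least as many items as clusters")
  if (m <= 1) stop("fuzzifier m must exceed 1")
  runOnce <- function(u) {
    trace <- numeric()
    centers <- matrix(0, c, ncol(x), dimnames = list(NULL, colnames(x)))
    for (it in seq_len(maxIter)) {
      um <- u^m
      tot <- colSums(um)
      # a cluster abandoned by all items keeps its previous center
      live <- tot > 1e-12
      centers[live, ] <- (t(um[, live, drop = FALSE]) %*% x) / tot[live]
      d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
        2 * x %*% t(centers)
      d2 <- pmax(d2, 0)
      trace <- c(trace, sum(um * d2))
      zero <- d2 < 1e-12
      uNew <- matrix(0, n, c)
      anyZero <- rowSums(zero) > 0
      if (any(anyZero))
        uNew[anyZero, ] <- zero[anyZero, , drop = FALSE] /
          rowSums(zero[anyZero, , drop = FALSE])
      if (any(!anyZero)) {
        w <- d2[!anyZero, , drop = FALSE]^(-1 / (m - 1))
        uNew[!anyZero, ] <- w / rowSums(w)
      }
      delta <- max(abs(uNew - u))
      u <- uNew
      if (delta < tol) break
    }
    um <- u^m
    tot <- colSums(um)
    live <- tot > 1e-12
    centers[live, ] <- (t(um[, live, drop = FALSE]) %*% x) / tot[live]
    d2 <- pmax(outer(rowSums(x^2), rowSums(centers^2), "+") -
                 2 * x %*% t(centers), 0)
    obj <- sum(um * d2)
    list(u = u, centers = centers, objective = obj,
         trace = c(trace, obj))
  }
  best <- NULL
  for (r in seq_len(restarts)) {
    set.seed(deriveSeed(seed, "fcm", r))
    u0 <- matrix(stats::runif(n * c), n, c)
    u0 <- u0 / rowSums(u0)
    res <- runOnce(u0)
    if (is.null(best) || res$objective < best$objective) best <- res
  }
  rownames(best$u) <- rownames(x)
  structure(list(
    memberships = best$u,
    centers = best$centers,
    cluster = apply(best$u, 1, which.max),
    membershipGrade = apply(best$u, 1, max),
    objective = best$objective,
    objectiveTrace = best$trace,
    c = c, m = m, seed = seed), class = "fcmResult")
}

#' @export
print.fcmResult <- function(x, ...) {
  cat(sprintf("Fuzzy c-means: %d items, %d clusters (m = %g), objective %.6g\n",
              nrow(x$memberships), x$c, x$m, x$objective))
  cat("cluster sizes (by argmax membership):",
      paste(tabulate(x$cluster, x$c), collapse = ", "), "\n")
  invisible(x)
}

#' Species response table in the C/H/HY share layout
#'
#' Builds the species x (C, H, HY, Fc, MG) table for one engine: grouped
#' response shares from each species' permutation-importance profile, the
#' argmax fuzzy cluster (Fc) and its membership grade (MG). Cluster labels
#' are relabelled in order of decreasing mean altitude (H) share so output
#' is stable across runs.
#'
#' @param profiles species x group share matrix (rows sum to 1).
#' @param clustering an `fcmResult` from [fuzzyCMeans()] on `profiles`.
#' @return data.frame with one row per species.
#' @export
responseTable <- function(profiles, clustering) {
  ord <- order(clustering$centers[, "H"], decreasing = TRUE)
  relabel <- match(seq_len(clustering$c), ord)
  data.frame(species = rownames(profiles),
             as.data.frame(profiles),
             Fc = relabel[clustering$cluster],
             MG = clustering$membershipGrade,
             row.names = NULL)
}
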