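# Shared fixtures, built once per test run.

.fixtures <- new.env()

# small synthetic grid + default virtual species
tinyWorld <- function() {
  if (is.null(.fixtures$world)) {
    grid <- generatePredictorGrid(nCells = 600, seed = 7)
    niches <- defaultNiches(grid)
    sim <- simulateSpecies(grid, niches, seed = 3)
    .fixtures$world <- list(grid = grid, niches = niches,
                            occ = sim$occurrences, truth = sim$truth)
  }
  .fixtures$world
}

# one-predictor grid with standard normal x (plus a pure-noise column),
# for parameter-recovery checks
gaussianGrid <- function(n = 3000, seed = 42) {
  set.seed(seed)
  predictorGrid(
    data.frame(cell_id = seq_len(n), x = rep(1:50, length.out = n),
               y = rep(seq_len(ceiling(n / 50)), each = 50)[seq_len(n)],
               temp = rnorm(n), noise = rnorm(n)),
    data.frame(name = c("temp", "noise"),
               category = c("climate", "climate"),
               kind = c("continuous", "continuous"),
               units = c("degC", "-")))
}

# brute-force AUC by positive/negative pair enumeration (independent oracle)
pairCountAUC <- function(p, truth) {
  pos <- p[truth == 1]
  neg <- p[truth == 0]
  tot <- 0
  for (a in pos) tot <- tot + sum(a > neg) + 0.5 * sum(a == neg)
  tot / (length(pos) * length(neg))
}

# exhaustive threshold scan (independent oracle for chooseThreshold)
scanThreshold <- function(p, truth) {
  cand <- sort(unique(p))
  sens <- vapply(cand, function(t) mean(p[truth == 1] >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(p[truth == 0] < t), numeric(1))
  lo <- pmin(sens, spec)
  best <- which(lo == max(lo))
  gap <- abs(sens - spec)[best]
  best <- best[gap == min(gap)]
  cand[best[which.min(cand[best])]]
}

# best label matching of a hard clustering against truth (small c: all
# permutations)
bestMatchAccuracy <- function(cluster, truthLabels, c) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  best <- 0
  for (pm in perms(seq_len(c)))
    best <- max(best, mean(pm[cluster] == truthLabels))
  best
}
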