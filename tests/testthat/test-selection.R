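test_that("univariate AUC matches pair enumeration and folds orientation", {
  expect_equal(univariateAUC(1:6, c(0, 0, 0, 1, 1, 1)), 1.0)
  expect_equal(univariateAUC(6:1, c(0, 0, 0, 1, 1, 1)), 1.0)  # folded
  expect_equal(univariateAUC(rep(2, 8), rep(c(0, 1), 4)), 0.5)
  # all four positive-negative pairs enumerated by hand: one win, one loss
  # per positive -> 0.5
  expect_equal(univariateAUC(c(2, 1, 3, 4), c(0, 1, 0, 1)), 0.5)
  expect_error(univariateAUC(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(101)
  for (i in 1:200) {
    n <- sample(8:40, 1)
    p <- sample(0:9, n, replace = TRUE)   # ties likely
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- pairCountAUC(p, y)
    expect_equal(univariateAUC(p, y), max(a, 1 - a), tolerance = 1e-12)
  }
})

test_that("correlation filter drops the lower-ranked member of violating pairs", {
  # forced rule: r = 0.9, the 0.60-ranked predictor goes
  assoc <- matrix(c(1, 0.9, 0.9, 1), 2, 2,
                  dimnames = list(c("A", "B"), c("A", "B")))
  out <- correlationFilter(NULL, ranking = c(A = 0.70, B = 0.60),
                           cap = 0.75, assoc = assoc)
  expect_equal(out$kept, "A")
  expect_equal(out$dropped$dropped, "B")
  expect_equal(out$dropped$r, 0.9)

  # no violation: set unchanged
  assoc2 <- diag(3); assoc2[assoc2 == 0] <- 0.2
  dimnames(assoc2) <- list(c("A", "B", "C"), c("A", "B", "C"))
  out2 <- correlationFilter(NULL, ranking = c(A = 0.7, B = 0.6, C = 0.5),
                            cap = 0.75, assoc = assoc2)
  expect_equal(out2$kept, c("A", "B", "C"))

  # chained violations: dropping the hub predictor B keeps {A, C}; matches
  # the exhaustive subset oracle (max summed ranking among feasible sets)
  assoc3 <- matrix(c(1, 0.8, 0.1,
                     0.8, 1, 0.8,
                     0.1, 0.8, 1), 3, 3,
                   dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  ranking3 <- c(A = 0.70, B = 0.55, C = 0.65)
  out3 <- correlationFilter(NULL, ranking = ranking3, cap = 0.75,
                            assoc = assoc3)
  subsets <- unlist(lapply(1:3, function(k)
    combn(names(ranking3), k, simplify = FALSE)), recursive = FALSE)
  feasible <- Filter(function(s) {
    a <- assoc3[s, s, drop = FALSE]; diag(a) <- 0; all(a < 0.75)
  }, subsets)
  bestSubset <- feasible[[which.max(vapply(feasible, function(s)
    sum(ranking3[s]), numeric(1)))]]
  expect_setequal(out3$kept, bestSubset)
  expect_setequal(out3$kept, c("A", "C"))

  expect_error(correlationFilter(NULL, c(A = 1), cap = 1.5), "cap")
})

test_that("correlation filter output always satisfies the cap", {
  set.seed(77)
  for (i in 1:25) {
    k <- sample(4:8, 1)
    X <- matrix(rnorm(60 * k), 60, k) %*% matrix(rnorm(k * k), k, k)
    colnames(X) <- paste0("P", seq_len(k))
    assoc <- abs(stats::cor(X))
    ranking <- stats::setNames(runif(k, 0.5, 1), colnames(X))
    out <- correlationFilter(NULL, ranking, cap = 0.75, assoc = assoc)
    a <- assoc[out$kept, out$kept, drop = FALSE]
    diag(a) <- 0
    expect_lt(max(a, 0), 0.75)
  }
})

test_that("PCA representatives follow the correlation structure", {
  set.seed(5)
  n <- 200
  a <- rnorm(n)
  d <- data.frame(cell_id = 1:n, x = 1, y = 1:n,
                  P1 = a, P2 = a, P3 = rnorm(n), K = rep(1, n))
  meta <- data.frame(name = c("P1", "P2", "P3", "K"),
                     category = "climate", kind = "continuous", units = "-")
  g <- predictorGrid(d, meta)

  one <- pcaRepresentatives(g, "P3")
  expect_equal(one$representatives, "P3")
  expect_equal(one$varianceFraction, 1.0)

  # duplicated pair loads PC1; the independent column owns PC2
  out <- pcaRepresentatives(g, c("P1", "P2", "P3"), nComponents = 2)
  expect_true(out$representatives[1] %in% c("P1", "P2"))
  expect_equal(out$representatives[2], "P3")
  # eigenstructure of the 3x3 correlation matrix: the duplicated pair
  # carries 2/3 of the variance, the independent column 1/3, up to the
  # finite-sample correlation between them
  expect_equal(out$varianceFraction[1], 2 / 3, tolerance = 0.05)
  expect_equal(out$varianceFraction[2], 1 / 3, tolerance = 0.05)
  expect_lt(out$varianceFraction[2], out$varianceFraction[1])

  expect_error(pcaRepresentatives(g, c("P1", "K")), "constant")
})

test_that("mixed-type association behaves like |r| on a common scale", {
  w <- tinyWorld()
  m <- associationMatrix(w$grid, c("AnnTMean", "Tmax", "RtypMost", "Lusemax"))
  expect_true(all(m >= 0 & m <= 1 + 1e-9))
  expect_equal(m, t(m))
  expect_equal(m["AnnTMean", "Tmax"],
               abs(stats::cor(w$grid@data$AnnTMean, w$grid@data$Tmax)))
  # a factor against itself is a perfect association
  g <- w$grid
  expect_equal(.cramersV(g@data$RtypMost, g@data$RtypMost), 1,
               tolerance = 1e-9)
})

test_that("three-criteria relevance rule counts and thresholds exactly", {
  s <- data.frame(predictor = c("a", "b", "c", "d"),
                  roc = c(0.65, 0.649, 0.55, 0.70),
                  pi = c(5.0, 4.99, 1.0, 6.0),
                  n_selected = c(19, 18, 20, 5))
  out <- selectRelevantPredictors(s, nSpecies = 38)
  # boundaries are inclusive: roc 0.65, pi 5, n 19 = ceiling(38/2) all pass
  expect_equal(out$criteria_passed, c(3L, 0L, 1L, 2L))
  expect_equal(out$relevant, c(TRUE, FALSE, FALSE, TRUE))
  # odd species count rounds the half criterion up
  out39 <- selectRelevantPredictors(s, nSpecies = 39)
  expect_equal(out39$criteria_passed[1], 2L)  # 19 < ceiling(39/2) = 20
  expect_error(selectRelevantPredictors(s[, 1:3], 38), "columns")
})
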