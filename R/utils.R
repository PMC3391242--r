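# Internal helpers shared across modules.

# Deterministic 31-bit seed derived from a master seed and a path of labels,
# so repetition/engine/species fits never share a stream by accident.
deriveSeed <- function(master, ...) {
  parts <- paste(c(master, ...), collapse = "/")
  h <- as.numeric(master) %% 2147483647
  for (code in utf8ToInt(parts)) h <- (h * 31 + code) %% 2147483647
  as.integer(h)
}

# Row-normalised Gaussian weight matrix for 1-d smoothing on a lattice axis.
.gaussBand <- function(n, sigma) {
  i <- seq_len(n)
  w <- exp(-outer(i, i, "-")^2 / (2 * sigma^2))
  w / rowSums(w)
}

# Smooth standardised random field on an ny x nx lattice, returned as an
# ny*nx vector in row-major cell order (x fastest). Consumes RNG state.
smoothField <- function(nx, ny, sigma) {
  z <- matrix(stats::rnorm(nx * ny), nrow = ny, ncol = nx)
  if (sigma > 0) z <- .gaussBand(ny, sigma) %*% z %*% t(.gaussBand(nx, sigma))
  v <- as.vector(t(z))        # row-major: cell k -> (row, col)
  (v - mean(v)) / stats::sd(v)
}

# Affine transform of a field to an exact target mean and an approximate
# target range (scale chosen so observed span maps onto the target span).
rescaleField <- function(z, mean, min, max) {
  s <- (max - min) / diff(range(z))
  z2 <- z * s
  z2 - mean(z2) + mean
}

.standardise <- function(z) (z - mean(z)) / stats::sd(z)

# Standardised residual of x on a set of basis vectors (empirical
# orthogonalisation). Smooth spatial fields have few effective degrees of
# freedom, so two independent draws can correlate strongly by chance; the
# generator therefore composes its fields from empirically orthogonalised
# components with exact mixing weights instead of relying on expectation.
.ortho <- function(x, basis) {
  B <- cbind(1, do.call(cbind, basis))
  .standardise(stats::lm.fit(B, x)$residuals)
}

# Standardised field with an exact empirical correlation `rho` against a
# standardised anchor.
.withCor <- function(field, anchor, rho) {
  a <- .standardise(anchor)
  perp <- .ortho(.standardise(field), list(a))
  rho * a + sqrt(1 - rho^2) * perp
}

.checkBinary <- function(truth) {
  u <- unique(truth)
  if (!all(u %in% c(0, 1))) stop("truth must be binary 0/1")
  if (length(u) < 2L) stop("truth must contain both classes")
  invisible(TRUE)
}

.alignMaps <- function(a, b) {
  if (length(cellIds(a)) != length(cellIds(b)) ||
      any(cellIds(a) != cellIds(b)))
    stop("maps are not aligned to the same cell set")
  invisible(TRUE)
}
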