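#' Generate a synthetic atlas-style predictor grid
#'
#' Builds a rectangular lattice of grid cells carrying spatially smooth,
#' partially correlated environmental fields that emulate a temperate
#' grid-cell atlas at the ~11 km scale grain: a north--south temperature
#' gradient tied to a positively skewed altitude field, precipitation
#' increasing with altitude, a right-skewed cumulative upstream river length,
#' an ordinal Strahler-order field derived from it, a ~10-level categorical
#' river-type field, and two anthropogenic predictors (dominant land use,
#' population density). Continuous fields are low-order trends plus
#' Gaussian-smoothed noise; the climate fields are calibrated so their grid
#' means match a 20th-century central-European baseline (annual mean
#' temperature 8.4 degC, annual precipitation 732.1 mm, ...), which makes the
#' bundled change scenarios of [defaultScenarios()] directly applicable.
#'
#' A designated "independent core" of predictors (see [corePredictors()]) is
#' constructed to keep all pairwise Pearson correlations below `corrCap`;
#' the remaining climate fields are deliberately collinear with a core field
#' (e.g. maximum temperature with annual mean temperature), providing
#' realistic material for [correlationFilter()].
#'
#' @param nCells number of grid cells (>= 10).
#' @param dims optional `c(nx, ny)` lattice dimensions; `nx * ny` must be at
#'   least `nCells` (trailing cells are dropped, mirroring cells excluded for
#'   missing environmental data). Default: near-square lattice.
#' @param corrCap upper bound (exclusive) on pairwise |r| within the core
#'   predictor set, in (0, 1].
#' @param smoothness Gaussian smoothing radius of the noise component, in
#'   cell units; `NULL` (default) scales it with the lattice so small test
#'   grids keep enough effective degrees of freedom. Purely a generator
#'   knob: real atlases do not state their spatial autocorrelation, so this
#'   is exposed rather than claimed.
#' @param seed integer seed; the output is deterministic given
#'   `(nCells, dims, corrCap, smoothness, seed)`.
#' @return A [PredictorGrid-class] with 15 predictors.
#' @examples
#' g <- generatePredictorGrid(nCells = 400, seed = 1)
#' g
#' @export
generatePredictorGrid <- function(nCells = 2935, dims = NULL, corrCap = 0.75,
                                  smoothness = NULL, seed = 1) {
  if (nCells < 10) stop("nCells must be at least 10")
  if (corrCap <= 0 || corrCap > 1) stop("corrCap must lie in (0, 1]")
  if (is.null(dims)) {
    nx <- ceiling(sqrt(nCells))
    ny <- ceiling(nCells / nx)
    dims <- c(nx, ny)
  }
  if (length(dims) != 2 || any(dims < 1) || prod(dims) < nCells)
    stop("dims must be c(nx, ny) with nx * ny >= nCells")
  nx <- dims[1]; ny <- dims[2]
  if (is.null(smoothness)) smoothness <- max(1.5, min(nx, ny) / 14)
  set.seed(seed)
  keep <- seq_len(nCells)
  # row-major cell order: x fastest, y = row (north at large y)
  xs <- ((keep - 1L) %% nx) + 1L
  ys <- ((keep - 1L) %/% nx) + 1L

  sf <- function(sigmaMult = 1) smoothField(nx, ny, smoothness * sigmaMult)[keep]
  lat <- .standardise(ys)              # northing
  lon <- .standardise(xs)              # easting

  # topography: high in the south, positively skewed
  altRaw <- .standardise(1.6 * .standardise((max(ys) - ys)^2) + sf(1.5))
  AltMean <- rescaleField(exp(0.9 * altRaw), mean = 320, min = 5, max = 2900)
  altS <- .standardise(AltMean)

  # Core fields are exact linear mixes of altitude, the (altitude-
  # orthogonalised) lattice trends and mutually orthogonalised noise
  # components, so every core pairwise correlation is pinned by
  # construction and stays below the cap at every seed; the monotone skew
  # transforms applied afterwards perturb it only mildly.
  latO <- .ortho(lat, list(altS))
  lonO <- .ortho(lon, list(altS, latO))
  base <- list(altS, latO, lonO)
  nz <- list()
  for (i in 1:7) {
    nz[[i]] <- .ortho(sf(), c(base, nz))
  }
  tRaw <- -0.45 * altS + 0.30 * latO + sqrt(1 - 0.45^2 - 0.30^2) * nz[[1]]
  AnnTMean <- rescaleField(-exp(-0.5 * tRaw), mean = 8.4, min = 2.5, max = 10.4)
  tS <- .standardise(AnnTMean)

  isoRaw <- nz[[2]]
  Isotherm <- rescaleField(isoRaw, mean = 3.1, min = 2.3, max = 3.5)

  tsRaw <- 0.50 * lonO + sqrt(1 - 0.50^2) * nz[[3]]
  TSeason <- rescaleField(exp(0.4 * tsRaw), mean = 63.7, min = 54.5, max = 76.8)

  pRaw <- 0.45 * altS + sqrt(1 - 0.45^2) * nz[[4]]
  AnnPMean <- rescaleField(exp(0.55 * pRaw),
                           mean = 732.1, min = 482.4, max = 1414.1)

  psRaw <- 0.30 * pRaw + sqrt(1 - 0.30^2) * nz[[5]]
  PSeason <- rescaleField(exp(0.5 * psRaw), mean = 20.7, min = 9.5, max = 37.1)

  # deliberately collinear climate fields (candidates for correlation
  # capping), anchored above the cap on their core partner
  Tmax <- rescaleField(.withCor(0.35 * .standardise(TSeason) + 0.2 * sf(),
                                tS, 0.88),
                       mean = 22.7, min = 19.4, max = 25.5)
  TWetQuar <- rescaleField(.withCor(sf(), tS, 0.90),
                           mean = 15.5, min = 7.6, max = 18.9)
  TDryQuar <- rescaleField(.withCor(sf(), tS, 0.85),
                           mean = 2.0, min = -4.5, max = 6.8)
  DiuTRange <- rescaleField(.withCor(sf(), .standardise(Isotherm), 0.88),
                            mean = 7.9, min = 6.1, max = 9.6)

  # hydromorphology: cumulative upstream length, Strahler order, river type
  cRaw <- -0.30 * altS + sqrt(1 - 0.30^2) *
    .ortho(0.55 * sf() + 0.6 * sf(0.5), c(base, nz))
  CumLenkm <- rescaleField(exp(1.1 * cRaw), mean = 280, min = 1, max = 2300)

  strLatent <- .withCor(stats::rnorm(nCells), cRaw, 0.70)
  strProps <- c(0.06, 0.13, 0.18, 0.20, 0.17, 0.12, 0.08, 0.04, 0.02)
  strBreaks <- stats::quantile(strLatent, probs = cumsum(strProps)[-9])
  Strahler <- as.integer(findInterval(strLatent, strBreaks) + 1L)

  rtLevels <- c("alpine", "foothill", "siliceous_highland",
                "calcareous_highland", "gravel", "sand", "organic",
                "loess_loam", "marsh", "floodplain")
  # altitude tilts the river-type mosaic without duplicating it: the field
  # must stay usable alongside AltMean under the correlation cap
  rtLatent <- .withCor(sf(), altS, 0.40)
  rtBreaks <- stats::quantile(rtLatent, probs = seq(0.1, 0.9, by = 0.1))
  # high-altitude decile -> alpine, lowest -> floodplain
  RtypMost <- factor(rtLevels[10L - findInterval(rtLatent, rtBreaks)],
                     levels = rtLevels)

  luLevels <- c("urban", "agriculture", "forest", "grassland",
                "freshwater", "wetland", "other")
  luProps <- c(0.07, 0.45, 0.30, 0.11, 0.04, 0.02, 0.01)
  luLatent <- .withCor(sf(0.75), altS, -0.35)
  luBreaks <- stats::quantile(luLatent, probs = cumsum(luProps)[-7])
  Lusemax <- factor(luLevels[findInterval(luLatent, luBreaks) + 1L],
                    levels = luLevels)

  popRaw <- .withCor(sf(0.75), altS, -0.25)
  Popmean <- rescaleField(exp(1.2 * popRaw), mean = 240, min = 10, max = 2000)

  data <- data.frame(
    cell_id = keep, x = xs, y = ys,
    AnnTMean = AnnTMean, DiuTRange = DiuTRange, Isotherm = Isotherm,
    TSeason = TSeason, Tmax = Tmax, TWetQuar = TWetQuar,
    TDryQuar = TDryQuar, AnnPMean = AnnPMean, PSeason = PSeason,
    AltMean = AltMean, CumLenkm = CumLenkm, Strahler = Strahler,
    RtypMost = RtypMost, Lusemax = Lusemax, Popmean = Popmean)
  meta <- data.frame(
    name = c("AnnTMean", "DiuTRange", "Isotherm", "TSeason", "Tmax",
             "TWetQuar", "TDryQuar", "AnnPMean", "PSeason", "AltMean",
             "CumLenkm", "Strahler", "RtypMost", "Lusemax", "Popmean"),
    category = c(rep("climate", 9), "topography",
                 rep("hydromorphology", 3), rep("anthropogenic", 2)),
    kind = c(rep("continuous", 11), "ordinal", "categorical", "categorical",
             "continuous"),
    units = c("degC", "degC", "-", "degC^2", "degC", "degC", "degC", "mm",
              "-", "m", "km", "-", "-", "-", "inhabitants/km^2"),
    stringsAsFactors = FALSE)
  grid <- new("PredictorGrid", data = data, meta = meta)

  core <- corePredictors()
  cm <- abs(stats::cor(data[core[core %in% names(data)]]))
  diag(cm) <- 0
  if (max(cm) >= corrCap)
    warning(sprintf("core predictor correlation %.2f exceeds cap %.2f",
                    max(cm), corrCap))
  grid
}

#' Designated independent core predictors of the synthetic grid
#'
#' The continuous predictors the generator constructs to satisfy the
#' pairwise correlation cap among themselves. The remaining climate fields
#' are intentionally collinear with one of these.
#' @return character vector of predictor names.
#' @export
corePredictors <- function() {
  c("AnnTMean", "Isotherm", "TSeason", "AnnPMean", "PSeason",
    "AltMean", "CumLenkm", "Popmean")
}

#' True occupancy probability of a virtual species
#'
#' Evaluates the logistic niche of a [NicheSpec-class] cell by cell:
#' `plogis(intercept + sum_j linear_j x_j + sum_j quadratic_j x_j^2 +
#' categorical level offsets)`.
#'
#' @param niche a [NicheSpec-class].
#' @param grid a [PredictorGrid-class].
#' @return numeric vector of probabilities, one per cell.
#' @export
nicheProbability <- function(niche, grid) {
  stats::plogis(.nicheLinearPredictor(niche, grid))
}

.nicheLinearPredictor <- function(niche, grid) {
  stopifnot(is(niche, "NicheSpec"), is(grid, "PredictorGrid"))
  used <- unique(c(names(niche@linear), names(niche@quadratic),
                   names(niche@categorical)))
  unknown <- setdiff(used, predictorNames(grid))
  if (length(unknown))
    stop("niche references unknown predictor(s): ",
         paste(unknown, collapse = ", "))
  lp <- rep(niche@intercept, nCells(grid))
  for (p in names(niche@linear))
    lp <- lp + niche@linear[[p]] * as.numeric(grid@data[[p]])
  for (p in names(niche@quadratic))
    lp <- lp + niche@quadratic[[p]] * as.numeric(grid@data[[p]])^2
  for (p in names(niche@categorical)) {
    off <- niche@categorical[[p]]
    lev <- as.character(grid@data[[p]])
    lp <- lp + ifelse(lev %in% names(off), off[lev], 0)
  }
  lp
}

#' Simulate virtual species occurrences on a predictor grid
#'
#' Draws per-cell Bernoulli presences from each species' true logistic
#' occupancy probability and returns both the binary occurrence table and
#' the exact probability map, which downstream tests use as ground truth
#' (e.g. to compute the attainable Bayes AUC).
#'
#' @param grid a [PredictorGrid-class].
#' @param niches non-empty list of [NicheSpec-class] objects.
#' @param seed integer seed; presences are deterministic given it.
#' @return list with `occurrences` ([OccurrenceTable-class]) and `truth`
#'   (cells x species matrix of probabilities).
#' @export
simulateSpecies <- function(grid, niches, seed = 1) {
  stopifnot(is(grid, "PredictorGrid"))
  if (!length(niches)) stop("niches must be non-empty")
  codes <- unname(vapply(niches, function(n) n@species_code, character(1)))
  truth <- vapply(niches, nicheProbability, grid = grid,
                  FUN.VALUE = numeric(nCells(grid)))
  colnames(truth) <- codes
  set.seed(seed)
  occ <- apply(truth, 2L, function(p) stats::rbinom(length(p), 1L, p))
  colnames(occ) <- codes
  list(occurrences = occurrenceTable(cellIds(grid), occ), truth = truth)
}

#' Apply a climate-shift scenario to a predictor grid
#'
#' Returns a new grid with `value' = value * scale + delta` for every
#' predictor named in the [ShiftSpec-class]; the baseline grid is left
#' unmodified. Only continuous and ordinal predictors may be shifted.
#'
#' @param grid a [PredictorGrid-class].
#' @param shift a [ShiftSpec-class].
#' @return a shifted [PredictorGrid-class].
#' @export
applyClimateShift <- function(grid, shift) {
  stopifnot(is(grid, "PredictorGrid"), is(shift, "ShiftSpec"))
  touched <- union(names(shift@delta), names(shift@scale))
  unknown <- setdiff(touched, predictorNames(grid))
  if (length(unknown))
    stop("shift references unknown predictor(s): ",
         paste(unknown, collapse = ", "))
  meta <- predictorMeta(grid)
  kinds <- meta$kind[match(touched, meta$name)]
  if (any(kinds == "categorical"))
    stop("categorical predictors cannot be shifted: ",
         paste(touched[kinds == "categorical"], collapse = ", "))
  data <- grid@data
  for (p in touched) {
    sc <- if (p %in% names(shift@scale)) shift@scale[[p]] else 1
    de <- if (p %in% names(shift@delta)) shift@delta[[p]] else 0
    data[[p]] <- data[[p]] * sc + de
  }
  new("PredictorGrid", data = data, meta = meta)
}

#' Bundled 2050s climate-shift scenarios
#'
#' Three general-circulation-model scenarios (ECHAM5, HadCM3, IPSL-CM4 under
#' the SRES A1b storyline, 2040--2069) expressed as additive shifts of the
#' bioclimatic predictors relative to the 20th-century baseline the
#' synthetic grid is calibrated to: e.g. annual mean temperature +2.4 degC
#' (ECHAM5) or +2.7 degC (HadCM3, IPSL-CM4) on a baseline mean of 8.4 degC,
#' and annual precipitation decreasing by 15.8--18.7 mm.
#'
#' @return named list of three [ShiftSpec-class] objects.
#' @examples
#' defaultScenarios()[["ECHAM5"]]
#' @export
defaultScenarios <- function() {
  list(
    ECHAM5 = shiftSpec("ECHAM5-A1b-2050s", delta = c(
      AnnTMean = 2.4, Isotherm = 0.1, TSeason = -1.0, AnnPMean = -15.8,
      Tmax = 2.8, PSeason = -5.7)),
    HADCM3 = shiftSpec("HADCM3-A1b-2050s", delta = c(
      AnnTMean = 2.7, Isotherm = 0.0, TSeason = 3.1, AnnPMean = -16.8,
      Tmax = 4.1, PSeason = -3.5)),
    `IPSL-CM4` = shiftSpec("IPSL-CM4-A1b-2050s", delta = c(
      AnnTMean = 2.7, Isotherm = 0.0, TSeason = 1.6, AnnPMean = -18.7,
      Tmax = 3.2, PSeason = 1.8)))
}

# Solve the niche intercept so the mean occupancy over the grid hits a
# target prevalence.
.solveIntercept <- function(niche, grid, prevalence) {
  f <- function(b0) {
    niche@intercept <- b0
    mean(nicheProbability(niche, grid)) - prevalence
  }
  lp <- .nicheLinearPredictor(niche, grid) - niche@intercept
  stats::uniroot(f, interval = c(-max(lp) - 40, -min(lp) + 40),
                 tol = 1e-10)$root
}

#' Default virtual species set
#'
#' Six virtual species spanning the thermal-response spectrum: two
#' cold-adapted (declining occupancy with annual mean temperature, one with
#' a unimodal cold optimum), two warm-adapted, and two climate-neutral
#' species driven by hydromorphology and topography only. Coefficients are
#' expressed per standard deviation of the supplied grid's fields and the
#' intercepts are solved so each species hits its target prevalence, so all
#' six comfortably clear a `> 50` presence inclusion filter at atlas scale.
#' The thermal guild of each species is attached as `attr(, "guild")`.
#'
#' @param grid the [PredictorGrid-class] the niches are calibrated against.
#' @return named list of six [NicheSpec-class] objects.
#' @export
defaultNiches <- function(grid) {
  d <- grid@data
  sdT <- stats::sd(d$AnnTMean); mT <- mean(d$AnnTMean)
  sdA <- stats::sd(d$AltMean)
  sdS <- stats::sd(d$Strahler)
  sdC <- stats::sd(d$CumLenkm)
  mA <- stats::median(d$AltMean)

  quadCoefs <- function(a, x0, sdx) {
    # -(a/sdx^2) * (x - x0)^2, constant absorbed by the intercept
    c(linear = 2 * a * x0 / sdx^2, quadratic = -a / sdx^2)
  }
  qc <- quadCoefs(2.0, mT - 1.5 * sdT, sdT)
  qa <- quadCoefs(3.0, mA, sdA)

  niches <- list(
    Frigusten = nicheSpec("Frigusten",
      linear = c(AnnTMean = -2.2 / sdT, AltMean = 0.8 / sdA)),
    Frigmonta = nicheSpec("Frigmonta",
      linear = c(AnnTMean = qc[["linear"]], Strahler = -0.5 / sdS),
      quadratic = c(AnnTMean = qc[["quadratic"]])),
    Thermexpa = nicheSpec("Thermexpa",
      linear = c(AnnTMean = 2.2 / sdT, CumLenkm = 0.9 / sdC)),
    Thermfluv = nicheSpec("Thermfluv",
      linear = c(AnnTMean = 1.8 / sdT, Strahler = 0.8 / sdS),
      categorical = list(RtypMost = c(sand = 1.2, loess_loam = 1.2,
                                      alpine = -1.2))),
    Neutrstra = nicheSpec("Neutrstra",
      linear = c(Strahler = 1.5 / sdS, CumLenkm = 1.0 / sdC,
                 AltMean = -0.6 / sdA)),
    Neutrsubs = nicheSpec("Neutrsubs",
      linear = c(AltMean = qa[["linear"]], Strahler = 1.2 / sdS),
      quadratic = c(AltMean = qa[["quadratic"]]),
      categorical = list(RtypMost = c(gravel = 1.4, sand = 1.4,
                                      organic = -1.0, marsh = -1.0))))
  prevalence <- c(Frigusten = 0.30, Frigmonta = 0.25, Thermexpa = 0.25,
                  Thermfluv = 0.30, Neutrstra = 0.40, Neutrsubs = 0.35)
  for (nm in names(niches))
    niches[[nm]]@intercept <- .solveIntercept(niches[[nm]], grid,
                                              prevalence[[nm]])
  attr(niches, "guild") <- c(Frigusten = "cold", Frigmonta = "cold",
                             Thermexpa = "warm", Thermfluv = "warm",
                             Neutrstra = "neutral", Neutrsubs = "neutral")
  niches
}
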