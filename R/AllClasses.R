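#' @import methods
NULL

#' PredictorGrid: grid cells by environmental predictors
#'
#' Tabular container for atlas-style grid data: one row per grid cell with an
#' integer cell id, lattice coordinates and one column per environmental
#' predictor, plus a per-predictor metadata table declaring its thematic
#' category (climate, topography, hydromorphology, anthropogenic) and
#' measurement kind (continuous, ordinal, categorical).
#'
#' Validity requires unique cell ids, no missing predictor values (cells with
#' gaps are expected to be dropped on load), exactly one metadata row per
#' predictor column, and declared finite level sets for categorical columns
#' (stored as factors).
#'
#' @slot data data.frame with columns `cell_id`, `x`, `y` and one column per
#'   predictor (numeric, integer or factor).
#' @slot meta data.frame with columns `name`, `category`, `kind`, `units`.
#' @export
setClass("PredictorGrid",
  slots = c(data = "data.frame", meta = "data.frame"))

.validPredictorGrid <- function(object) {
  msg <- character()
  d <- object@data
  m <- object@meta
  need <- c("cell_id", "x", "y")
  if (!all(need %in% names(d)))
    return("data must contain columns cell_id, x, y")
  if (anyDuplicated(d$cell_id))
    msg <- c(msg, "cell_id values must be unique")
  predCols <- setdiff(names(d), need)
  if (!all(c("name", "category", "kind", "units") %in% names(m)))
    return("meta must have columns name, category, kind, units")
  if (!setequal(m$name, predCols) || anyDuplicated(m$name))
    msg <- c(msg, "meta must have exactly one row per predictor column")
  okCat <- c("climate", "topography", "hydromorphology", "anthropogenic")
  if (!all(m$category %in% okCat))
    msg <- c(msg, sprintf("category must be one of %s",
                          paste(okCat, collapse = ", ")))
  okKind <- c("continuous", "ordinal", "categorical")
  if (!all(m$kind %in% okKind))
    msg <- c(msg, sprintf("kind must be one of %s",
                          paste(okKind, collapse = ", ")))
  for (p in intersect(m$name, predCols)) {
    k <- m$kind[match(p, m$name)]
    col <- d[[p]]
    if (anyNA(col)) msg <- c(msg, sprintf("predictor '%s' has missing values", p))
    if (k == "categorical" && !is.factor(col))
      msg <- c(msg, sprintf("categorical predictor '%s' must be a factor", p))
    if (k != "categorical" && !is.numeric(col))
      msg <- c(msg, sprintf("%s predictor '%s' must be numeric", k, p))
  }
  if (length(msg)) msg else TRUE
}
setValidity("PredictorGrid", .validPredictorGrid)

#' Construct a PredictorGrid
#'
#' @param data data.frame with `cell_id`, `x`, `y` and predictor columns.
#' @param meta data.frame with `name`, `category`, `kind`, `units` (one row
#'   per predictor column). Rows of `data` with missing predictor values are
#'   dropped with a message, mirroring the exclusion of cells lacking
#'   environmental information.
#' @return A [PredictorGrid-class] object.
#' @export
predictorGrid <- function(data, meta) {
  stopifnot(is.data.frame(data), is.data.frame(meta))
  meta$name <- as.character(meta$name)
  predCols <- setdiff(names(data), c("cell_id", "x", "y"))
  cc <- stats::complete.cases(data[predCols])
  if (!all(cc)) {
    message(sum(!cc), " cell(s) dropped due to missing predictor values")
    data <- data[cc, , drop = FALSE]
    rownames(data) <- NULL
  }
  new("PredictorGrid", data = data, meta = meta)
}

#' OccurrenceTable: binary species presence per grid cell
#'
#' @slot cell_id integer vector of cell ids (matching a PredictorGrid).
#' @slot occ integer matrix, cells x species, values 0/1, column names are
#'   species codes.
#' @export
setClass("OccurrenceTable",
  slots = c(cell_id = "integer", occ = "matrix"))

setValidity("OccurrenceTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@cell_id)) msg <- c(msg, "cell_id must be unique")
  if (nrow(object@occ) != length(object@cell_id))
    msg <- c(msg, "occ must have one row per cell")
  if (is.null(colnames(object@occ)) && ncol(object@occ) > 0)
    msg <- c(msg, "occ columns must be named by species code")
  if (!all(object@occ %in% c(0L, 1L)))
    msg <- c(msg, "occ values must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct an OccurrenceTable
#'
#' @param cell_id integer cell ids.
#' @param occ cells x species matrix of 0/1 values, columns named by species
#'   code.
#' @export
occurrenceTable <- function(cell_id, occ) {
  occ <- as.matrix(occ)
  storage.mode(occ) <- "integer"
  new("OccurrenceTable", cell_id = as.integer(cell_id), occ = occ)
}

#' NicheSpec: a virtual species' logistic niche
#'
#' The true occupancy probability of a virtual species is
#' `plogis(intercept + sum(linear * x) + sum(quadratic * x^2) + categorical
#' offsets)`, evaluated cell by cell on a paired [PredictorGrid-class].
#'
#' @slot species_code character scalar.
#' @slot intercept numeric scalar on the logit scale.
#' @slot linear named numeric, predictor -> linear coefficient.
#' @slot quadratic named numeric, predictor -> quadratic coefficient
#'   (negative values give unimodal responses).
#' @slot categorical named list, predictor -> named numeric of per-level
#'   logit offsets.
#' @export
setClass("NicheSpec",
  slots = c(species_code = "character", intercept = "numeric",
            linear = "numeric", quadratic = "numeric",
            categorical = "list"))

setValidity("NicheSpec", function(object) {
  msg <- character()
  if (length(object@species_code) != 1L) msg <- c(msg, "species_code must be scalar")
  if (length(object@intercept) != 1L) msg <- c(msg, "intercept must be scalar")
  if (length(object@linear) && is.null(names(object@linear)))
    msg <- c(msg, "linear coefficients must be named by predictor")
  if (length(object@quadratic) && is.null(names(object@quadratic)))
    msg <- c(msg, "quadratic coefficients must be named by predictor")
  if (length(object@categorical)) {
    if (is.null(names(object@categorical)))
      msg <- c(msg, "categorical offsets must be named by predictor")
    bad <- !vapply(object@categorical,
                   function(v) is.numeric(v) && !is.null(names(v)), logical(1))
    if (any(bad)) msg <- c(msg, "categorical offsets must be named numerics")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a NicheSpec
#'
#' @param species_code species code string.
#' @param intercept logit-scale intercept.
#' @param linear named numeric of linear logit coefficients.
#' @param quadratic named numeric of quadratic logit coefficients.
#' @param categorical named list (predictor -> named numeric of level
#'   offsets).
#' @export
nicheSpec <- function(species_code, intercept = 0, linear = numeric(),
                      quadratic = numeric(), categorical = list()) {
  new("NicheSpec", species_code = species_code,
      intercept = as.numeric(intercept), linear = linear,
      quadratic = quadratic, categorical = categorical)
}

#' ShiftSpec: a climate-change scenario as predictor shifts
#'
#' A scenario is an affine change per predictor: `value' = value * scale +
#' delta`. Predictors not listed are unchanged; categorical predictors may
#' not be shifted.
#'
#' @slot scenario_name character scalar, e.g. "ECHAM5-A1b-2050s".
#' @slot delta named numeric of additive shifts.
#' @slot scale named numeric of multiplicative factors (default 1).
#' @export
setClass("ShiftSpec",
  slots = c(scenario_name = "character", delta = "numeric", scale = "numeric"))

setValidity("ShiftSpec", function(object) {
  msg <- character()
  if (length(object@scenario_name) != 1L)
    msg <- c(msg, "scenario_name must be scalar")
  if (length(object@delta) && is.null(names(object@delta)))
    msg <- c(msg, "delta must be named by predictor")
  if (length(object@scale) && is.null(names(object@scale)))
    msg <- c(msg, "scale must be named by predictor")
  if (length(msg)) msg else TRUE
})

#' Construct a ShiftSpec
#'
#' @param scenario_name scenario label.
#' @param delta named numeric of additive shifts per predictor.
#' @param scale named numeric of multiplicative factors per predictor.
#' @export
shiftSpec <- function(scenario_name, delta = numeric(), scale = numeric()) {
  new("ShiftSpec", scenario_name = scenario_name, delta = delta, scale = scale)
}

#' FittedSDM: one fitted niche-model engine
#'
#' @slot engine one of "GLM", "GAM", "RF", "ME".
#' @slot species_code species the model was fitted for.
#' @slot selected_predictors predictors retained by the engine's own
#'   selection (stepwise AIC, out-of-bag forward selection, or L1 shrinkage).
#' @slot fit engine-specific fitted object / parameter list.
#' @slot threshold decision threshold in (0,1); NA until calibrated.
#' @slot repetition_id split repetition index.
#' @slot seed integer seed the fit was made reproducible with.
#' @slot calibration_ranges named list predictor -> c(min, max) over the
#'   calibration cells (factor levels seen, for categorical predictors).
#' @export
setClass("FittedSDM",
  slots = c(engine = "character", species_code = "character",
            selected_predictors = "character", fit = "list",
            threshold = "numeric", repetition_id = "integer",
            seed = "integer", calibration_ranges = "list"))

setValidity("FittedSDM", function(object) {
  msg <- character()
  if (!object@engine %in% c("GLM", "GAM", "RF", "ME"))
    msg <- c(msg, "engine must be one of GLM, GAM, RF, ME")
  th <- object@threshold
  if (length(th) != 1L || (!is.na(th) && (th <= 0 || th > 1)))
    msg <- c(msg, "threshold must be a scalar in (0,1] or NA")
  if (length(msg)) msg else TRUE
})

#' ConsensusMap: majority-vote binary map over an ensemble
#'
#' Presence is 1 exactly when strictly more than half of the ensemble
#' members predict presence (ties on even ensembles fall to absence).
#'
#' @slot cell_id integer cell ids.
#' @slot presence integer 0/1 consensus indicator.
#' @slot vote_fraction numeric in [0,1], fraction of members voting presence.
#' @slot members character vector of member provenance labels.
#' @export
setClass("ConsensusMap",
  slots = c(cell_id = "integer", presence = "integer",
            vote_fraction = "numeric", members = "character"))

setValidity("ConsensusMap", function(object) {
  msg <- character()
  n <- length(object@cell_id)
  if (length(object@presence) != n || length(object@vote_fraction) != n)
    msg <- c(msg, "presence and vote_fraction must align with cell_id")
  if (!all(object@presence %in% c(0L, 1L)))
    msg <- c(msg, "presence must be 0/1")
  if (any(object@vote_fraction < 0 | object@vote_fraction > 1))
    msg <- c(msg, "vote_fraction must lie in [0,1]")
  if (any(object@presence != as.integer(object@vote_fraction > 0.5)))
    msg <- c(msg, "presence must equal vote_fraction > 0.5")
  if (length(msg)) msg else TRUE
})
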