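# Plain-text I/O: CSV tables with JSON/YAML sidecars.

#' Write / read a PredictorGrid as CSV plus JSON metadata sidecar
#'
#' The cell table goes to `<path>` as CSV with a header row; the
#' per-predictor metadata (category, kind, units, categorical level sets)
#' goes to `<path>.meta.json`.
#'
#' @param grid a [PredictorGrid-class].
#' @param path CSV file path.
#' @return `path`, invisibly.
#' @export
writePredictorGrid <- function(grid, path) {
  utils::write.csv(grid@data, path, row.names = FALSE)
  meta <- grid@meta
  levelSets <- lapply(stats::setNames(meta$name, meta$name), function(p)
    if (is.factor(grid@data[[p]])) levels(grid@data[[p]]) else NULL)
  jsonlite::write_json(list(predictors = meta,
                            levels = levelSets[!vapply(levelSets, is.null,
                                                       logical(1))]),
                       paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writePredictorGrid
#' @export
readPredictorGrid <- function(path) {
  data <- utils::read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".meta.json"),
                              simplifyVector = TRUE)
  meta <- as.data.frame(side$predictors)
  for (p in names(side$levels))
    data[[p]] <- factor(data[[p]], levels = side$levels[[p]])
  predictorGrid(data, meta)
}

#' Write / read an OccurrenceTable as CSV
#'
#' One `cell_id` column plus one 0/1 column per species code.
#'
#' @param occ an [OccurrenceTable-class].
#' @param path CSV file path.
#' @export
writeOccurrenceTable <- function(occ, path) {
  utils::write.csv(data.frame(cell_id = cellIds(occ),
                              occurrenceMatrix(occ), check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeOccurrenceTable
#' @export
readOccurrenceTable <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  occurrenceTable(d$cell_id, as.matrix(d[setdiff(names(d), "cell_id")]))
}

.nicheToList <- function(n) {
  list(species_code = n@species_code, intercept = n@intercept,
       linear = as.list(n@linear), quadratic = as.list(n@quadratic),
       categorical = lapply(n@categorical, as.list))
}

#' Write / read niche specifications as YAML
#'
#' @param niches list of [NicheSpec-class] objects.
#' @param path YAML file path.
#' @export
writeNicheSpecs <- function(niches, path) {
  yaml::write_yaml(lapply(niches, .nicheToList), path, precision = 15)
  invisible(path)
}

#' @rdname writeNicheSpecs
#' @export
readNicheSpecs <- function(path) {
  raw <- yaml::read_yaml(path)
  niches <- lapply(raw, function(r)
    nicheSpec(r$species_code, r$intercept,
              linear = unlist(r$linear) %||% numeric(),
              quadratic = unlist(r$quadratic) %||% numeric(),
              categorical = lapply(r$categorical, unlist)))
  names(niches) <- vapply(niches, function(n) n@species_code, character(1))
  niches
}

#' Write / read climate-shift scenarios as YAML
#'
#' @param shifts list of [ShiftSpec-class] objects.
#' @param path YAML file path.
#' @export
writeShiftSpecs <- function(shifts, path) {
  yaml::write_yaml(lapply(shifts, function(s)
    list(scenario_name = s@scenario_name, delta = as.list(s@delta),
         scale = as.list(s@scale))), path, precision = 15)
  invisible(path)
}

#' @rdname writeShiftSpecs
#' @export
readShiftSpecs <- function(path) {
  raw <- yaml::read_yaml(path)
  shifts <- lapply(raw, function(r)
    shiftSpec(r$scenario_name, delta = unlist(r$delta) %||% numeric(),
              scale = unlist(r$scale) %||% numeric()))
  names(shifts) <- vapply(shifts, function(s) s@scenario_name, character(1))
  shifts
}

#' Serialise a fitted model to JSON
#'
#' Writes the declared serialisation of a [FittedSDM-class]: engine,
#' species, selected predictors, threshold, seed, calibration ranges, and
#' engine-specific parameters — coefficient vectors for the GLM/GAM engines
#' (spline bases are declared by their term labels), feature weights and
#' standardisation constants for the ME engine, and seed plus
#' hyperparameters for the RF engine (a bagged forest is reproduced exactly
#' by regrowing it with [fitRF()] on the same calibration cells and seed,
#' which is far smaller than shipping 500 trees).
#'
#' @param model a [FittedSDM-class].
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
writeFittedSDM <- function(model, path) {
  fit <- model@fit
  params <- switch(fit$kind,
    glm = if (isTRUE(fit$ridge))
      list(type = "ridge", a0 = fit$a0,
           beta = as.list(stats::setNames(fit$beta, names(fit$center))),
           center = as.list(fit$center), scale = as.list(fit$scale))
    else list(type = "coefficients",
              coefficients = as.list(stats::coef(fit$model)),
              terms = attr(stats::terms(fit$model), "term.labels")),
    gam = list(type = "coefficients",
               coefficients = as.list(stats::coef(fit$model)),
               terms = attr(stats::terms(fit$model), "term.labels")),
    rf = list(type = "regrow", seed = model@seed, nTrees = fit$nTrees),
    maxent = list(type = "weights", lambda = as.list(fit$lambda),
                  normConst = fit$normConst, reg = fit$reg))
  jsonlite::write_json(list(
    engine = model@engine, species = model@species_code,
    repetition = model@repetition_id, seed = model@seed,
    selected_predictors = model@selected_predictors,
    threshold = model@threshold,
    calibration_ranges = model@calibration_ranges,
    parameters = params), path, auto_unbox = TRUE, digits = NA,
    force = TRUE)
  invisible(path)
}

#' Write a ConsensusMap as CSV
#'
#' Columns `cell_id`, `presence`, `vote_fraction`; the ensemble manifest
#' goes to `<path>.members.json`.
#'
#' @param map a [ConsensusMap-class].
#' @param path CSV file path.
#' @export
writeConsensusMap <- function(map, path) {
  utils::write.csv(data.frame(cell_id = cellIds(map),
                              presence = presence(map),
                              vote_fraction = voteFraction(map)),
                   path, row.names = FALSE)
  jsonlite::write_json(list(members = map@members),
                       paste0(path, ".members.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Write the report bundle of a pipeline run to a directory
#'
#' Emits the evaluation table, relevance report, response tables, change
#' summaries, mismatch reports and consensus maps as CSV, plus the run
#' manifest as JSON.
#'
#' @param bundle result of [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeReportBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.csv(x, file.path(dir, f),
                                       row.names = FALSE)
  w(bundle$evaluation, "evaluation.csv")
  w(bundle$relevance, "relevance.csv")
  for (eng in names(bundle$responseTables))
    w(bundle$responseTables[[eng]], sprintf("response_%s.csv", eng))
  for (sp in names(bundle$changeSummaries))
    w(bundle$changeSummaries[[sp]], sprintf("change_%s.csv", sp))
  for (sp in names(bundle$mismatchReports))
    w(bundle$mismatchReports[[sp]], sprintf("mismatch_%s.csv", sp))
  for (sp in names(bundle$consensusCurrent))
    writeConsensusMap(bundle$consensusCurrent[[sp]],
                      file.path(dir, sprintf("consensus_current_%s.csv", sp)))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
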