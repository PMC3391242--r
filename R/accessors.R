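#' @rdname PredictorGrid-class
#' @export
setMethod("cellIds", "PredictorGrid", function(x) x@data$cell_id)

#' @rdname OccurrenceTable-class
#' @export
setMethod("cellIds", "OccurrenceTable", function(x) x@cell_id)

#' @rdname ConsensusMap-class
#' @export
setMethod("cellIds", "ConsensusMap", function(x) x@cell_id)

#' @rdname PredictorGrid-class
#' @export
setMethod("nCells", "PredictorGrid", function(x) nrow(x@data))

#' @rdname PredictorGrid-class
#' @export
setMethod("predictorNames", "PredictorGrid", function(x) x@meta$name)

#' @rdname PredictorGrid-class
#' @export
setMethod("predictorMeta", "PredictorGrid", function(x) x@meta)

#' @rdname PredictorGrid-class
#' @export
setMethod("predictorData", "PredictorGrid", function(x, predictors = NULL) {
  if (is.null(predictors)) predictors <- predictorNames(x)
  missing <- setdiff(predictors, names(x@data))
  if (length(missing))
    stop("unknown predictor(s): ", paste(missing, collapse = ", "))
  x@data[predictors]
})

#' @rdname OccurrenceTable-class
#' @export
setMethod("speciesCodes", "OccurrenceTable", function(x) colnames(x@occ))

#' @rdname OccurrenceTable-class
#' @export
setMethod("occurrenceMatrix", "OccurrenceTable", function(x) x@occ)

#' @rdname OccurrenceTable-class
#' @export
setMethod("presenceCount", "OccurrenceTable", function(x) colSums(x@occ))

#' @rdname FittedSDM-class
#' @export
setMethod("engine", "FittedSDM", function(x) x@engine)

#' @rdname FittedSDM-class
#' @export
setMethod("threshold", "FittedSDM", function(x) x@threshold)

#' @rdname FittedSDM-class
#' @export
setMethod("threshold<-", "FittedSDM", function(x, value) {
  x@threshold <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname FittedSDM-class
#' @export
setMethod("selectedPredictors", "FittedSDM",
          function(x) x@selected_predictors)

#' @rdname FittedSDM-class
#' @export
setMethod("calibrationRanges", "FittedSDM", function(x) x@calibration_ranges)

#' @rdname ConsensusMap-class
#' @export
setMethod("presence", "ConsensusMap", function(x) x@presence)

#' @rdname ConsensusMap-class
#' @export
setMethod("voteFraction", "ConsensusMap", function(x) x@vote_fraction)

setMethod("show", "PredictorGrid", function(object) {
  m <- object@meta
  cat("PredictorGrid:", nrow(object@data), "cells,", nrow(m), "predictors\n")
  for (cat_ in unique(m$category))
    cat(sprintf("  %-15s %s\n", cat_,
                paste(m$name[m$category == cat_], collapse = ", ")))
  invisible(object)
})

setMethod("show", "OccurrenceTable", function(object) {
  cat("OccurrenceTable:", length(object@cell_id), "cells,",
      ncol(object@occ), "species\n")
  if (ncol(object@occ)) {
    freq <- round(colMeans(object@occ), 3)
    cat("  occurrence frequency:\n")
    print(freq)
  }
  invisible(object)
})

setMethod("show", "NicheSpec", function(object) {
  cat("NicheSpec for", object@species_code,
      "| intercept", signif(object@intercept, 3), "\n")
  if (length(object@linear))
    cat("  linear:   ", paste(names(object@linear),
        signif(object@linear, 3), sep = "=", collapse = ", "), "\n")
  if (length(object@quadratic))
    cat("  quadratic:", paste(names(object@quadratic),
        signif(object@quadratic, 3), sep = "=", collapse = ", "), "\n")
  if (length(object@categorical))
    cat("  categorical offsets on:",
        paste(names(object@categorical), collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "ShiftSpec", function(object) {
  cat("ShiftSpec", object@scenario_name, "\n")
  if (length(object@delta))
    cat("  delta:", paste(names(object@delta), signif(object@delta, 4),
        sep = "=", collapse = ", "), "\n")
  if (length(object@scale))
    cat("  scale:", paste(names(object@scale), signif(object@scale, 4),
        sep = "=", collapse = ", "), "\n")
  invisible(object)
})

setMethod("show", "FittedSDM", function(object) {
  cat(sprintf("FittedSDM [%s] %s (rep %d, seed %d)\n", object@engine,
              object@species_code, object@repetition_id, object@seed))
  cat("  predictors:", paste(object@selected_predictors, collapse = ", "), "\n")
  cat("  threshold:", if (is.na(object@threshold)) "not calibrated"
      else signif(object@threshold, 4), "\n")
  invisible(object)
})

setMethod("show", "ConsensusMap", function(object) {
  cat("ConsensusMap:", length(object@cell_id), "cells,",
      length(object@members), "ensemble members\n")
  cat("  predicted presences:", sum(object@presence), "\n")
  invisible(object)
})
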