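#' @rdname PredictorGrid-class
#' @param object,x a gridsdm object
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname PredictorGrid-class
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))

#' @rdname PredictorGrid-class
#' @export
setGeneric("predictorNames", function(x) standardGeneric("predictorNames"))

#' @rdname PredictorGrid-class
#' @export
setGeneric("predictorMeta", function(x) standardGeneric("predictorMeta"))

#' @rdname PredictorGrid-class
#' @param predictors optional character vector restricting the columns
#' @export
setGeneric("predictorData",
           function(x, predictors = NULL) standardGeneric("predictorData"))

#' @rdname OccurrenceTable-class
#' @export
setGeneric("speciesCodes", function(x) standardGeneric("speciesCodes"))

#' @rdname OccurrenceTable-class
#' @export
setGeneric("occurrenceMatrix", function(x) standardGeneric("occurrenceMatrix"))

#' @rdname OccurrenceTable-class
#' @export
setGeneric("presenceCount", function(x) standardGeneric("presenceCount"))

#' @rdname FittedSDM-class
#' @export
setGeneric("engine", function(x) standardGeneric("engine"))

#' @rdname FittedSDM-class
#' @export
setGeneric("threshold", function(x) standardGeneric("threshold"))

#' @rdname FittedSDM-class
#' @param value replacement value
#' @export
setGeneric("threshold<-", function(x, value) standardGeneric("threshold<-"))

#' @rdname FittedSDM-class
#' @export
setGeneric("selectedPredictors",
           function(x) standardGeneric("selectedPredictors"))

#' @rdname FittedSDM-class
#' @export
setGeneric("calibrationRanges",
           function(x) standardGeneric("calibrationRanges"))

#' @rdname ConsensusMap-class
#' @export
setGeneric("presence", function(x) standardGeneric("presence"))

#' @rdname ConsensusMap-class
#' @export
setGeneric("voteFraction", function(x) standardGeneric("voteFraction"))
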