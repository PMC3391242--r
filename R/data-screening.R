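#' Reference predictor screening summary
#'
#' A bundled screening summary for 15 environmental predictors evaluated
#' over 38 freshwater fish species on an ~11 km atlas grid: per predictor
#' the mean orientation-corrected univariate ROC score, the mean
#' permutation importance (percent) across the four engine families, and
#' the number of species whose fitted models retained the predictor. It is
#' the canonical input shape for [selectRelevantPredictors()] and is used
#' to exercise the three-criteria relevance rule at realistic values.
#'
#' @param nSpecies the species total the `n_selected` column refers to.
#' @return data.frame with columns `predictor`, `category`, `roc`, `pi`,
#'   `n_selected`; `nSpecies` is attached as an attribute.
#' @examples
#' s <- atlasScreeningSummary()
#' selectRelevantPredictors(s, nSpecies = attr(s, "nSpecies"))
#' @export
atlasScreeningSummary <- function(nSpecies = 38) {
  path <- system.file("extdata", "atlas_screening_summary.csv",
                      package = "gridsdm", mustWork = TRUE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  attr(d, "nSpecies") <- nSpecies
  d
}
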