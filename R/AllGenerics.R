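#' Number of retained events
#'
#' @param x an [EventTable-class] or [GatedPopulation-class].
#' @return integer scalar.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Event data accessor
#'
#' @param x an [EventTable-class].
#' @return the underlying `data.frame` of events.
#' @export
setGeneric("eventData", function(x) standardGeneric("eventData"))

#' Population keys of an event table
#'
#' @param x an [EventTable-class].
#' @return a `data.frame` with one row per population:
#'   `strain_id`, `condition_id`, `replicate_id`, `batch_id`, `n_events`.
#' @export
setGeneric("populationKeys", function(x) standardGeneric("populationKeys"))

#' DM residuals of a fitted noise trend
#'
#' @param object a [NoiseTrend-class].
#' @return a `data.frame` with columns `gene_id`, `condition_id`, `e`, `v`,
#'   `dm`.
#' @export
setGeneric("dmResiduals", function(object) standardGeneric("dmResiduals"))

#' Evaluate a fitted noise trend
#'
#' @param object a [NoiseTrend-class].
#' @param e numeric vector of mean values; beyond the fitted range the
#'   boundary trend value is returned (constant extrapolation).
#' @return numeric vector of expected SDs.
#' @export
setGeneric("trendValues", function(object, e) standardGeneric("trendValues"))

#' Curve table of a cumulative rank-scan
#'
#' @param object a [CumulativeCurve-class].
#' @return the curve `data.frame` (`cutoff`, `n_genes`, `mean_cov`, `se_cov`).
#' @export
setGeneric("curveTable", function(object) standardGeneric("curveTable"))

#' Planted truth of a simulated dataset
#'
#' @param object a [FlowSimulation-class].
#' @return the truth list (elements `genes`, `gene_condition`, `conditions`).
#' @export
setGeneric("simTruth", function(object) standardGeneric("simTruth"))
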