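#' EventTable: per-cell flow-cytometry events
#'
#' Container for list-mode flow-cytometry events in linear arbitrary units,
#' keyed by strain, condition, replicate and measurement batch.  A
#' *population* is the set of events sharing one
#' `(strain_id, condition_id, replicate_id)` triple; each population belongs
#' to exactly one batch (the acquisition date used to build FSC gates).
#'
#' @slot events a `data.frame` with character columns `strain_id`,
#'   `condition_id`, `replicate_id`, `batch_id` and numeric columns `fsc`,
#'   `ssc`, `yfp_raw` (linear a.u.; no log-amplifier transforms).
#'
#' @seealso [readEvents()], [writeEvents()], [applyGate()]
#' @export
setClass("EventTable", representation(events = "data.frame"))

.EVENT_COLS <- c("strain_id", "condition_id", "replicate_id", "batch_id",
                 "fsc", "ssc", "yfp_raw")

setValidity("EventTable", function(object) {
  ev <- object@events
  missing <- setdiff(.EVENT_COLS, names(ev))
  if (length(missing))
    return(paste0("missing column(s): ", paste(missing, collapse = ", ")))
  for (col in c("fsc", "ssc", "yfp_raw"))
    if (!is.numeric(ev[[col]]))
      return(paste0("column '", col, "' must be numeric"))
  if (nrow(ev)) {
    if (anyNA(ev$fsc) || anyNA(ev$ssc) || anyNA(ev$yfp_raw))
      return("fsc/ssc/yfp_raw must not contain NA")
    if (min(ev$fsc) < 0 || min(ev$ssc) < 0)
      return("fsc and ssc must be non-negative")
    if (min(ev$yfp_raw) < 0)
      return("yfp_raw must be non-negative")
    # one batch per population (data.table keeps this O(n) and light)
    keys <- unique(data.table::as.data.table(
      ev[c("strain_id", "condition_id", "replicate_id", "batch_id")]))
    if (anyDuplicated(keys[, c("strain_id", "condition_id",
                               "replicate_id")]))
      return("a (strain, condition, replicate) population must belong to exactly one batch")
  }
  TRUE
})

#' FscGate: a narrow forward-scatter gate
#'
#' A closed interval `[low, high]` on log10(FSC), centred on the mode of the
#' cumulative (all-strain) FSC distribution for one condition and batch.
#' The default half-width of 0.1 log10 units gives a gate exactly 0.2 wide.
#'
#' @slot condition_id,batch_id character scalars identifying the pooled
#'   population the gate was built from (`NA` when built standalone).
#' @slot mode_log10 numeric scalar, the estimated mode of log10 FSC.
#' @slot halfwidth positive numeric scalar (log10 units).
#' @slot low,high numeric scalars, `mode_log10 -/+ halfwidth`.
#'
#' @seealso [buildFscGate()], [estimateFscMode()], [applyGate()]
#' @export
setClass("FscGate", representation(
  condition_id = "character", batch_id = "character",
  mode_log10 = "numeric", halfwidth = "numeric",
  low = "numeric", high = "numeric"))

setValidity("FscGate", function(object) {
  if (!is.finite(object@mode_log10)) return("mode_log10 must be finite")
  if (!is.finite(object@halfwidth) || object@halfwidth <= 0)
    return("halfwidth must be a positive real")
  if (object@low >= object@high) return("low must be < high")
  w <- object@high - object@low
  if (abs(w - 2 * object@halfwidth) > 1e-12 * max(1, abs(w)))
    return("gate width must equal 2 * halfwidth")
  TRUE
})

#' GatedPopulation: one gated, background-corrected population
#'
#' Holds the log10-transformed, autofluorescence-corrected fluorescence of
#' the events of one population that fell inside the FSC gate and exceeded
#' the autofluorescence level, together with rejection bookkeeping:
#' `nEvents(x) + x@n_rejected_gate + x@n_rejected_background` equals the
#' number of events originally recorded for the population.
#'
#' @slot strain_id,condition_id,replicate_id,batch_id character scalars.
#' @slot log_yfp numeric vector, log10(yfp_raw - autofluorescence), finite.
#' @slot autofluorescence_used positive numeric scalar (linear a.u.).
#' @slot n_rejected_gate,n_rejected_background integer counts.
#'
#' @seealso [correctYfp()], [qcPopulation()], [populationStats()]
#' @export
setClass("GatedPopulation", representation(
  strain_id = "character", condition_id = "character",
  replicate_id = "character", batch_id = "character",
  log_yfp = "numeric", autofluorescence_used = "numeric",
  n_rejected_gate = "integer", n_rejected_background = "integer"))

setValidity("GatedPopulation", function(object) {
  if (length(object@log_yfp) && !all(is.finite(object@log_yfp)))
    return("log_yfp must be finite (corrected intensity strictly positive)")
  if (!is.finite(object@autofluorescence_used) ||
      object@autofluorescence_used <= 0)
    return("autofluorescence_used must be a positive real")
  if (object@n_rejected_gate < 0L || object@n_rejected_background < 0L)
    return("rejection counts must be non-negative")
  TRUE
})

#' NoiseTrend: the V_pop-vs-E_pop trend and its DM residuals
#'
#' The mean-dependence of expression noise, fitted by a running median of
#' the per-point standard deviations (sorted by mean) followed by a cubic
#' smoothing spline through the running-median sequence.  The DM residual of
#' a point is `v - trend(e)`; within the fitted range the trend is the
#' spline, beyond it the boundary value is held constant.
#'
#' @slot points a `data.frame` with columns `gene_id`, `condition_id`, `e`,
#'   `v`, `dm` (one row per (gene, condition) point, sorted by `e`).
#' @slot knots a `data.frame` with columns `e`, `median_v`: the
#'   running-median sequence the spline was fitted to.
#' @slot window odd integer, running-median window in points.
#' @slot smoothing the smoothing setting used (`"auto"` for
#'   GCV-chosen spline stiffness, `0` for exact interpolation of the
#'   running median, or a numeric `spar`).
#' @slot trend a function mapping mean values to expected SD.
#'
#' @seealso [fitNoiseTrend()], [dmFromTable()], [meanDmvPerGene()]
#' @export
setClass("NoiseTrend", representation(
  points = "data.frame", knots = "data.frame", window = "integer",
  smoothing = "ANY", trend = "function"))

setValidity("NoiseTrend", function(object) {
  need <- c("gene_id", "condition_id", "e", "v", "dm")
  if (!all(need %in% names(object@points)))
    return(paste0("points must have columns ", paste(need, collapse = ", ")))
  if (object@window %% 2L != 1L) return("window must be odd")
  TRUE
})

#' CumulativeCurve: rank-scan cumulative means of a covariate
#'
#' Genes are ranked by a noise (or other) score in descending order and
#' scanned from high to low.  Each cut-off is the score of the gene at rank
#' `min_first, min_first + 1, ...`; at cut-off `x` the mean and standard
#' error (sample SD / sqrt(n)) of the covariate are computed over all genes
#' with score `>= x` (ties included, so the first point holds at least
#' `min_first` genes).
#'
#' @slot curve a `data.frame` with columns `cutoff`, `n_genes`, `mean_cov`,
#'   `se_cov`, ordered from the highest cut-off (fewest genes) downwards.
#' @slot covariate character scalar naming the averaged covariate.
#'
#' @seealso [cumulativeCurve()], [cumulativePlasticityCurve()]
#' @export
setClass("CumulativeCurve",
         representation(curve = "data.frame", covariate = "character"))

setValidity("CumulativeCurve", function(object) {
  need <- c("cutoff", "n_genes", "mean_cov", "se_cov")
  if (!all(need %in% names(object@curve)))
    return(paste0("curve must have columns ", paste(need, collapse = ", ")))
  n <- object@curve$n_genes
  if (length(n) && any(diff(n) < 0))
    return("n_genes must be non-decreasing as the cutoff decreases")
  TRUE
})

#' PcaResult: PCA of mean expression with missingness filtering
#'
#' Principal components of a gene-by-condition matrix of mean expression
#' after the two-step missingness filter: conditions missing more than a
#' fixed number of genes are dropped first, then only genes observed in all
#' remaining conditions are kept.  Conditions are the observations.
#'
#' @slot scores conditions x components score matrix.
#' @slot loadings genes x components loading matrix.
#' @slot var_explained numeric vector of variance fractions (sums to 1).
#' @slot kept_conditions,kept_genes character vectors after filtering.
#'
#' @seealso [pcaExpression()]
#' @export
setClass("PcaResult", representation(
  scores = "matrix", loadings = "matrix", var_explained = "numeric",
  kept_conditions = "character", kept_genes = "character"))

setValidity("PcaResult", function(object) {
  if (length(object@var_explained) &&
      abs(sum(object@var_explained) - 1) > 1e-9)
    return("var_explained must sum to 1")
  if (is.unsorted(rev(object@var_explained)))
    return("components must be ordered by decreasing variance")
  TRUE
})

#' FlowSimulation: a synthetic dataset with its planted truth
#'
#' Result of [simulateDataset()]: the synthetic events (including a
#' reporter-free control strain), the planted per-gene and per-condition
#' parameters, and metadata tables ready for [runPipeline()].
#'
#' @slot events an [EventTable-class].
#' @slot truth a list with elements `genes` (per-gene class, planted
#'   plasticity scale, extrinsic noise SD, baseline mean), `gene_condition`
#'   (per gene x condition true log10 mean) and `conditions` (per-condition
#'   cell-size location, autofluorescence level).
#' @slot gene_meta a `data.frame`: `gene_id`, `essential`, `msr_count`,
#'   `tr_count`.
#' @slot condition_meta a `data.frame`: `condition_id`, `carbon_source`,
#'   `environment_id`, `supplement_richness`.
#' @slot config the [simulationConfig()] list that produced the dataset.
#'
#' @seealso [simulateDataset()], [runPipeline()]
#' @export
setClass("FlowSimulation", representation(
  events = "EventTable", truth = "list", gene_meta = "data.frame",
  condition_meta = "data.frame", config = "list"))
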