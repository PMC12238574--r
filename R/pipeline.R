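#' Run the full noise/plasticity analysis pipeline
#'
#' End-to-end orchestration over an event table: per-(condition, batch)
#' cumulative-population FSC gates -> gating -> autofluorescence
#' subtraction using the control strain -> event-count QC -> population
#' statistics (`E_pop`, `V_pop`) -> replicate averaging -> global
#' noise-vs-mean trend and `DM_V` -> per-gene plasticity and mean `DM_V`
#' -> association analyses.  The run is fully deterministic: identical
#' inputs and parameters give identical outputs, and every population is
#' accounted for in either the result tables or the exclusion log.
#'
#' @param x an [EventTable-class] or a [FlowSimulation-class] (whose
#'   metadata tables are then used automatically).
#' @param gene_meta optional `data.frame` (`gene_id`, `essential`,
#'   `msr_count`, `tr_count`); the `strain_id` of reporter populations is
#'   the `gene_id`.
#' @param condition_meta optional `data.frame` of condition annotations.
#' @param control_strain strain id of the reporter-free control
#'   (default `"CONTROL"`).
#' @param autofluorescence optional positive scalar overriding the
#'   control-derived autofluorescence (then no control strain is needed).
#' @param halfwidth FSC-gate half-width in log10 units (default 0.1).
#' @param min_events QC floor on corrected events per population
#'   (default 4000).
#' @param min_control_events hard floor on gated control events per
#'   (condition, batch) (default 100).
#' @param window,smoothing trend parameters, see [fitNoiseTrend()].
#' @param min_conditions floor for plasticity, see [computePlasticity()].
#' @param min_replicates floor for replicate averaging (default 2).
#' @param autofluorescence_statistic `"mean"` (default) or `"median"`.
#' @param per_replicate_dm logical; `TRUE` fits the noise trend on
#'   per-replicate `(E_pop, V_pop)` points instead of replicate-averaged
#'   ones (sensitivity analysis; default `FALSE`, averaging first).
#' @return a list with elements `gates`, `autofluorescence`,
#'   `population_stats`, `gene_condition_stats`, `noise_trend`
#'   ([NoiseTrend-class] or `NULL`), `gene_noise`, `gene_summary`,
#'   `associations`, `qc_log` (one row per input population with counts
#'   and a reason code), and `params`.
#' @examples
#' sim <- simulateDataset(simulationConfig(
#'   n_nonessential = 4, n_essential = 2, n_conditions = 3,
#'   events_per_population = 500, seed = 11))
#' res <- runPipeline(sim, min_events = 100, min_conditions = 2)
#' head(res$gene_summary)
#' @export
runPipeline <- function(x, gene_meta = NULL, condition_meta = NULL,
                        control_strain = "CONTROL",
                        autofluorescence = NULL,
                        halfwidth = 0.1, min_events = 4000L,
                        min_control_events = 100L,
                        window = "auto", smoothing = "auto",
                        min_conditions = 5L, min_replicates = 2L,
                        autofluorescence_statistic = c("mean", "median"),
                        per_replicate_dm = FALSE) {
  autofluorescence_statistic <- match.arg(autofluorescence_statistic)
  if (is(x, "FlowSimulation")) {
    if (is.null(gene_meta)) gene_meta <- x@gene_meta
    if (is.null(condition_meta)) condition_meta <- x@condition_meta
    control_strain <- x@config$control_strain
    x <- x@events
  }
  stopifnot(is(x, "EventTable"))
  ev <- eventData(x)

  ## The gate, autofluorescence and population statistics all live inside
  ## one (condition, batch): events are processed chunk by chunk, so peak
  ## memory stays close to the input table regardless of its size.
  grp_dt <- data.table(condition_id = ev$condition_id,
                       batch_id = ev$batch_id)
  groups <- grp_dt[, list(idx = list(.I)),
                   by = list(condition_id, batch_id)]
  rm(grp_dt)

  gate_rows <- vector("list", nrow(groups))
  af_rows <- vector("list", nrow(groups))
  ps_rows <- vector("list", nrow(groups))
  log_rows <- vector("list", nrow(groups))
  for (gi in seq_len(nrow(groups))) {
    idx <- groups$idx[[gi]]
    cond <- groups$condition_id[gi]; batch <- groups$batch_id[gi]
    chunk <- data.table(strain_id = ev$strain_id[idx],
                        replicate_id = ev$replicate_id[idx],
                        lfsc = log10(ev$fsc[idx]),
                        yfp_raw = ev$yfp_raw[idx])

    ## 1-2. cumulative-population gate, applied as a closed interval
    mode_log10 <- estimateFscMode(ev$fsc[idx])
    lo <- mode_log10 - halfwidth; hi <- mode_log10 + halfwidth
    gate_rows[[gi]] <- data.frame(condition_id = cond, batch_id = batch,
                                  mode_log10 = mode_log10, low = lo,
                                  high = hi)
    chunk[, in_gate := lfsc >= lo & lfsc <= hi]

    ## 3. autofluorescence from the gated control strain
    if (is.null(autofluorescence)) {
      ctrl_y <- chunk[in_gate & strain_id == control_strain, yfp_raw]
      if (!length(ctrl_y))
        stop("no control-strain events for (condition, batch): ",
             cond, "/", batch)
      if (length(ctrl_y) < min_control_events)
        stop("fewer than ", min_control_events,
             " gated control events in (", cond, ", ", batch, ")")
      if (length(ctrl_y) < 4000L)
        warning("control population below 4,000 gated events in (",
                cond, ", ", batch, "); autofluorescence may be noisy")
      af_val <- if (autofluorescence_statistic == "mean") mean(ctrl_y)
                else median(ctrl_y)
      n_ctrl <- length(ctrl_y)
    } else {
      stopifnot(is.numeric(autofluorescence), autofluorescence > 0)
      af_val <- autofluorescence
      n_ctrl <- NA_integer_
    }
    af_rows[[gi]] <- data.frame(condition_id = cond, batch_id = batch,
                                af = af_val, n_control = n_ctrl)

    ## 4-5. subtract, drop non-positive corrected events, per-population
    ##      statistics and bookkeeping
    chunk[, keep := in_gate & strain_id != control_strain &
            yfp_raw > af_val]
    counts <- chunk[, list(n_total = .N, n_gated = sum(in_gate),
                           n_corrected = sum(keep)),
                    by = list(strain_id, replicate_id)]
    corr <- chunk[keep == TRUE, list(strain_id, replicate_id,
                                     log_yfp = log10(yfp_raw - af_val))]
    rm(chunk)
    st <- corr[, list(e_pop = mean(log_yfp), v_pop = sd(log_yfp),
                      n_events = .N),
               by = list(strain_id, replicate_id)]
    rm(corr)
    st[, `:=`(condition_id = cond, batch_id = batch)]
    counts[, `:=`(condition_id = cond, batch_id = batch)]
    ps_rows[[gi]] <- st
    log_rows[[gi]] <- counts
  }
  gates <- rbindlist(gate_rows)
  ctrl <- rbindlist(af_rows)
  ps <- rbindlist(ps_rows)
  qc_log <- rbindlist(log_rows)

  data.table::setcolorder(ps, c("strain_id", "condition_id",
                                "replicate_id", "batch_id"))
  ps[is.na(v_pop), v_pop := 0]   # single-event population
  ps_pass <- ps[n_events >= min_events]

  ## exclusion log: every input population appears exactly once
  data.table::setcolorder(qc_log, c("strain_id", "condition_id",
                                    "replicate_id", "batch_id"))
  qc_log[, `:=`(n_rejected_gate = n_total - n_gated,
                n_rejected_background = n_gated - n_corrected)]
  qc_log[strain_id == control_strain, n_rejected_background := NA_integer_]
  qc_log[, qc_pass := n_corrected >= min_events &
           strain_id != control_strain]
  qc_log[, reason := ifelse(strain_id == control_strain, "control",
                            ifelse(qc_pass, "ok", "qc_below_min_events"))]
  setorder(qc_log, strain_id, condition_id, replicate_id)

  stats_df <- as.data.frame(ps_pass)
  gc_stats <- if (nrow(stats_df))
    averageReplicates(stats_df, min_replicates = min_replicates)
  else data.frame(gene_id = character(), condition_id = character(),
                  e_pop_mean = numeric(), v_pop_mean = numeric(),
                  n_replicates = integer())

  ## 6. noise trend + DM residuals
  trend_points <- if (per_replicate_dm && nrow(stats_df)) {
    data.frame(gene_id = stats_df$strain_id,
               condition_id = paste(stats_df$condition_id,
                                    stats_df$replicate_id, sep = "/"),
               e = stats_df$e_pop, v = stats_df$v_pop)
  } else if (nrow(gc_stats)) {
    data.frame(gene_id = gc_stats$gene_id,
               condition_id = gc_stats$condition_id,
               e = gc_stats$e_pop_mean, v = gc_stats$v_pop_mean)
  } else NULL
  noise_trend <- NULL
  gene_noise <- NULL
  if (!is.null(trend_points) && nrow(trend_points) >= 8L) {
    noise_trend <- fitNoiseTrend(trend_points, window = window,
                                 smoothing = smoothing)
    gene_noise <- suppressMessages(meanDmvPerGene(noise_trend))
  }

  ## 7. per-gene summary
  summary_df <- if (nrow(gc_stats))
    suppressWarnings(geneSummary(gc_stats, gene_noise, gene_meta,
                                 min_conditions = min_conditions))
  else data.frame(gene_id = character(), plasticity = numeric(),
                  mean_e_pop = numeric(), n_conditions = integer(),
                  mean_dmv = numeric())

  ## 8. associations
  assoc <- .pipelineAssociations(summary_df, noise_trend, gc_stats)

  list(gates = as.data.frame(gates),
       autofluorescence = as.data.frame(ctrl),
       population_stats = stats_df,
       gene_condition_stats = gc_stats,
       noise_trend = noise_trend,
       gene_noise = gene_noise,
       gene_summary = summary_df,
       associations = assoc,
       qc_log = as.data.frame(qc_log),
       params = list(control_strain = control_strain,
                     halfwidth = halfwidth, min_events = min_events,
                     window = window, smoothing = smoothing,
                     min_conditions = min_conditions,
                     min_replicates = min_replicates,
                     autofluorescence_statistic =
                       autofluorescence_statistic,
                     per_replicate_dm = per_replicate_dm))
}

.tryAssoc <- function(expr) tryCatch(expr, error = function(e) NULL)

.pipelineAssociations <- function(summary_df, noise_trend, gc_stats) {
  out <- list()
  ok <- is.finite(summary_df$plasticity) & is.finite(summary_df$mean_dmv)
  s <- summary_df[ok, , drop = FALSE]
  out$noise_vs_plasticity <- .tryAssoc(
    spearmanAssoc(s$mean_dmv, s$plasticity))
  if ("essential" %in% names(s)) {
    ne <- s[!s$essential, , drop = FALSE]
    es <- s[s$essential, , drop = FALSE]
    out$noise_vs_plasticity_nonessential <- .tryAssoc(
      spearmanAssoc(ne$mean_dmv, ne$plasticity))
    out$noise_vs_plasticity_essential <- .tryAssoc(
      spearmanAssoc(es$mean_dmv, es$plasticity))
    out$plasticity_by_essentiality <- .tryAssoc(
      rankSumTest(es$plasticity, ne$plasticity))
    out$mean_dmv_by_essentiality <- .tryAssoc(
      rankSumTest(es$mean_dmv, ne$mean_dmv))
    if ("msr_count" %in% names(s)) {
      out$msr_vs_noise_nonessential <- .tryAssoc(
        spearmanAssoc(ne$msr_count, ne$mean_dmv))
      out$msr_vs_plasticity_nonessential <- .tryAssoc(
        spearmanAssoc(ne$msr_count, ne$plasticity))
      out$cumulative_msr_curve <- .tryAssoc(
        cumulativeCurve(ne$mean_dmv, ne$msr_count,
                        covariate_name = "msr_count"))
      out$cumulative_plasticity_curve <- .tryAssoc(
        cumulativePlasticityCurve(ne$mean_dmv, ne$plasticity))
    }
  }
  if (!is.null(noise_trend)) {
    pts <- dmResiduals(noise_trend)
    out$dm_vs_e <- .tryAssoc(spearmanAssoc(pts$dm, pts$e))
    lo <- pts$e <= stats::quantile(pts$e, 1 / 3)
    out$v_vs_e_low_tercile <- .tryAssoc(
      spearmanAssoc(pts$v[lo], pts$e[lo]))
  }
  if (nrow(gc_stats)) {
    m <- expressionMatrix(gc_stats)
    out$pca <- .tryAssoc(pcaExpression(m))
  }
  out
}

#' Gene x condition mean-expression matrix
#'
#' Reshapes replicate-averaged statistics into the genes x conditions
#' matrix consumed by [pcaExpression()] (`NA` where a gene x condition was
#' dropped by QC or the duplicate requirement).
#'
#' @param gc_stats a `data.frame` from [averageReplicates()].
#' @return numeric matrix, genes x conditions.
#' @export
expressionMatrix <- function(gc_stats) {
  genes <- sort(unique(gc_stats$gene_id))
  conds <- sort(unique(gc_stats$condition_id))
  m <- matrix(NA_real_, length(genes), length(conds),
              dimnames = list(genes, conds))
  m[cbind(match(gc_stats$gene_id, genes),
          match(gc_stats$condition_id, conds))] <- gc_stats$e_pop_mean
  m
}
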