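#' Population mean and SD of log10 expression
#'
#' `E_pop` is the arithmetic mean and `V_pop` the sample standard deviation
#' (denominator n - 1) of the log10-transformed, background-corrected
#' fluorescence of one gated population.  Both are computed on the log
#' scale, which tames the long right tail of single-cell protein-number
#' distributions.
#'
#' @param pop a [GatedPopulation-class], or a numeric vector of `log_yfp`
#'   values (keys then taken from `...`).
#' @param strain_id,condition_id,replicate_id key overrides when `pop` is a
#'   bare numeric vector.
#' @return a one-row `data.frame`: `strain_id`, `condition_id`,
#'   `replicate_id`, `e_pop`, `v_pop`, `n_events`.
#' @examples
#' populationStats(c(1, 3), strain_id = "g")  # e_pop 2, v_pop sqrt(2)
#' @export
populationStats <- function(pop, strain_id = NA_character_,
                            condition_id = NA_character_,
                            replicate_id = NA_character_) {
  if (is(pop, "GatedPopulation")) {
    strain_id <- pop@strain_id
    condition_id <- pop@condition_id
    replicate_id <- pop@replicate_id
    v <- pop@log_yfp
  } else {
    v <- pop
  }
  stopifnot(is.numeric(v))
  if (length(v) == 0L) stop("cannot compute statistics of an empty population")
  data.frame(strain_id = strain_id, condition_id = condition_id,
             replicate_id = replicate_id,
             e_pop = mean(v),
             v_pop = if (length(v) > 1L) sd(v) else 0,
             n_events = length(v))
}

#' Average population statistics across biological replicates
#'
#' `E_pop` and `V_pop` are averaged (unweighted arithmetic mean) among the
#' biological replicates of each gene x condition.  Conditions lacking
#' biological duplicates — fewer than two replicates surviving QC — are
#' omitted for that gene.
#'
#' @param stats a `data.frame` of [populationStats()] rows (any number of
#'   genes and conditions; `strain_id` doubles as the gene identifier).
#' @param min_replicates minimum surviving replicates (default 2).
#' @return a `data.frame`: `gene_id`, `condition_id`, `e_pop_mean`,
#'   `v_pop_mean`, `n_replicates`, one row per retained gene x condition.
#' @export
averageReplicates <- function(stats, min_replicates = 2L) {
  need <- c("strain_id", "condition_id", "e_pop", "v_pop")
  if (!all(need %in% names(stats)))
    stop("stats must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(stats[, c("strain_id", "condition_id",
                              "replicate_id")]))
    stop("duplicate (strain, condition, replicate) rows in stats")
  dt <- as.data.table(stats)
  out <- dt[, list(e_pop_mean = mean(e_pop), v_pop_mean = mean(v_pop),
                   n_replicates = .N),
            by = list(gene_id = strain_id, condition_id)]
  out <- out[n_replicates >= min_replicates]
  setorder(out, gene_id, condition_id)
  as.data.frame(out)
}

#' Across-condition plasticity of mean expression
#'
#' A gene's plasticity is the sample standard deviation of its
#' replicate-averaged `E_pop` across nutrient conditions: how much the
#' population-mean expression moves when the environment changes.  Genes
#' observed in fewer than `min_conditions` conditions are excluded
#' (returned as `NA` with a warning) — a SD over a handful of conditions is
#' too unstable to rank.
#'
#' @param e_pop_means numeric vector of per-condition `e_pop_mean` values
#'   for one gene.
#' @param min_conditions minimum conditions required (default 5).
#' @return non-negative numeric scalar, or `NA_real_` when under-supported.
#' @examples
#' computePlasticity(c(1, 2, 3), min_conditions = 3)  # sample SD = 1
#' @export
computePlasticity <- function(e_pop_means, min_conditions = 5L) {
  stopifnot(is.numeric(e_pop_means))
  e_pop_means <- e_pop_means[is.finite(e_pop_means)]
  if (length(e_pop_means) < min_conditions) {
    warning("gene observed in ", length(e_pop_means),
            " conditions (< ", min_conditions, "); plasticity undefined")
    return(NA_real_)
  }
  sd(e_pop_means)
}

#' Per-gene summary table
#'
#' Joins plasticity, mean DM residual and gene annotations into the
#' analysis-ready per-gene table.
#'
#' @param gene_condition a `data.frame` from [averageReplicates()].
#' @param gene_noise a `data.frame` from [meanDmvPerGene()] (or `NULL`).
#' @param gene_meta optional `data.frame` with `gene_id`, `essential`,
#'   `msr_count`, `tr_count`.
#' @param min_conditions passed to [computePlasticity()].
#' @return a `data.frame`: `gene_id`, `plasticity`, `mean_e_pop`,
#'   `mean_dmv`, `n_conditions`, plus annotation columns when supplied.
#'   Genes under the condition floor carry `NA` plasticity.
#' @export
geneSummary <- function(gene_condition, gene_noise = NULL, gene_meta = NULL,
                        min_conditions = 5L) {
  dt <- as.data.table(gene_condition)
  out <- dt[, list(
    plasticity = if (.N >= min_conditions) sd(e_pop_mean) else NA_real_,
    mean_e_pop = mean(e_pop_mean),
    n_conditions = .N), by = gene_id]
  out <- as.data.frame(out)
  if (!is.null(gene_noise))
    out <- merge(out, gene_noise[, c("gene_id", "mean_dmv")],
                 by = "gene_id", all.x = TRUE)
  else out$mean_dmv <- NA_real_
  if (!is.null(gene_meta))
    out <- merge(out, gene_meta, by = "gene_id", all.x = TRUE)
  out[order(out$gene_id), , drop = FALSE]
}
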