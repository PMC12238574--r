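#' Growth threshold from sterile controls
#'
#' Significant growth in a microplate OD595 assay is declared above a
#' threshold derived from the sterile control wells: the grand mean of the
#' sterile OD595 values plus `n_sd` (default 5) times the mean of the
#' per-control-set sample SDs.  Control sets are the laboratory-natural
#' grouping (plate or condition); with `grouping = "pooled"` a single SD
#' over all sterile wells is used instead.
#'
#' @param od numeric vector of sterile-control OD595 values.
#' @param sets optional grouping vector (same length as `od`) assigning
#'   wells to control sets; `NULL` treats all wells as one set.
#' @param n_sd multiplier on the mean SD (default 5).
#' @param grouping `"per_set"` (default) or `"pooled"`.
#' @return numeric scalar threshold.
#' @examples
#' growthThreshold(c(0.04, 0.06))  # mean 0.05 + 5 * sd
#' @export
growthThreshold <- function(od, sets = NULL, n_sd = 5,
                            grouping = c("per_set", "pooled")) {
  grouping <- match.arg(grouping)
  stopifnot(is.numeric(od))
  od <- od[is.finite(od)]
  if (!length(od)) stop("no sterile-control OD values supplied")
  if (is.null(sets) || grouping == "pooled") sets <- rep(1L, length(od))
  stopifnot(length(sets) == length(od))
  per_set_n <- tapply(od, sets, length)
  if (any(per_set_n < 2L))
    stop("every sterile control set needs at least 2 wells")
  mean_sd <- mean(tapply(od, sets, sd))
  mean(od) + n_sd * mean_sd
}

#' Classify growth of one strain in one condition
#'
#' A strain shows significant growth when *more than half* of its
#' biological replicates exceed the threshold (strict inequalities on both
#' the OD comparison and the majority count: 2 of 4 is not a majority).
#'
#' @param replicate_ods numeric vector of replicate OD595 values.
#' @param threshold numeric scalar from [growthThreshold()].
#' @param strain_id,condition_id optional identifiers for the record.
#' @return a one-row `data.frame`: `strain_id`, `condition_id`, `grows`,
#'   `n_above`, `n_total`, `threshold`.
#' @export
classifyGrowth <- function(replicate_ods, threshold,
                           strain_id = NA_character_,
                           condition_id = NA_character_) {
  stopifnot(is.numeric(replicate_ods), length(replicate_ods) >= 1L,
            is.numeric(threshold), length(threshold) == 1L)
  n_above <- sum(replicate_ods > threshold)
  n_total <- length(replicate_ods)
  data.frame(strain_id = strain_id, condition_id = condition_id,
             grows = n_above > n_total / 2,
             n_above = n_above, n_total = n_total, threshold = threshold)
}

#' Conditional-essentiality label for one strain
#'
#' A knockout strain that grows under at least one tested condition but
#' fails under at least one other exhibits conditional growth; its gene is
#' conditionally essential.  Strains growing everywhere are unconditionally
#' dispensable under the tested panel; strains growing nowhere are reported
#' as their own category and flagged for manual review (universal failure
#' in synthetic media by a strain viable in rich medium is biologically
#' conditional, but usually signals an assay problem).
#'
#' @param calls a `data.frame` with columns `condition_id` and `grows` (all
#'   rows for one strain, at least 2 conditions).
#' @return character scalar: `"grows_everywhere"`,
#'   `"conditionally_essential"`, or `"no_growth_all"`.
#' @export
conditionalEssentiality <- function(calls) {
  stopifnot(is.data.frame(calls), all(c("condition_id", "grows") %in%
                                        names(calls)))
  if (nrow(calls) < 2L)
    stop("need growth calls from at least 2 conditions")
  n_grow <- sum(calls$grows)
  if (n_grow == nrow(calls)) "grows_everywhere"
  else if (n_grow == 0L) "no_growth_all"
  else "conditionally_essential"
}

#' Run the essentiality classifier on a full growth assay
#'
#' Computes the sterile-based threshold, calls growth per strain x
#' condition, and labels each strain.  Sterile wells are the rows whose
#' `strain_id` equals `sterile_strain`, grouped into control sets by
#' condition.
#'
#' @param assay a `data.frame`: `strain_id`, `condition_id`,
#'   `replicate_id`, `od595`.
#' @param sterile_strain identifier of the sterile-control rows (default
#'   `"STERILE"`).
#' @param n_sd threshold multiplier (default 5).
#' @param grouping sterile-SD grouping, see [growthThreshold()].
#' @return a list: `threshold`, `calls` (per strain x condition), `labels`
#'   (per strain, with a `review` flag for `no_growth_all`).
#' @export
callGrowthAssay <- function(assay, sterile_strain = "STERILE", n_sd = 5,
                            grouping = c("per_set", "pooled")) {
  grouping <- match.arg(grouping)
  need <- c("strain_id", "condition_id", "replicate_id", "od595")
  stopifnot(all(need %in% names(assay)))
  sterile <- assay[assay$strain_id == sterile_strain, , drop = FALSE]
  if (!nrow(sterile))
    stop("no sterile control wells (strain_id == '", sterile_strain, "')")
  thr <- growthThreshold(sterile$od595, sets = sterile$condition_id,
                         n_sd = n_sd, grouping = grouping)
  tested <- assay[assay$strain_id != sterile_strain, , drop = FALSE]
  grp <- split(tested, list(tested$strain_id, tested$condition_id),
               drop = TRUE)
  calls <- do.call(rbind, lapply(grp, function(g)
    classifyGrowth(g$od595, thr, strain_id = g$strain_id[1L],
                   condition_id = g$condition_id[1L])))
  rownames(calls) <- NULL
  calls <- calls[order(calls$strain_id, calls$condition_id), , drop = FALSE]
  labels <- do.call(rbind, lapply(split(calls, calls$strain_id),
    function(cc) data.frame(strain_id = cc$strain_id[1L],
                            label = conditionalEssentiality(cc))))
  rownames(labels) <- NULL
  labels$review <- labels$label == "no_growth_all"
  list(threshold = thr, calls = calls, labels = labels)
}
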