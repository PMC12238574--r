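#' Estimate the mode of the pooled log10 FSC distribution
#'
#' The narrow FSC gate for one (condition, batch) is centred on the mode of
#' the *cumulative* population: the forward-scatter values of all strains
#' measured under that condition on that date, pooled.  The mode is the
#' argmax of a Gaussian kernel density estimate (Silverman's rule-of-thumb
#' bandwidth) of log10 FSC, evaluated on a 512-point grid spanning the data
#' range — robust to histogram binning artefacts.
#'
#' @param fsc an [EventTable-class] (its `fsc` column is used) or a numeric
#'   vector of linear FSC values, pooled over all strains of one
#'   (condition, batch).
#' @param min_events minimum pooled events required (default 100).
#' @return the mode of log10 FSC (numeric scalar).
#' @examples
#' estimateFscMode(rep(1000, 200))  # point mass at 10^3 -> 3
#' @export
estimateFscMode <- function(fsc, min_events = 100L) {
  if (is(fsc, "EventTable")) fsc <- eventData(fsc)$fsc
  stopifnot(is.numeric(fsc))
  if (any(fsc <= 0)) stop("FSC values must be positive (linear a.u.)")
  if (length(fsc) < min_events)
    stop("too few pooled events for mode estimation: ", length(fsc),
         " < ", min_events)
  lf <- log10(fsc)
  rng <- range(lf)
  if (diff(rng) == 0) return(rng[1L])
  d <- density(lf, bw = "nrd0", n = 512L, from = rng[1L], to = rng[2L])
  d$x[which.max(d$y)]
}

#' Build a narrow FSC gate around a mode
#'
#' The gate is the closed interval `mode +/- halfwidth` on the log10 scale;
#' the default half-width 0.1 yields the standard 0.2-wide narrow gate.
#'
#' @param mode_log10 finite numeric scalar, mode of log10 FSC.
#' @param halfwidth positive numeric scalar (default 0.1 log10 units).
#' @param condition_id,batch_id optional identifiers recorded on the gate.
#' @return an [FscGate-class].
#' @examples
#' buildFscGate(2.5)  # [2.4, 2.6]
#' @export
buildFscGate <- function(mode_log10, halfwidth = 0.1,
                         condition_id = NA_character_,
                         batch_id = NA_character_) {
  if (!is.numeric(mode_log10) || length(mode_log10) != 1L ||
      !is.finite(mode_log10))
    stop("mode_log10 must be a finite numeric scalar")
  if (!is.numeric(halfwidth) || length(halfwidth) != 1L ||
      !is.finite(halfwidth) || halfwidth <= 0)
    stop("halfwidth must be a positive real")
  new("FscGate", condition_id = as.character(condition_id),
      batch_id = as.character(batch_id),
      mode_log10 = mode_log10, halfwidth = halfwidth,
      low = mode_log10 - halfwidth, high = mode_log10 + halfwidth)
}

#' Apply an FSC gate to events
#'
#' Keeps events with `low <= log10(fsc) <= high` (closed on both ends;
#' boundary mass is negligible for continuous data).  The number of
#' rejected events is `nEvents(input) - nEvents(output)` and is also
#' attached as attribute `n_rejected` for convenience.
#'
#' @param x an [EventTable-class].
#' @param gate an [FscGate-class].
#' @return the gated [EventTable-class] (possibly empty), with attribute
#'   `n_rejected`.
#' @export
applyGate <- function(x, gate) {
  stopifnot(is(x, "EventTable"), is(gate, "FscGate"))
  ev <- eventData(x)
  lf <- log10(ev$fsc)
  keep <- lf >= gate@low & lf <= gate@high
  out <- new("EventTable", events = ev[keep, , drop = FALSE])
  attr(out, "n_rejected") <- sum(!keep)
  out
}

#' Estimate autofluorescence from a gated control population
#'
#' Cells lacking the fluorescent reporter still emit background
#' fluorescence; that autofluorescence is estimated per (condition, batch)
#' from the control strain's events *after the same FSC gate*, as the
#' arithmetic mean of raw fluorescence on the linear scale (median
#' available via `statistic`).
#'
#' @param control an [EventTable-class] of gated control-strain events, or
#'   a numeric vector of raw fluorescence values.
#' @param statistic `"mean"` (default) or `"median"`.
#' @param min_events hard floor on control events (default 100); a warning
#'   is emitted below 4,000, the QC floor applied to reporter populations.
#' @return positive numeric scalar (linear a.u.).
#' @export
estimateAutofluorescence <- function(control, statistic = c("mean", "median"),
                                     min_events = 100L) {
  statistic <- match.arg(statistic)
  if (is(control, "EventTable")) control <- eventData(control)$yfp_raw
  stopifnot(is.numeric(control))
  if (length(control) < min_events)
    stop("too few control events for autofluorescence estimation: ",
         length(control), " < ", min_events)
  if (length(control) < 4000L)
    warning("control population has fewer than 4,000 events (",
            length(control), "); autofluorescence estimate may be noisy")
  af <- if (statistic == "mean") mean(control) else median(control)
  if (!is.finite(af) || af <= 0)
    stop("estimated autofluorescence is not a positive real: ", af)
  af
}

#' Subtract autofluorescence and log-transform
#'
#' For every gated event with raw fluorescence strictly above the
#' autofluorescence level, emits `log10(yfp_raw - autofluorescence)`.
#' Events at or below the autofluorescence level are removed (a corrected
#' intensity of zero has no logarithm) and counted in
#' `n_rejected_background`.
#'
#' @param x an [EventTable-class] of gated events from a single population.
#' @param autofluorescence positive scalar (linear a.u.).
#' @param n_rejected_gate events already rejected by the FSC gate for this
#'   population, carried through for conservation bookkeeping.
#' @return a [GatedPopulation-class].
#' @examples
#' ev <- EventTable(data.frame(strain_id = "g", condition_id = "c",
#'   replicate_id = "r", batch_id = "b", fsc = 300, ssc = 300,
#'   yfp_raw = 150))
#' correctYfp(ev, 50)  # log10(100) = 2
#' @export
correctYfp <- function(x, autofluorescence, n_rejected_gate = 0L) {
  stopifnot(is(x, "EventTable"))
  if (!is.numeric(autofluorescence) || length(autofluorescence) != 1L ||
      !is.finite(autofluorescence) || autofluorescence <= 0)
    stop("autofluorescence must be a positive real")
  ev <- eventData(x)
  k <- unique(ev[, c("strain_id", "condition_id", "replicate_id",
                     "batch_id")])
  if (nrow(k) > 1L)
    stop("correctYfp expects events from a single population; got ",
         nrow(k))
  if (nrow(k) == 0L)
    k <- data.frame(strain_id = NA_character_, condition_id = NA_character_,
                    replicate_id = NA_character_, batch_id = NA_character_)
  keep <- ev$yfp_raw > autofluorescence
  new("GatedPopulation",
      strain_id = k$strain_id, condition_id = k$condition_id,
      replicate_id = k$replicate_id, batch_id = k$batch_id,
      log_yfp = log10(ev$yfp_raw[keep] - autofluorescence),
      autofluorescence_used = autofluorescence,
      n_rejected_gate = as.integer(n_rejected_gate),
      n_rejected_background = sum(!keep))
}

#' @describeIn correctYfp number of retained (corrected) events.
#' @aliases nEvents,GatedPopulation-method
#' @export
setMethod("nEvents", "GatedPopulation", function(x) length(x@log_yfp))

#' Event-count quality control
#'
#' Populations with fewer than `min_events` events after gating and
#' background correction are omitted from all downstream analysis; the
#' default floor is 4,000 events.
#'
#' @param pop a [GatedPopulation-class] or an integer event count.
#' @param min_events integer floor (default 4000).
#' @return `TRUE` iff the population retains at least `min_events` events.
#' @export
qcPopulation <- function(pop, min_events = 4000L) {
  n <- if (is(pop, "GatedPopulation")) nEvents(pop) else as.integer(pop)
  n >= min_events
}
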