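#' Construct an EventTable
#'
#' Builds the canonical per-cell event container from a `data.frame`.
#' Non-canonical channel names (e.g. instrument exports with `FSC-A`,
#' `SSC-A`, `FITC-A`) are mapped via `channels`; key columns accept either
#' the canonical `strain_id` style or bare `strain`/`condition`/`replicate`/
#' `batch` names.
#'
#' @param df a `data.frame` of events.
#' @param channels named list mapping canonical channels to column names in
#'   `df`; defaults cover common instrument conventions.
#' @return an [EventTable-class].
#' @examples
#' ev <- EventTable(data.frame(
#'   strain_id = "g1", condition_id = "c1", replicate_id = "r1",
#'   batch_id = "b1", fsc = c(300, 400), ssc = c(250, 260),
#'   yfp_raw = c(120, 180)))
#' nEvents(ev)
#' @export
EventTable <- function(df, channels = defaultChannels()) {
  df <- as.data.frame(df)
  # map key columns
  key_alias <- c(strain_id = "strain", condition_id = "condition",
                 replicate_id = "replicate", batch_id = "batch")
  for (canon in names(key_alias)) {
    if (!canon %in% names(df) && key_alias[[canon]] %in% names(df))
      names(df)[names(df) == key_alias[[canon]]] <- canon
  }
  # map measurement channels
  chan_target <- c(fsc = "fsc", ssc = "ssc", yfp = "yfp_raw")
  for (chan in names(chan_target)) {
    canon <- chan_target[[chan]]
    if (canon %in% names(df)) next
    hit <- intersect(channels[[chan]], names(df))
    if (length(hit)) {
      names(df)[names(df) == hit[[1L]]] <- canon
    } else {
      stop("required channel '", chan, "' not found; looked for: ",
           paste(c(canon, channels[[chan]]), collapse = ", "))
    }
  }
  for (col in c("strain_id", "condition_id", "replicate_id", "batch_id"))
    df[[col]] <- as.character(df[[col]])
  for (col in c("fsc", "ssc", "yfp_raw"))   # canonical storage is double
    df[[col]] <- as.numeric(df[[col]])
  new("EventTable", events = df[, .EVENT_COLS, drop = FALSE])
}

#' Default channel-name aliases
#'
#' The instrument channel names for forward scatter, side scatter and the
#' YFP detector vary between cytometers; the 515-545 nm emission window
#' used for YFP commonly appears as a FITC channel.
#'
#' @return named list of character vectors of accepted column names.
#' @export
defaultChannels <- function() {
  list(fsc = c("FSC", "FSC-A", "FSC-H"),
       ssc = c("SSC", "SSC-A", "SSC-H"),
       yfp = c("YFP", "FITC-A", "FITC", "YFP-A", "FL1-A"))
}

#' @describeIn EventTable number of events.
#' @aliases nEvents,EventTable-method
#' @param x an EventTable.
#' @export
setMethod("nEvents", "EventTable", function(x) nrow(x@events))

#' @rdname eventData
#' @export
setMethod("eventData", "EventTable", function(x) x@events)

#' @rdname populationKeys
#' @export
setMethod("populationKeys", "EventTable", function(x) {
  dt <- as.data.table(x@events)
  out <- dt[, list(batch_id = batch_id[1L], n_events = .N),
            by = list(strain_id, condition_id, replicate_id)]
  as.data.frame(out)
})

setMethod("show", "EventTable", function(object) {
  k <- populationKeys(object)
  cat("EventTable:", nEvents(object), "events,",
      nrow(k), "populations,",
      length(unique(k$condition_id)), "conditions,",
      length(unique(k$batch_id)), "batches\n")
})

setMethod("show", "FscGate", function(object) {
  cat(sprintf("FscGate [%s | %s]: mode %.4f, [%.4f, %.4f] log10 FSC\n",
              object@condition_id, object@batch_id, object@mode_log10,
              object@low, object@high))
})

setMethod("show", "GatedPopulation", function(object) {
  cat(sprintf(
    "GatedPopulation %s/%s/%s: %d events (gate-rejected %d, background-rejected %d), AF %.3g\n",
    object@strain_id, object@condition_id, object@replicate_id,
    length(object@log_yfp), object@n_rejected_gate,
    object@n_rejected_background, object@autofluorescence_used))
})

#' Flag events below acquisition thresholds
#'
#' Acquisition thresholds (the instrument records only events above its FSC
#' and SSC trigger values; 200 a.u. each in the reference setup) are treated
#' as metadata: they are *not* re-applied when reading data, but events at
#' or below a threshold can be flagged for inspection.
#'
#' @param x an [EventTable-class].
#' @param fsc_min,ssc_min numeric thresholds (linear a.u.); default 0 flags
#'   only degenerate zero-scatter events.
#' @return logical vector, `TRUE` for sub-threshold events.
#' @export
subThresholdEvents <- function(x, fsc_min = 0, ssc_min = 0) {
  ev <- eventData(x)
  ev$fsc <= fsc_min | ev$ssc <= ssc_min
}

#' Read flow-cytometry events
#'
#' Reads either the canonical CSV event table (exact header
#' `strain_id,condition_id,replicate_id,batch_id,fsc,ssc,yfp_raw`, the
#' loss-free interchange dialect) or an FCS 3.0/3.1 file written by
#' [writeEvents()] (float32 list mode, linear values; population keys are
#' carried in custom TEXT keywords and can be overridden).
#'
#' No events are dropped at read time; use [subThresholdEvents()] to flag
#' degenerate records.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @param channels channel-name aliases, see [defaultChannels()].
#' @param keys optional named list overriding `strain_id`, `condition_id`,
#'   `replicate_id`, `batch_id` for FCS files lacking key keywords.
#' @return an [EventTable-class].
#' @export
readEvents <- function(path, format = c("auto", "csv", "fcs"),
                       channels = defaultChannels(), keys = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read events: no such file: ", path)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  if (format == "csv") {
    df <- as.data.frame(fread(path))
    return(EventTable(df, channels = channels))
  }
  fcs <- .readFCS(path)
  df <- as.data.frame(fcs$data)
  kw <- fcs$keywords
  for (k in c("strain_id", "condition_id", "replicate_id", "batch_id")) {
    val <- keys[[k]]
    if (is.null(val)) val <- kw[[paste0("NP$", toupper(k))]]
    if (is.null(val)) val <- NA_character_
    df[[k]] <- as.character(val)
  }
  EventTable(df, channels = channels)
}

#' Write flow-cytometry events
#'
#' CSV is the canonical loss-free dialect (numeric values round-trip
#' exactly).  FCS output is float32 list mode (FCS 3.1), one population per
#' file; values round-trip within float32 representation.
#'
#' @param x an [EventTable-class]; for FCS the table must contain a single
#'   population.
#' @param path output file path.
#' @param format `"auto"` (by extension), `"csv"` or `"fcs"`.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(x, path, format = c("auto", "csv", "fcs")) {
  stopifnot(is(x, "EventTable"))
  if (nEvents(x) == 0L) stop("refusing to write an empty event table")
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.fcs$", path, ignore.case = TRUE)) "fcs" else "csv"
  ev <- eventData(x)
  if (format == "csv") {
    fwrite(as.data.table(ev), path)
    return(invisible(path))
  }
  k <- populationKeys(x)
  if (nrow(k) != 1L)
    stop("FCS output holds one population per file; got ", nrow(k),
         " populations — write populations separately or use CSV")
  mat <- cbind(FSC = ev$fsc, SSC = ev$ssc, YFP = ev$yfp_raw)
  .writeFCS(path, mat, keywords = c(
    "NP$STRAIN_ID" = k$strain_id, "NP$CONDITION_ID" = k$condition_id,
    "NP$REPLICATE_ID" = k$replicate_id, "NP$BATCH_ID" = k$batch_id))
  invisible(path)
}
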