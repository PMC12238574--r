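# DM machinery: the mean-dependence of expression noise is captured by a
# running median of SDs over points sorted by mean (median-based, so single
# outlying populations barely move the trend), smoothed by a cubic spline;
# a point's DM value is its vertical residual from that trend.

# centered running median; the window shrinks symmetrically at the edges so
# no data beyond the observed range is invented
.runningMedian <- function(v, window) {
  n <- length(v)
  h <- (window - 1L) %/% 2L
  out <- numeric(n)
  for (i in seq_len(n)) {
    k <- min(h, i - 1L, n - i)
    out[i] <- median(v[(i - k):(i + k)])
  }
  out
}

.autoWindow <- function(n) {
  w <- round(0.15 * n)
  if (w %% 2 == 0) w <- w + 1
  w <- max(11, min(101, w))
  # keep the auto window feasible on small tables
  wmax <- n %/% 2
  if (wmax %% 2 == 0) wmax <- wmax - 1
  as.integer(max(3, min(w, wmax)))
}

.fitTrendCore <- function(e, v, window, smoothing) {
  n <- length(e)
  stopifnot(length(v) == n)
  if (any(!is.finite(e))) stop("means must be finite")
  if (any(!is.finite(v) | v < 0)) stop("SDs must be finite and non-negative")
  if (identical(window, "auto")) window <- .autoWindow(n)
  window <- as.integer(window)
  if (window %% 2L != 1L) stop("window must be an odd integer")
  if (n < 2L * window)
    stop("only ", n, " points for window ", window,
         "; choose a smaller window (need at least 2 x window points)")
  rm_v <- .runningMedian(v, window)
  e_min <- min(e); e_max <- max(e)
  if (identical(smoothing, 0) || identical(smoothing, 0L)) {
    # no smoothing: the trend interpolates the running-median knots exactly
    agg <- tapply(rm_v, e, mean)
    xs <- as.numeric(names(agg))
    trend_fun <- if (length(xs) > 1L)
      approxfun(xs, as.numeric(agg), rule = 2L)
    else function(z) rep(as.numeric(agg), length(z))
    fitted <- rm_v
  } else {
    args <- list(x = e, y = rm_v, cv = FALSE)   # cv = FALSE: GCV
    if (is.numeric(smoothing)) args$spar <- smoothing
    else if (!identical(smoothing, "auto"))
      stop("smoothing must be \"auto\" or a numeric value (0 = interpolate)")
    fit <- do.call(smooth.spline, args)
    trend_fun <- function(z)
      predict(fit, pmin(pmax(z, e_min), e_max))$y
    fitted <- trend_fun(e)
  }
  list(window = window, running_median = rm_v, fitted = fitted,
       trend_fun = trend_fun)
}

#' Fit the noise-vs-mean trend and compute DM residuals
#'
#' Pools all (gene, condition) points of replicate-averaged `(E_pop,
#' V_pop)` into one global trend: points are sorted by mean (ties broken
#' stably by gene then condition), the running median of the SDs is taken
#' in a centred window of `window` points (shrinking symmetrically at the
#' edges), and a cubic smoothing spline is fitted through the
#' running-median sequence (stiffness chosen by generalized
#' cross-validation when `smoothing = "auto"`).  Each point's `DM_V` is its
#' vertical deviation from the trend, `v - trend(e)` — a mean-compensated
#' noise measure comparable between genes of different expression levels.
#'
#' @param points a `data.frame` with columns `gene_id`, `condition_id` and
#'   either `e`, `v` or `e_pop_mean`, `v_pop_mean`.
#' @param window odd integer running-median window in points, or `"auto"`
#'   (the odd number nearest 15% of the point count, bounded to
#'   \[11, 101\]).
#' @param smoothing `"auto"` (GCV), `0` (spline disabled: the trend
#'   interpolates the running-median knots exactly), or a numeric `spar`
#'   passed to [stats::smooth.spline()].
#' @return a [NoiseTrend-class].
#' @seealso [meanDmvPerGene()], [dmFromTable()], [trendValues()]
#' @export
fitNoiseTrend <- function(points, window = "auto", smoothing = "auto") {
  points <- as.data.frame(points)
  if (!"e" %in% names(points) && "e_pop_mean" %in% names(points))
    points$e <- points$e_pop_mean
  if (!"v" %in% names(points) && "v_pop_mean" %in% names(points))
    points$v <- points$v_pop_mean
  need <- c("gene_id", "condition_id", "e", "v")
  if (!all(need %in% names(points)))
    stop("points must have columns ", paste(need, collapse = ", "))
  ord <- order(points$e, points$gene_id, points$condition_id,
               method = "radix")
  p <- points[ord, need, drop = FALSE]
  core <- .fitTrendCore(p$e, p$v, window, smoothing)
  p$dm <- p$v - core$fitted
  rownames(p) <- NULL
  new("NoiseTrend", points = p,
      knots = data.frame(e = p$e, median_v = core$running_median),
      window = core$window, smoothing = smoothing,
      trend = core$trend_fun)
}

#' @rdname dmResiduals
#' @export
setMethod("dmResiduals", "NoiseTrend", function(object) object@points)

#' @rdname trendValues
#' @export
setMethod("trendValues", "NoiseTrend", function(object, e) object@trend(e))

setMethod("show", "NoiseTrend", function(object) {
  cat(sprintf(
    "NoiseTrend: %d points, window %d, smoothing %s, e range [%.3f, %.3f]\n",
    nrow(object@points), object@window,
    paste(format(object@smoothing), collapse = ""),
    min(object@points$e), max(object@points$e)))
})

#' Mean DM residual per gene
#'
#' Averages a gene's DM values (unweighted) across the nutrient conditions
#' in which it was measured, yielding one mean-compensated noise score per
#' gene.  Genes observed in a single condition are retained but flagged.
#'
#' @param trend a [NoiseTrend-class].
#' @return a `data.frame`: `gene_id`, `mean_dmv`, `n_conditions`,
#'   `low_support` (`TRUE` when only one condition contributed).
#' @export
meanDmvPerGene <- function(trend) {
  stopifnot(is(trend, "NoiseTrend"))
  dt <- as.data.table(trend@points)
  out <- dt[, list(mean_dmv = mean(dm), n_conditions = .N), by = gene_id]
  out <- as.data.frame(out[order(gene_id)])
  out$low_support <- out$n_conditions < 2L
  if (any(out$low_support))
    message(sum(out$low_support),
            " gene(s) have a single surviving condition; mean DM flagged")
  out
}

#' DM residuals of an arbitrary (mean, SD) table
#'
#' The same running-median + smoothing-spline residual machinery applied to
#' any table of per-key means and SDs — for instance log2 mRNA expression
#' means/SDs across environments, where the residual is the
#' transcriptional-plasticity measure `DM_env`.
#'
#' @param table a `data.frame` whose first column (or a column named `key`)
#'   identifies the entries, with numeric columns `mean` and `sd`.
#' @param window,smoothing as in [fitNoiseTrend()].
#' @return the input table with a `dm` column appended, in the original row
#'   order.
#' @export
dmFromTable <- function(table, window = "auto", smoothing = "auto") {
  table <- as.data.frame(table)
  key_col <- if ("key" %in% names(table)) "key" else names(table)[1L]
  if (!all(c("mean", "sd") %in% names(table)))
    stop("table must have numeric columns 'mean' and 'sd'")
  pts <- data.frame(gene_id = as.character(table[[key_col]]),
                    condition_id = as.character(seq_len(nrow(table))),
                    e = table$mean, v = table$sd)
  tr <- fitNoiseTrend(pts, window = window, smoothing = smoothing)
  res <- tr@points
  idx <- match(as.character(seq_len(nrow(table))), res$condition_id)
  out <- table
  out$dm <- res$dm[idx]
  out
}
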