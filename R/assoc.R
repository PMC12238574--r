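#' Spearman rank correlation
#'
#' Rank correlation with average-rank tie handling and a two-sided p-value
#' (exact for small tie-free samples, t-approximation otherwise, as in
#' [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length (at least 4).
#' @return a list: `r` (rho), `p` (two-sided p-value), `n`.
#' @export
spearmanAssoc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) != length(y) || length(x) < 4L)
    stop("need at least 4 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rank correlation undefined for a constant vector")
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided comparison of two independent groups: exact for small samples
#' without ties, normal approximation with tie and continuity correction
#' otherwise.  When the statistic equals its null expectation
#' `n1 * n2 / 2` — e.g. identical groups — the two-sided p is 1 by
#' definition (every permutation is at least as extreme).
#'
#' @param a,b numeric vectors (each at least 3 observations for a
#'   meaningful test; at least 1 required).
#' @return a list: `statistic` (Mann-Whitney U / W), `p`, `n1`, `n2`.
#' @export
rankSumTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  wt <- suppressWarnings(wilcox.test(a, b, alternative = "two.sided"))
  p <- wt$p.value
  if (isTRUE(all.equal(unname(wt$statistic),
                       length(a) * length(b) / 2))) p <- 1
  list(statistic = unname(wt$statistic), p = min(1, p),
       n1 = length(a), n2 = length(b))
}

#' Kruskal-Wallis test
#'
#' Chi-square approximation with tie correction across two or more groups.
#' The fully degenerate case (all observations identical) carries no
#' evidence against the null and is reported as p = 1.
#'
#' @param values numeric vector.
#' @param groups group labels, same length as `values`.
#' @return a list: `statistic` (H), `df`, `p`.
#' @export
kruskalWallisTest <- function(values, groups) {
  keep <- is.finite(values) & !is.na(groups)
  values <- values[keep]; groups <- factor(groups[keep])
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 observations")
  if (length(unique(values)) == 1L)
    return(list(statistic = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Brown-Forsythe test for equality of spread
#'
#' The median-centred variant of Levene's test: a one-way ANOVA F-test on
#' absolute deviations from the group medians, robust to non-normality.
#'
#' @param a,b numeric vectors (each at least 3 observations).
#' @return a list: `statistic` (F), `p`, `n1`, `n2`.
#' @export
brownForsytheTest <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 3L || length(b) < 3L)
    stop("each group needs at least 3 observations")
  y <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  lt <- car::leveneTest(y, g, center = median)
  list(statistic = lt[["F value"]][1L], p = lt[["Pr(>F)"]][1L],
       n1 = length(a), n2 = length(b))
}

#' Cumulative rank-scan curve
#'
#' Genes are ranked by `noise` in descending order and scanned from high to
#' low.  The cut-offs are the noise values of the genes at ranks
#' `min_first, min_first + 1, ..., n`; at each cut-off `x` the mean and
#' standard error (sample SD / sqrt(n)) of `covariate` are computed over
#' *all* genes with noise `>= x`.  The inclusive rule means ties spanning a
#' cut-off are all included, so the first (rightmost) point always holds at
#' least `min_first` genes; the default `min_first = 6` keeps the earliest
#' means and error bars from resting on fewer than five genes.
#'
#' @param noise numeric vector of per-gene noise scores.
#' @param covariate numeric vector, aligned with `noise` (e.g. MSR counts).
#' @param min_first rank of the first cut-off (default 6).
#' @param covariate_name label stored on the result.
#' @return a [CumulativeCurve-class].
#' @export
cumulativeCurve <- function(noise, covariate, min_first = 6L,
                            covariate_name = "covariate") {
  stopifnot(is.numeric(noise), is.numeric(covariate),
            length(noise) == length(covariate))
  keep <- is.finite(noise) & is.finite(covariate)
  noise <- noise[keep]; covariate <- covariate[keep]
  n <- length(noise)
  if (n < min_first)
    stop("need at least min_first = ", min_first, " genes; got ", n)
  ord <- order(noise, decreasing = TRUE)
  s <- noise[ord]; cv <- covariate[ord]
  # cumulative first and second moments along the descending ranking
  cs <- cumsum(cv); cs2 <- cumsum(cv^2)
  ranks <- seq.int(min_first, n)
  rows <- lapply(ranks, function(r) {
    x <- s[r]
    # inclusive cut-off: every gene whose noise ties the rank-r gene counts
    m <- max(which(s >= x))
    mean_cov <- cs[m] / m
    var_cov <- if (m > 1L) max(0, (cs2[m] - cs[m]^2 / m) / (m - 1L)) else 0
    data.frame(cutoff = x, n_genes = m, mean_cov = mean_cov,
               se_cov = sqrt(var_cov) / sqrt(m))
  })
  new("CumulativeCurve", curve = do.call(rbind, rows),
      covariate = covariate_name)
}

#' Cumulative rank-scan of plasticity against noise
#'
#' Identical machinery to [cumulativeCurve()] with per-gene plasticity as
#' the covariate: nonessential genes ranked by noise and scanned from high
#' to low.
#'
#' @inheritParams cumulativeCurve
#' @param plasticity numeric vector of per-gene plasticity values.
#' @return a [CumulativeCurve-class].
#' @export
cumulativePlasticityCurve <- function(noise, plasticity, min_first = 6L) {
  cumulativeCurve(noise, plasticity, min_first = min_first,
                  covariate_name = "plasticity")
}

#' @rdname curveTable
#' @export
setMethod("curveTable", "CumulativeCurve", function(object) object@curve)

setMethod("show", "CumulativeCurve", function(object) {
  cat(sprintf("CumulativeCurve (%s): %d cutoffs, %d..%d genes\n",
              object@covariate, nrow(object@curve),
              min(object@curve$n_genes), max(object@curve$n_genes)))
})

#' PCA of mean expression with missingness filtering
#'
#' Some conditions push many genes below the detection limit, which would
#' gut a complete-case PCA.  The two-step filter drops those conditions
#' first: (1) exclude conditions missing more than
#' `max_missing_genes_per_condition` genes; (2) keep only genes observed in
#' all remaining conditions.  Conditions are the observations; each gene is
#' centred (no scaling by default — all values share the log10 scale).
#'
#' @param e_matrix numeric matrix, genes x conditions, `NA` for missing
#'   gene x condition measurements; dimnames identify genes and conditions.
#' @param max_missing_genes_per_condition integer (default 4): a condition
#'   missing more genes than this is excluded.
#' @param scale. logical, scale genes to unit variance (default `FALSE`).
#' @return a [PcaResult-class].
#' @export
pcaExpression <- function(e_matrix, max_missing_genes_per_condition = 4L,
                          scale. = FALSE) {
  stopifnot(is.matrix(e_matrix), is.numeric(e_matrix))
  if (is.null(rownames(e_matrix)))
    rownames(e_matrix) <- paste0("gene", seq_len(nrow(e_matrix)))
  if (is.null(colnames(e_matrix)))
    colnames(e_matrix) <- paste0("cond", seq_len(ncol(e_matrix)))
  missing_per_cond <- colSums(is.na(e_matrix))
  keep_cond <- missing_per_cond <= max_missing_genes_per_condition
  sub <- e_matrix[, keep_cond, drop = FALSE]
  keep_gene <- rowSums(is.na(sub)) == 0L
  sub <- sub[keep_gene, , drop = FALSE]
  if (ncol(sub) < 3L || nrow(sub) < 3L) {
    report <- paste(sprintf("%s: %d missing", colnames(e_matrix),
                            missing_per_cond), collapse = "; ")
    stop("fewer than 3 conditions or 3 genes remain after the ",
         "missingness filter [", report, "]")
  }
  pc <- prcomp(t(sub), center = TRUE, scale. = scale.)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  new("PcaResult", scores = pc$x, loadings = pc$rotation,
      var_explained = ve,
      kept_conditions = colnames(sub), kept_genes = rownames(sub))
}

setMethod("show", "PcaResult", function(object) {
  cat(sprintf(
    "PcaResult: %d conditions x %d genes; PC1 %.1f%%, PC2 %.1f%%\n",
    length(object@kept_conditions), length(object@kept_genes),
    100 * object@var_explained[1L],
    if (length(object@var_explained) > 1L)
      100 * object@var_explained[2L] else NA_real_))
})
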