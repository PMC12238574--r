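makePoints <- function(e, v, gene = "g") {
  data.frame(gene_id = gene, condition_id = as.character(seq_along(e)),
             e = e, v = v)
}

test_that("the trend recovers a straight line with near-zero residuals", {
  e <- seq(1, 3, length.out = 200)
  v <- 0.5 - 0.1 * e
  tr <- fitNoiseTrend(makePoints(e, v), window = 15)
  expect_lt(max(abs(dmResiduals(tr)$dm)), 1e-6)
})

test_that("planted per-gene offsets are recovered as mean residuals", {
  set.seed(71)
  genes <- paste0("g", 1:20)
  offsets <- seq(-0.05, 0.045, length.out = 20)
  names(offsets) <- genes
  rows <- do.call(rbind, lapply(genes, function(g) {
    e <- runif(20, 1, 3)
    v <- 0.4 * exp(-e) + 0.1 + offsets[[g]]   # fixed monotone curve + offset
    data.frame(gene_id = g, condition_id = as.character(seq_along(e)),
               e = e, v = v)
  }))
  tr <- fitNoiseTrend(rows, window = 31)
  got <- meanDmvPerGene(tr)
  err <- got$mean_dmv - offsets[got$gene_id]
  # recovered offsets are correct up to a common trend-level shift
  expect_lt(max(abs(err - mean(err))), 0.01)
})

test_that("with smoothing disabled residuals equal the naive running median", {
  set.seed(72)
  for (i in 1:5) {
    n <- sample(100:400, 1)
    w <- 2 * sample(5:15, 1) + 1
    e <- sort(runif(n, 0, 4))
    v <- 0.3 * exp(-e) + 0.05 + rnorm(n, 0, 0.02)
    v <- pmax(v, 0)
    tr <- fitNoiseTrend(makePoints(e, v), window = w, smoothing = 0)
    pts <- dmResiduals(tr)
    expect_lt(max(abs(pts$dm - (pts$v - naiveRunningMedian(pts$v, w)))),
              1e-9)
  }
})

test_that("the residual identity dm = v - trend(e) holds at every point", {
  set.seed(73)
  e <- runif(300, 1, 3)
  v <- 0.2 * exp(-e) + 0.08 + abs(rnorm(300, 0, 0.02))
  tr <- fitNoiseTrend(makePoints(e, v))
  pts <- dmResiduals(tr)
  expect_lt(max(abs(pts$dm - (pts$v - trendValues(tr, pts$e)))), 1e-9)
  # constant extrapolation beyond the data range
  expect_equal(trendValues(tr, min(pts$e) - 10),
               trendValues(tr, min(pts$e)))
  expect_equal(trendValues(tr, max(pts$e) + 10),
               trendValues(tr, max(pts$e)))
})

test_that("adding a constant to every SD shifts the trend, not the residuals", {
  set.seed(74)
  e <- runif(250, 1, 3)
  v <- 0.3 * exp(-e) + 0.05 + abs(rnorm(250, 0, 0.01))
  t1 <- fitNoiseTrend(makePoints(e, v), window = 21)
  t2 <- fitNoiseTrend(makePoints(e, v + 0.7), window = 21)
  expect_lt(max(abs(dmResiduals(t2)$dm - dmResiduals(t1)$dm)), 1e-6)
  expect_equal(trendValues(t2, 2) - trendValues(t1, 2), 0.7,
               tolerance = 1e-6)
})

test_that("a single inflated point barely moves the trend elsewhere", {
  set.seed(75)
  e <- sort(runif(300, 1, 3))
  v <- 0.3 * exp(-e) + 0.05 + abs(rnorm(300, 0, 0.01))
  t1 <- fitNoiseTrend(makePoints(e, v), window = 31)
  v2 <- v; v2[150] <- v2[150] + 1.0
  t2 <- fitNoiseTrend(makePoints(e, v2), window = 31)
  other <- setdiff(seq_along(e), 150)
  expect_lt(max(abs(trendValues(t2, e[other]) -
                      trendValues(t1, e[other]))), 0.05)
})

test_that("mean DM per gene is the group mean of residuals", {
  pts <- data.frame(gene_id = c("g1", "g1", "g2"),
                    condition_id = c("c1", "c2", "c1"),
                    e = c(1, 2, 3), v = c(0.3, 0.2, 0.1),
                    dm = c(0.1, -0.1, 0.2))
  tr <- new("NoiseTrend", points = pts,
            knots = data.frame(e = pts$e, median_v = pts$v),
            window = 3L, smoothing = 0, trend = function(z) z)
  expect_message(got <- meanDmvPerGene(tr), "single surviving condition")
  expect_equal(got$mean_dmv[got$gene_id == "g1"], 0)
  expect_equal(got$mean_dmv[got$gene_id == "g2"], 0.2)
  expect_true(got$low_support[got$gene_id == "g2"])

  # random instance vs an independent group-by mean
  set.seed(76)
  e <- runif(200, 1, 3)
  v <- 0.2 + abs(rnorm(200, 0, 0.05))
  g <- sample(paste0("g", 1:10), 200, replace = TRUE)
  tr2 <- fitNoiseTrend(data.frame(gene_id = g,
                                  condition_id = as.character(1:200),
                                  e = e, v = v))
  got2 <- meanDmvPerGene(tr2)
  ref <- tapply(dmResiduals(tr2)$dm, dmResiduals(tr2)$gene_id, mean)
  expect_equal(got2$mean_dmv, as.numeric(ref[got2$gene_id]),
               tolerance = 1e-12)
})

test_that("dmFromTable applies the same machinery to generic tables", {
  set.seed(77)
  n <- 150
  tab <- data.frame(key = paste0("k", 1:n), mean = runif(n, 2, 8),
                    sd = 0.3)
  out <- dmFromTable(tab, window = 15)
  expect_equal(names(out), c("key", "mean", "sd", "dm"))
  # constant SD: residuals all ~0
  expect_lt(max(abs(out$dm)), 1e-6)

  # identical input through fitNoiseTrend gives identical residuals
  set.seed(78)
  tab2 <- data.frame(key = paste0("k", 1:n), mean = runif(n, 2, 8),
                     sd = 0.4 * exp(-runif(n, 2, 8) / 4) + 0.1)
  tab2$sd <- tab2$sd + abs(rnorm(n, 0, 0.02))
  out2 <- dmFromTable(tab2, window = 21, smoothing = 0)
  tr <- fitNoiseTrend(data.frame(gene_id = tab2$key,
                                 condition_id = as.character(1:n),
                                 e = tab2$mean, v = tab2$sd),
                      window = 21, smoothing = 0)
  pts <- dmResiduals(tr)
  expect_equal(out2$dm, pts$dm[match(tab2$key, pts$gene_id)],
               tolerance = 1e-12)
})

test_that("window validation guards the fit", {
  e <- 1:20 / 5
  expect_error(fitNoiseTrend(makePoints(e, rep(0.2, 20)), window = 15),
               "smaller window")
  expect_error(fitNoiseTrend(makePoints(e, rep(0.2, 20)), window = 4),
               "odd")
})
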