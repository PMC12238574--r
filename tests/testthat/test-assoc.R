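test_that("Spearman correlation handles perfect order and ties", {
  expect_equal(spearmanAssoc(c(1, 2, 3, 4), c(8, 6, 4, 2))$r, -1)
  expect_equal(spearmanAssoc(c(1, 2, 3, 5), c(1, 2, 3, 5))$r, 1)
  # tied data equal rank-then-Pearson
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  got <- spearmanAssoc(x, y)
  expect_equal(got$r, cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearmanAssoc(rep(1, 5), 1:5), "constant")
  expect_error(spearmanAssoc(1:3, 3:1), "at least 4")
})

test_that("rank-sum test matches exact enumeration and symmetry", {
  # {1,2,3} vs {4,5,6}: 2 of choose(6,3)=20 assignments are as extreme
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6))$p, 0.1)
  # identical multisets sit at the exact centre: two-sided p = 1
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p, 1)
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum detects a planted shift in lognormal groups", {
  set.seed(81)
  power_at <- function(shift) sum(vapply(1:100, function(i) {
    a <- rlnorm(22, 1, 0.5)
    b <- rlnorm(67, 1 + shift * 0.5, 0.5)  # shift in units of the log SD
    rankSumTest(a, b)$p < 0.05
  }, logical(1)))
  # 0.8-SD shift at n = 22 vs 67: rejected in a clear majority of runs
  expect_gt(power_at(0.8), 60)
  # power grows with the planted shift and exceeds the nominal level
  expect_gt(power_at(0.3), 10)
})

test_that("Kruskal-Wallis agrees with the hand-computed H statistic", {
  # three separated groups of 3: ranks 1-9, H = 12/90 * (12+75+192)/3... = 7.2
  v <- c(1, 2, 3, 10, 11, 12, 20, 21, 22)
  g <- rep(c("a", "b", "c"), each = 3)
  got <- kruskalWallisTest(v, g)
  expect_equal(got$statistic, 7.2, tolerance = 1e-12)
  expect_equal(got$df, 2)
  expect_lt(got$p, 0.05)
  # two groups: H relates monotonically to the rank-sum comparison
  v2 <- c(1, 3, 5, 7, 2, 4, 6, 20)
  g2 <- rep(c("a", "b"), each = 4)
  expect_equal(kruskalWallisTest(v2, g2)$p,
               kruskal.test(v2, factor(g2))$p.value)
  # fully degenerate data carry no evidence: p = 1
  expect_equal(kruskalWallisTest(rep(5, 6), rep(c("a", "b"), 3))$p, 1)
  expect_error(kruskalWallisTest(1:5, rep("a", 5)), "2 groups")
})

test_that("Brown-Forsythe equals ANOVA on deviations from group medians", {
  set.seed(82)
  a <- rnorm(30, 0, 1); b <- rnorm(25, 0, 2.5)
  got <- brownForsytheTest(a, b)
  # independent oracle: one-way ANOVA F on |x - median(group)|
  d <- c(abs(a - median(a)), abs(b - median(b)))
  g <- factor(rep(c("a", "b"), c(30, 25)))
  f_oracle <- anova(lm(d ~ g))[["F value"]][1]
  expect_equal(got$statistic, f_oracle, tolerance = 1e-10)

  # identical groups: zero statistic
  expect_equal(brownForsytheTest(a, a)$statistic, 0, tolerance = 1e-12)

  # 10x spread difference at n = 50 is detected
  set.seed(83)
  x <- rnorm(50, 0, 1); y <- rnorm(50, 0, 10)
  expect_lt(brownForsytheTest(x, y)$p, 0.01)
})

test_that("the cumulative curve matches hand computation on 1..6", {
  cc <- curveTable(cumulativeCurve(6:1, 6:1, min_first = 6))
  expect_equal(nrow(cc), 1L)
  expect_equal(cc$n_genes, 6L)
  expect_equal(cc$mean_cov, 3.5)
  expect_equal(cc$se_cov, sd(1:6) / sqrt(6), tolerance = 1e-12)
})

test_that("cumulative curves equal brute-force filter-and-average", {
  bruteCurve <- function(noise, covariate, min_first = 6) {
    s <- sort(noise, decreasing = TRUE)
    do.call(rbind, lapply(min_first:length(noise), function(r) {
      x <- s[r]
      sel <- covariate[noise >= x]
      data.frame(cutoff = x, n_genes = length(sel), mean_cov = mean(sel),
                 se_cov = if (length(sel) > 1) sd(sel) / sqrt(length(sel))
                          else 0)
    }))
  }
  set.seed(84)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    noise <- rnorm(n)
    covariate <- rpois(n, 2)
    got <- curveTable(cumulativeCurve(noise, covariate))
    ref <- bruteCurve(noise, covariate)
    expect_equal(got$cutoff, ref$cutoff, tolerance = 1e-12)
    expect_equal(got$n_genes, ref$n_genes)
    expect_equal(got$mean_cov, ref$mean_cov, tolerance = 1e-12)
    expect_equal(got$se_cov, ref$se_cov, tolerance = 1e-12)
  }
})

test_that("cumulative-curve structural properties hold", {
  set.seed(85)
  noise <- rnorm(30); covariate <- rnorm(30)
  cc <- curveTable(cumulativeCurve(noise, covariate))
  # last cutoff reproduces the global mean and SE exactly
  expect_equal(cc$mean_cov[nrow(cc)], mean(covariate), tolerance = 1e-12)
  expect_equal(cc$se_cov[nrow(cc)], sd(covariate) / sqrt(30),
               tolerance = 1e-12)
  expect_true(all(diff(cc$n_genes) >= 0))
  expect_gte(cc$n_genes[1], 6)
  # constant covariate: all means equal it, all SEs zero
  k <- curveTable(cumulativeCurve(noise, rep(2.5, 30)))
  expect_true(all(k$mean_cov == 2.5))
  expect_true(all(k$se_cov == 0))
  # removing the lowest-noise gene changes only the final point
  drop <- which.min(noise)
  cc2 <- curveTable(cumulativeCurve(noise[-drop], covariate[-drop]))
  expect_equal(cc2$mean_cov, cc$mean_cov[-nrow(cc)], tolerance = 1e-12)
})

test_that("the plasticity curve is the same machinery and is monotone for monotone input", {
  set.seed(86)
  noise <- rnorm(15); covariate <- rnorm(15)
  expect_equal(curveTable(cumulativePlasticityCurve(noise, covariate)),
               curveTable(cumulativeCurve(noise, covariate)))
  # plasticity increasing with noise: cumulative mean falls as the cutoff drops
  noise2 <- 15:1; plast <- 15:1 / 10
  cc <- curveTable(cumulativePlasticityCurve(noise2, plast))
  expect_true(all(diff(cc$mean_cov) <= 0))
  # min_first = n: single point, the global mean/SE
  one <- curveTable(cumulativeCurve(noise, covariate, min_first = 15))
  expect_equal(nrow(one), 1L)
  expect_equal(one$mean_cov, mean(covariate))
})

test_that("PCA applies the two-step missingness filter", {
  m <- matrix(rnorm(32), 8, 4,
              dimnames = list(paste0("g", 1:8), LETTERS[1:4]))
  m[1:5, "D"] <- NA           # condition D misses 5 genes -> excluded
  m[6, "A"] <- NA             # g6 missing in a retained condition -> dropped
  res <- pcaExpression(m)
  expect_equal(res@kept_conditions, c("A", "B", "C"))
  expect_equal(res@kept_genes, paste0("g", c(1:5, 7, 8)))
  expect_equal(sum(res@var_explained), 1, tolerance = 1e-9)
  expect_error(pcaExpression(matrix(NA_real_, 5, 5)), "missingness")
})

test_that("PCA reproduces the eigen-structure of the centred matrix", {
  # rank-1 matrix: PC1 explains everything
  g <- rnorm(6); w <- c(1, 2, 3, 4)
  r1 <- pcaExpression(outer(g, w))
  expect_equal(r1@var_explained[1], 1, tolerance = 1e-9)

  set.seed(87)
  m <- matrix(rnorm(200), 20, 10)
  res <- pcaExpression(m)
  centred <- t(scale(t(m), center = TRUE, scale = FALSE))
  recon <- res@scores %*% t(res@loadings)     # conditions x genes
  expect_equal(recon, t(centred), tolerance = 1e-9,
               ignore_attr = TRUE)
  ev <- eigen(cov(t(centred)))$values
  expect_equal(res@var_explained, ev[seq_along(res@var_explained)] /
                 sum(ev), tolerance = 1e-9)
})
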