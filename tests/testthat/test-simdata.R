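smallConfig <- function(seed = 1L, ...) {
  simulationConfig(n_nonessential = 6L, n_essential = 3L,
                   n_conditions = 4L, events_per_population = 300L,
                   seed = seed, ...)
}

test_that("the same seed reproduces the dataset bit-identically", {
  s1 <- simulateDataset(smallConfig(seed = 9))
  s2 <- simulateDataset(smallConfig(seed = 9))
  expect_identical(eventData(s1), eventData(s2))
  expect_identical(simTruth(s1), simTruth(s2))
  s3 <- simulateDataset(smallConfig(seed = 10))
  expect_false(identical(eventData(s1)$yfp_raw, eventData(s3)$yfp_raw))
})

test_that("enlarging the design leaves earlier populations unchanged", {
  small <- simulateDataset(smallConfig(seed = 4))
  big <- simulateDataset(simulationConfig(
    n_nonessential = 6L, n_essential = 3L, n_conditions = 6L,
    events_per_population = 300L, seed = 4L))
  ev_s <- eventData(small)
  ev_b <- eventData(big)
  shared <- ev_b[ev_b$condition_id %in% unique(ev_s$condition_id), ]
  ord <- function(d) d[order(d$condition_id, d$replicate_id, d$strain_id), ]
  a <- ord(ev_s); b <- ord(shared)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
})

test_that("the noise-free limit collapses every population to a point", {
  cfg <- simulationConfig(
    n_nonessential = 2L, n_essential = 1L, n_conditions = 2L,
    events_per_population = 100L, seed = 2L,
    noise_model = list(
      burst_size = 0,
      extrinsic = list(nonessential = c(intercept = -1e6,
                                        gene_scatter = 0),
                       essential = c(intercept = -1e6, gene_scatter = 0)),
      coupling = c(nonessential = 0, essential = 0)),
    cellsize_model = c(fsc_location_mean = 2.5, fsc_location_sd = 0.1,
                       size_scatter = 0, fsc_instrument_sd = 0,
                       ssc_instrument_sd = 0),
    measurement_model = c(autofluorescence_meanlog = log(30),
                          autofluorescence_sdlog = 0,
                          instrument_sd = 0))
  sim <- simulateDataset(cfg)
  ev <- eventData(sim)
  per_pop <- tapply(ev$yfp_raw,
                    paste(ev$strain_id, ev$condition_id, ev$replicate_id),
                    function(v) diff(range(v)))
  expect_true(all(per_pop == 0))
  # downstream V_pop is exactly zero
  res <- suppressWarnings(runPipeline(sim, min_events = 10, min_conditions = 2))
  expect_true(all(res$population_stats$v_pop == 0))
})

test_that("the copula plants the requested noise-plasticity rank coupling", {
  sim <- simulateDataset(simulationConfig(
    n_conditions = 1L, events_per_population = 1L, seed = 12))
  g <- simTruth(sim)$genes
  ne <- g[!g$essential, ]
  r_ne <- cor(ne$extrinsic_sd, ne$plasticity_scale, method = "spearman")
  expect_lt(abs(r_ne - 0.6), 0.15)   # gene-level sampling error at n = 67
  es <- g[g$essential, ]
  r_es <- cor(es$extrinsic_sd, es$plasticity_scale, method = "spearman")
  expect_lt(abs(r_es), 0.45)          # n = 22, planted 0
})

test_that("planted class differences point the right way", {
  sim <- simulateDataset(simulationConfig(
    n_conditions = 1L, events_per_population = 1L, seed = 13))
  g <- simTruth(sim)$genes
  expect_gt(median(g$plasticity_scale[!g$essential]),
            median(g$plasticity_scale[g$essential]))
  expect_gt(median(g$extrinsic_sd[!g$essential]),
            median(g$extrinsic_sd[g$essential]))
  expect_true(all(g$msr_count <= g$tr_count))
})

test_that("the mean-noise relationship has the two regimes", {
  # pooled populations: V falls with E at low expression, flattens on the
  # extrinsic floor at high expression
  run <- memo("regime_run", {
    sim <- simulateDataset(simulationConfig(
      events_per_population = 2000L, seed = 17))
    suppressWarnings(runPipeline(sim, min_events = 800L))
  })
  pts <- dmResiduals(run$noise_trend)
  lo <- pts$e <= quantile(pts$e, 1 / 3)
  hi <- pts$e >= quantile(pts$e, 2 / 3)
  expect_lt(cor(pts$v[lo], pts$e[lo], method = "spearman"), 0)
  expect_lt(abs(cor(pts$v[hi], pts$e[hi], method = "spearman")), 0.3)
})

test_that("invalid configurations are rejected with the offending fields", {
  expect_error(simulationConfig(events_per_population = 0),
               "events_per_population")
  expect_error(simulationConfig(
    noise_model = list(burst_size = 10,
                       extrinsic = list(
                         nonessential = c(intercept = -2, gene_scatter = 0.4),
                         essential = c(intercept = -3, gene_scatter = 0.4)),
                       coupling = c(nonessential = 1.5, essential = 0))),
    "coupling")
})
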