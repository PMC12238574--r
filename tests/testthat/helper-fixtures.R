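# Shared fixtures.  Heavy simulation runs are computed once per test
# session and memoised here so several test files can share them.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small event table spanning two populations
tinyEvents <- function() {
  EventTable(data.frame(
    strain_id = rep(c("gA", "gB"), each = 3),
    condition_id = "c1", replicate_id = "r1", batch_id = "b1",
    fsc = c(300, 320, 340, 280, 290, 310),
    ssc = c(250, 255, 260, 240, 245, 250),
    yfp_raw = c(120, 150, 180, 90, 100, 110)))
}

# independently coded naive running median: symmetric shrinking window
naiveRunningMedian <- function(v, window) {
  n <- length(v)
  h <- (window - 1) / 2
  vapply(seq_len(n), function(i) {
    k <- min(h, i - 1, n - i)
    median(v[(i - k):(i + k)])
  }, numeric(1))
}

# full default-design run: 89 genes x 20 conditions x 2 replicates x
# 10,000 events (the reference study scale)
defaultRun <- function() {
  memo("default_run", {
    sim <- simulateDataset(simulationConfig(seed = 42L))
    res <- runPipeline(sim)
    truth <- simTruth(sim)
    rm(sim)
    list(res = res, truth = truth)
  })
}

# reduced multi-seed runs: 20 seeds at 5,000 events/population with the
# QC floor scaled proportionally (2,000 events)
multiSeedRuns <- function() {
  memo("multi_seed_runs", {
    lapply(1:20, function(s) {
      sim <- simulateDataset(simulationConfig(
        events_per_population = 5000L, seed = s))
      res <- suppressWarnings(runPipeline(sim, min_events = 2000L))
      a <- res$associations
      list(seed = s,
           ne = a$noise_vs_plasticity_nonessential,
           es = a$noise_vs_plasticity_essential,
           p_plast = a$plasticity_by_essentiality$p,
           p_dmv = a$mean_dmv_by_essentiality$p)
    })
  })
}
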