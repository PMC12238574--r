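test_that("FSC mode estimation recovers point masses and planted modes", {
  # point mass
  expect_equal(estimateFscMode(rep(1000, 200)), 3)
  # unimodal symmetric about 2.5: KDE argmax within 0.05 at 50,000 events
  set.seed(21)
  fsc <- 10^rnorm(50000, 2.5, 0.12)
  expect_lt(abs(estimateFscMode(fsc) - 2.5), 0.05)
  # two-component mixture: the major mode wins
  set.seed(22)
  lf <- c(rnorm(35000, 2.0, 0.05), rnorm(15000, 3.0, 0.05))
  expect_lt(abs(estimateFscMode(10^lf) - 2.0), 0.05)
  expect_error(estimateFscMode(rep(1000, 10)), "too few")
})

test_that("gates are centred intervals of exact width 2 x halfwidth", {
  g <- buildFscGate(2.5)
  expect_equal(g@low, 2.4)
  expect_equal(g@high, 2.6)
  for (m in c(-1.2, 0, 2.5, 4.8)) {
    gg <- buildFscGate(m)
    expect_equal(gg@high - gg@low, 0.2)
  }
  g2 <- buildFscGate(2.0, halfwidth = 0.05)
  expect_equal(c(g2@low, g2@high), c(1.95, 2.05))
  expect_error(buildFscGate(2.5, halfwidth = 0), "positive")
  expect_error(buildFscGate(NaN), "finite")
})

test_that("gating keeps the closed interval and conserves events", {
  df <- data.frame(strain_id = "g", condition_id = "c", replicate_id = "r",
                   batch_id = "b", ssc = 300, yfp_raw = 100,
                   fsc = 10^c(2.39, 2.40, 2.55, 2.61))
  kept <- applyGate(EventTable(df), buildFscGate(2.5))
  expect_equal(sort(log10(eventData(kept)$fsc)), c(2.40, 2.55))
  expect_equal(attr(kept, "n_rejected"), 2L)

  # gate spanning the whole range keeps everything
  wide <- applyGate(EventTable(df), buildFscGate(2.5, halfwidth = 5))
  expect_equal(nEvents(wide), 4L)

  # conservation on a random table
  set.seed(31)
  df2 <- data.frame(strain_id = "g", condition_id = "c",
                    replicate_id = "r", batch_id = "b",
                    fsc = rlnorm(500, 5.8, 0.5), ssc = 300, yfp_raw = 100)
  ev2 <- EventTable(df2)
  out <- applyGate(ev2, buildFscGate(2.5))
  expect_equal(nEvents(out) + attr(out, "n_rejected"), nEvents(ev2))
})

test_that("autofluorescence is the linear-scale mean of the control", {
  base <- data.frame(strain_id = "BW", condition_id = "c",
                     replicate_id = "r", batch_id = "b", fsc = 300,
                     ssc = 300)
  ctl <- EventTable(cbind(base[rep(1, 200), ],
                          yfp_raw = rep(c(40, 60), 100)))
  expect_equal(suppressWarnings(estimateAutofluorescence(ctl)), 50)
  expect_equal(suppressWarnings(estimateAutofluorescence(rep(30, 150))), 30)
  set.seed(41)
  y <- rlnorm(10000, log(30), 0.3)
  expect_equal(estimateAutofluorescence(y), mean(y), tolerance = 1e-12)
  expect_error(estimateAutofluorescence(rep(30, 10)), "too few")
  expect_warning(estimateAutofluorescence(rep(c(20, 40), 100)),
                 "4,000")
})

test_that("background correction drops events at or below autofluorescence", {
  base <- data.frame(strain_id = "g", condition_id = "c",
                     replicate_id = "r", batch_id = "b", fsc = 300,
                     ssc = 300)
  ev <- EventTable(cbind(base[rep(1, 3), ], yfp_raw = c(150, 49, 50)))
  pop <- correctYfp(ev, 50, n_rejected_gate = 2L)
  expect_equal(pop@log_yfp, 2)           # log10(150 - 50)
  expect_equal(pop@n_rejected_background, 2L)  # 49 below, 50 exactly at
  expect_equal(nEvents(pop) + pop@n_rejected_gate +
                 pop@n_rejected_background, 5L)
  expect_error(correctYfp(ev, 0), "positive")
})

test_that("correction is order-independent up to permutation", {
  set.seed(51)
  base <- data.frame(strain_id = "g", condition_id = "c",
                     replicate_id = "r", batch_id = "b", fsc = 300,
                     ssc = 300)
  y <- rlnorm(300, log(120), 0.6)
  ev1 <- EventTable(cbind(base[rep(1, 300), ], yfp_raw = y))
  ev2 <- EventTable(cbind(base[rep(1, 300), ], yfp_raw = sample(y)))
  p1 <- correctYfp(ev1, 50); p2 <- correctYfp(ev2, 50)
  expect_equal(sort(p1@log_yfp), sort(p2@log_yfp))
  expect_equal(p1@n_rejected_background, p2@n_rejected_background)
})

test_that("the QC floor is 'fewer than', not 'at most'", {
  expect_false(qcPopulation(3999L))
  expect_true(qcPopulation(4000L))
  expect_true(qcPopulation(50000L))
  expect_true(qcPopulation(150L, min_events = 100L))
})
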