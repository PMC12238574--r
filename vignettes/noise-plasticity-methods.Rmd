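---
title: "Quantifying noise and plasticity in single-cell protein expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying noise and plasticity in single-cell protein expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noiseplast)
```

## The two quantities

A clonal population of cells growing in one environment still shows broad
cell-to-cell variation in the abundance of any given protein.  That
within-population heterogeneity is **noise**.  The same gene's *mean*
expression also moves when the environment changes — different carbon
sources, different nutrient supplements.  That across-environment movement
of the mean is **plasticity**.  `noiseplast` measures both from
flow-cytometry data on fluorescent-protein fusion strains (one reporter
strain per gene) grown under many nutrient conditions, and tests whether
they are coupled at the gene level.

Per gated, background-corrected population (one strain, one condition, one
biological replicate):

* `E_pop` — mean of log10 fluorescence,
* `V_pop` — sample standard deviation (denominator `n − 1`) of log10
  fluorescence.

Both are computed on the log scale because single-cell protein-number
distributions are long-tailed; a handful of very bright cells would
otherwise dominate the variance.  After averaging `E_pop` and `V_pop`
across biological replicates:

* **plasticity** of a gene = SD of its replicate-averaged `E_pop` across
  conditions;
* **noise** of a gene = its mean `DM_V` across conditions (next section).

## Why noise must be mean-compensated: `DM_V`

Noise depends strongly on the mean: at low expression, stochastic
production in bursts makes the squared coefficient of variation scale
roughly as 1/mean (intrinsic noise); at high expression, fluctuations in
shared cellular context set a mean-independent floor (extrinsic noise).
Comparing raw `V_pop` between genes of different expression levels would
mostly re-measure their means.

`fitNoiseTrend()` therefore pools all (gene, condition) points, sorts them
by `E_pop`, takes a **running median** of `V_pop` in a centred window, and
fits a **cubic smoothing spline** through the running-median sequence.  A
point's `DM_V` is its vertical residual from that trend.  The running
median, not a running mean, carries the real robustness burden: a single
aberrant population shifts the trend at other points by far less than its
own deviation.  The spline only irons out the staircase the median leaves
behind.

Numerical choices, all configurable:

* **Window**: the odd number nearest 15% of the point count, bounded to
  [11, 101].  A fraction-of-data window scales across dataset sizes; the
  bounds stop tiny datasets from using degenerate windows and huge ones
  from oversmoothing.
* **Edge rule**: the window shrinks symmetrically at the extremes (at the
  k-th point from an edge the window spans 2k − 1 points), so the trend
  never extrapolates beyond observed data.  `stats::runmed`'s end rules do
  not implement this convention, which is why the running median is coded
  in the package.
* **Spline stiffness**: chosen by generalized cross-validation
  (`smoothing = "auto"`); `smoothing = 0` disables the spline entirely and
  the trend interpolates the running-median knots — the mode used by the
  oracle tests, where residuals must equal an independently coded running
  median exactly.
* **Extrapolation**: constant at the boundary trend value.
* **Ties in `E_pop`**: stable sort by (e, gene, condition) keeps output
  deterministic.

`dmFromTable()` applies the identical machinery to any (mean, SD) table —
e.g. log2 mRNA means/SDs across environments, where the residual is the
transcriptional-plasticity measure `DM_env`.

Replicate averaging happens **before** trend fitting (the averaged
`(E_pop, V_pop)` points are what the trend sees).  The ordering is
genuinely ambiguous in the source protocol; averaging first matches the
stated sequence of operations, and `runPipeline(per_replicate_dm = TRUE)`
provides the alternative (trend on per-replicate points) as a sensitivity
analysis.  On default synthetic data the two orderings rank genes almost
identically (rank correlation > 0.8 in the test suite).

## Gating and background correction

Total fluorescence scales with cell size, and cell size shifts with
nutrient conditions.  The pipeline removes most of the size dependence by
a narrow forward-scatter gate built per (condition, measurement batch)
from the **cumulative population** — the pooled events of *all* strains
measured under that condition on that date:

1. the mode of log10 FSC of the pooled events is estimated by a Gaussian
   kernel density (Silverman bandwidth, argmax on a 512-point grid — robust
   to histogram binning, unlike a binned mode);
2. the gate is the closed interval mode ± 0.1 log10 units (width exactly
   0.2);
3. autofluorescence — the background emission of cells lacking the
   reporter — is the linear-scale mean of the gated control strain's raw
   fluorescence per (condition, batch) (median available via
   `autofluorescence_statistic`);
4. each gated event's corrected intensity is `yfp_raw − autofluorescence`;
   events at or below the background are removed (zero has no logarithm,
   and negative corrected intensities are measurement artefacts);
5. populations retaining fewer than 4,000 events are dropped, and
   conditions lacking two surviving replicates are dropped per gene.

The closed gate interval is a convention; boundary mass is negligible for
continuous data.  The acquisition thresholds instruments apply before
recording (FSC, SSC > 200 in the reference setup) are treated as metadata
and not re-applied.

## Association analyses

* `spearmanAssoc`, `rankSumTest`, `kruskalWallisTest` — thin, validated
  wrappers over the base R tests (average-rank ties, two-sided p-values).
  Two conventions are worth stating: a rank-sum statistic exactly at its
  null expectation reports p = 1 (every permutation is at least as
  extreme), and a fully degenerate Kruskal–Wallis input (all observations
  identical) reports p = 1 rather than NaN.
* `brownForsytheTest` — the median-centred Levene variant
  (`car::leveneTest`), for comparing spread between gene groups.
* `cumulativeCurve` — genes ranked by noise, scanned from high to low; at
  each cut-off (the noise of the gene at rank 6, 7, …) the mean ± SE
  (sample SD / √n) of a covariate such as the number of
  metabolite-sensing regulators is computed over all genes at or above
  the cut-off.  The inclusive (`>=`) rule is the only convention under
  which the first point is guaranteed to hold six genes, which is the
  point of starting at rank 6: means and error bars over fewer genes are
  unreliable.
* `pcaExpression` — PCA of the gene × condition `E_pop` matrix with a
  two-step missingness filter: conditions missing more than 4 genes are
  excluded first (some conditions push many reporters below detection),
  then only genes observed in all remaining conditions are kept.  Genes
  are centred but not scaled by default — all values already share the
  log10 scale, and scaling would inflate flat genes.

No multiple-testing correction is applied across the association tests;
the analyses are reported as individual hypothesis tests, matching
standard practice for this design.

## The growth-threshold essentiality classifier

Microplate OD595 assays classify knockout growth: the threshold is the
grand mean of the sterile-control wells plus five times the **mean of the
per-control-set sample SDs** ("mean SD among sterile controls" is read as
the mean of per-set SDs, the laboratory-natural grouping; a single pooled
SD is available via `grouping = "pooled"`).  A strain grows in a condition
when **strictly more than half** of its replicates exceed the threshold
(strict on both counts: 2 of 4 is not a majority, and OD exactly at the
threshold does not count).  A strain growing somewhere but not everywhere
is conditionally essential.  Strains growing nowhere get their own label
(`no_growth_all`) with a review flag rather than being folded into the
conditional class: for knockouts viable in rich medium, universal failure
in synthetic media is biologically conditional but usually signals an
assay problem.

## The synthetic-data generator

`simulateDataset()` draws full event-level datasets with known truth.  Per
gene *g*: a baseline log10 mean `β_g ~ N(2.5, 0.35)`; a regulator count
`msr_g ~ Poisson(1.5)` (nonessential) or `Poisson(0.5)` (essential); a
plasticity scale `P_g = softplus(intercept + slope·msr_g + scatter·a_g)`;
an extrinsic-noise SD `η_g = softplus(intercept + scatter·b_g)`, where
`(a_g, b_g)` is a standard-normal pair whose Pearson correlation
`2·sin(π·ρ/6)` plants a target *Spearman* correlation ρ between noise and
plasticity — 0.6 for nonessential genes, 0 for essential genes.  Per
condition *c*: a cell-size location `φ_c ~ N(2.5, 0.15)` and a
condition-specific mean shift `δ_gc = P_g·z_gc`, `z_gc ~ N(0, 1)`.  Per
cell: an extrinsic deviation `N(0, η_g)`; an intrinsic Gamma draw with
fixed burst size `b = 10` a.u. (CV² = b/mean — the simplest mechanism
producing the 1/mean regime at low expression without simulating
kinetics); a multiplicative cell-size factor that also drives FSC (which
is what makes the narrow gate matter); lognormal per-cell autofluorescence
(mean ≈ 31 a.u.) added to every event; and a reporter-free control strain
emitting autofluorescence only.

Class differences are planted the way the biology suggests: essential
genes get a lower plasticity intercept, a lower extrinsic floor, fewer
regulators, and zero noise–plasticity coupling.

Defaults describe the reference design: 67 + 22 genes, 20 conditions, 2
biological replicates each measured on its own date (batch = replicate
day), 10,000 events per population.  The baseline-mean location (2.5) puts
typical corrected intensities well above the ~31 a.u. autofluorescence so
that background removal does not gut low-expression populations, while the
0.35 gene scatter still produces a clear intrinsic-noise slope at the low
end.  One master seed determines everything; per-(gene, condition,
replicate) sub-streams mean that enlarging the design leaves earlier
populations bit-identical.

What the generator does *not* emulate: instrument drift and carryover,
doublets, spectral spillover, growth-rate-dependent global machinery, or
any mechanistic transcription–translation kinetics.  Passing tests
demonstrate that the *pipeline* recovers what was planted under this
statistical structure — not that real cytometry data satisfy the
generator's assumptions.

## Validation scales and reduced runs

The test suite validates the headline properties at two scales:

* one full-design run (89 genes × 20 conditions × 2 replicates × 10,000
  events) for the mean-compensation property — compensated noise is
  rank-uncorrelated with the mean (|ρ| < 0.1) while raw noise falls
  steeply with the mean in the lowest tercile;
* twenty reduced runs (5,000 events/population, seeds 1–20) for recovery
  of the planted coupling and class differences.  At 5,000 acquired
  events the ±0.1 gate (which keeps ~70% of events) leaves ~3,500, so the
  reduced runs scale the QC floor proportionally to 2,000 events; the
  4,000 default matches the reference protocol at full acquisition depth
  and stays untouched everywhere else.

## Known limitations

* The FCS reader/writer covers float32 list-mode FCS 3.0/3.1 with linear
  values — the dialect the pipeline itself emits — not log-amplified,
  integer, or multi-dataset files.  CSV is the canonical loss-free
  interchange format.
* The spline stiffness under `"auto"` is GCV-chosen per dataset, so DM
  values are comparable within a run but not across runs with different
  point sets; window sensitivity should be checked with the `window`
  argument when datasets are small.
* `DM_V` does not decompose noise into intrinsic and extrinsic components;
  that requires dual-reporter data.
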