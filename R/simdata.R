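# Synthetic flow-cytometry generator.  The generative model plants, per
# gene, a plasticity scale (SD of the condition-specific shift of the log10
# mean) and an extrinsic-noise SD, rank-coupled through a Gaussian copula;
# per cell, a Gamma intrinsic draw with fixed burst size reproduces the
# CV^2 ~ 1/mean regime at low expression while the extrinsic term sets the
# mean-independent noise floor at high expression.  Cell size enters
# fluorescence multiplicatively and drives FSC, motivating the narrow gate.

.softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))

# deterministic sub-stream seeds: changing the number of conditions or
# replicates never perturbs the draws of earlier populations
.subSeed <- function(seed, gene = 0L, cond = 0L, rep = 0L, stream = 0L) {
  as.integer((abs(seed) + 1000003 * gene + 10007 * cond + 101 * rep +
                777767 * stream) %% 2147483647)
}

#' Simulation configuration
#'
#' Builds and validates the parameter list for [simulateDataset()].  The
#' defaults describe the reference study design: 67 nonessential and 22
#' essential reporter genes, 20 nutrient conditions, 2 biological
#' replicates measured on separate dates, 10,000 events per population,
#' log10 fluorescence means centred near 2.5 a.u., an intrinsic burst size
#' of 10 a.u., gene-specific extrinsic noise floors (lower for the
#' essential class), and a planted gene-level rank correlation of 0.6
#' between extrinsic noise and plasticity for nonessential genes (0 for
#' essential genes).
#'
#' @param n_nonessential,n_essential gene counts per class.
#' @param n_conditions,n_replicates,events_per_population design sizes.
#' @param seed integer master seed; fully determines the dataset.
#' @param base_mean_log10 `c(location, scale)` of the per-gene baseline
#'   log10 mean expression (a.u.).
#' @param msr_rate per-class Poisson rate of metabolic-sensory-regulator
#'   counts.
#' @param tr_extra_rate per-class Poisson rate of additional (non-MSR)
#'   transcriptional regulators; `tr_count = msr_count + extra`.
#' @param plasticity_model per-class `c(intercept, msr_slope,
#'   gene_scatter)`; the gene's plasticity scale is
#'   `softplus(intercept + msr_slope * msr + gene_scatter * z)` (log10
#'   units).
#' @param noise_model list: `burst_size` (a.u.), per-class `extrinsic`
#'   `c(intercept, gene_scatter)` mapped through softplus to the extrinsic
#'   SD (log10 units), and per-class `coupling` — the target Spearman
#'   correlation between a gene's extrinsic noise and its plasticity scale.
#' @param cellsize_model `c(fsc_location_mean, fsc_location_sd,
#'   size_scatter, fsc_instrument_sd, ssc_instrument_sd)`: per-condition
#'   log10 FSC locations and within-population scatter (log10 units).
#' @param measurement_model `c(autofluorescence_meanlog,
#'   autofluorescence_sdlog, instrument_sd)`: per-cell lognormal
#'   autofluorescence (natural-log parameters, linear a.u.) and
#'   multiplicative instrument noise (log10 units).
#' @param control_strain identifier of the reporter-free control strain.
#' @return a validated named list of class `"SimulationConfig"`.
#' @export
simulationConfig <- function(
    n_nonessential = 67L, n_essential = 22L, n_conditions = 20L,
    n_replicates = 2L, events_per_population = 10000L, seed = 1L,
    base_mean_log10 = c(location = 2.5, scale = 0.35),
    msr_rate = c(nonessential = 1.5, essential = 0.5),
    tr_extra_rate = c(nonessential = 2, essential = 1),
    plasticity_model = list(
      nonessential = c(intercept = -1.8, msr_slope = 0.25,
                       gene_scatter = 0.5),
      essential = c(intercept = -2.3, msr_slope = 0.1,
                    gene_scatter = 0.5)),
    noise_model = list(
      burst_size = 10,
      extrinsic = list(
        nonessential = c(intercept = -2.6, gene_scatter = 0.4),
        essential = c(intercept = -3.0, gene_scatter = 0.4)),
      coupling = c(nonessential = 0.6, essential = 0)),
    cellsize_model = c(fsc_location_mean = 2.5, fsc_location_sd = 0.15,
                       size_scatter = 0.08, fsc_instrument_sd = 0.05,
                       ssc_instrument_sd = 0.1),
    measurement_model = c(autofluorescence_meanlog = log(30),
                          autofluorescence_sdlog = 0.3,
                          instrument_sd = 0.02),
    control_strain = "CONTROL") {
  cfg <- list(
    n_nonessential = as.integer(n_nonessential),
    n_essential = as.integer(n_essential),
    n_conditions = as.integer(n_conditions),
    n_replicates = as.integer(n_replicates),
    events_per_population = as.integer(events_per_population),
    seed = as.integer(seed),
    base_mean_log10 = base_mean_log10, msr_rate = msr_rate,
    tr_extra_rate = tr_extra_rate, plasticity_model = plasticity_model,
    noise_model = noise_model, cellsize_model = cellsize_model,
    measurement_model = measurement_model,
    control_strain = as.character(control_strain))
  bad <- character()
  if (cfg$n_nonessential < 0L || cfg$n_essential < 0L ||
      cfg$n_nonessential + cfg$n_essential < 1L)
    bad <- c(bad, "n_nonessential/n_essential")
  if (cfg$n_conditions < 1L) bad <- c(bad, "n_conditions")
  if (cfg$n_replicates < 1L) bad <- c(bad, "n_replicates")
  if (cfg$events_per_population < 1L) bad <- c(bad, "events_per_population")
  if (base_mean_log10[["scale"]] < 0) bad <- c(bad, "base_mean_log10")
  if (any(msr_rate < 0) || any(tr_extra_rate < 0))
    bad <- c(bad, "msr_rate/tr_extra_rate")
  if (noise_model$burst_size < 0) bad <- c(bad, "noise_model$burst_size")
  if (any(abs(noise_model$coupling) > 1))
    bad <- c(bad, "noise_model$coupling (must be in [-1, 1])")
  if (any(cellsize_model[-1] < 0)) bad <- c(bad, "cellsize_model scales")
  if (measurement_model[["autofluorescence_sdlog"]] < 0 ||
      measurement_model[["instrument_sd"]] < 0)
    bad <- c(bad, "measurement_model scales")
  for (cls in c("nonessential", "essential")) {
    if (plasticity_model[[cls]][["gene_scatter"]] < 0)
      bad <- c(bad, paste0("plasticity_model$", cls))
    if (noise_model$extrinsic[[cls]][["gene_scatter"]] < 0)
      bad <- c(bad, paste0("noise_model$extrinsic$", cls))
  }
  if (length(bad))
    stop("invalid simulation config field(s): ", paste(bad, collapse = ", "))
  structure(cfg, class = "SimulationConfig")
}

# per-population event draws; a fixed draw order keeps sub-streams stable
.popEvents <- function(n, L, eta, burst, phi, cs, mm, control = FALSE) {
  e_dev <- rnorm(n, 0, eta)
  mu <- 10^(L + e_dev)
  a_prot <- if (burst > 0) rgamma(n, shape = mu / burst, scale = burst)
            else mu
  s <- 10^rnorm(n, phi, cs[["size_scatter"]])
  fsc <- s * 10^rnorm(n, 0, cs[["fsc_instrument_sd"]])
  ssc <- s * 10^rnorm(n, 0, cs[["ssc_instrument_sd"]])
  af <- rlnorm(n, mm[["autofluorescence_meanlog"]],
               mm[["autofluorescence_sdlog"]])
  yfp <- if (control) af
         else a_prot * (s / 10^phi) *
              10^rnorm(n, 0, mm[["instrument_sd"]]) + af
  list(fsc = fsc, ssc = ssc, yfp_raw = yfp)
}

#' Simulate a synthetic flow-cytometry dataset with known truth
#'
#' Draws a full multi-strain, multi-condition event dataset (including a
#' reporter-free control strain emitting autofluorescence only) from the
#' generative model described in [simulationConfig()], and records every
#' planted quantity.  All randomness derives from the single `seed`:
#' sub-streams are derived per (gene, condition, replicate), so enlarging
#' the design leaves earlier populations bit-identical.
#'
#' @param config a [simulationConfig()] list.
#' @return a [FlowSimulation-class].
#' @examples
#' sim <- simulateDataset(simulationConfig(
#'   n_nonessential = 3, n_essential = 1, n_conditions = 2,
#'   events_per_population = 200, seed = 7))
#' sim
#' @export
simulateDataset <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  n_genes <- cfg$n_nonessential + cfg$n_essential
  classes <- rep(c("nonessential", "essential"),
                 c(cfg$n_nonessential, cfg$n_essential))
  gene_ids <- sprintf("g%03d", seq_len(n_genes))

  # --- gene-level draws (master stream) ---
  set.seed(.subSeed(cfg$seed, stream = 1L))
  beta <- rnorm(n_genes, cfg$base_mean_log10[["location"]],
                cfg$base_mean_log10[["scale"]])
  msr <- integer(n_genes); tr_extra <- integer(n_genes)
  lat_a <- numeric(n_genes); lat_b <- numeric(n_genes)
  for (cls in c("nonessential", "essential")) {
    idx <- which(classes == cls)
    if (!length(idx)) next
    msr[idx] <- rpois(length(idx), cfg$msr_rate[[cls]])
    tr_extra[idx] <- rpois(length(idx), cfg$tr_extra_rate[[cls]])
    # Gaussian copula: Pearson r giving the target Spearman coupling
    rho_s <- cfg$noise_model$coupling[[cls]]
    r <- 2 * sin(pi * rho_s / 6)
    a <- rnorm(length(idx))
    b <- r * a + sqrt(1 - r^2) * rnorm(length(idx))
    lat_a[idx] <- a; lat_b[idx] <- b
  }
  plast_scale <- numeric(n_genes); eta <- numeric(n_genes)
  for (cls in c("nonessential", "essential")) {
    idx <- which(classes == cls)
    if (!length(idx)) next
    pm <- cfg$plasticity_model[[cls]]
    plast_scale[idx] <- .softplus(pm[["intercept"]] +
      pm[["msr_slope"]] * msr[idx] + pm[["gene_scatter"]] * lat_a[idx])
    em <- cfg$noise_model$extrinsic[[cls]]
    eta[idx] <- .softplus(em[["intercept"]] +
                            em[["gene_scatter"]] * lat_b[idx])
  }

  # --- condition-level draws ---
  cond_ids <- sprintf("c%02d", seq_len(cfg$n_conditions))
  phi <- vapply(seq_len(cfg$n_conditions), function(ci) {
    set.seed(.subSeed(cfg$seed, cond = ci, stream = 2L))
    rnorm(1L, cfg$cellsize_model[["fsc_location_mean"]],
          cfg$cellsize_model[["fsc_location_sd"]])
  }, numeric(1))

  # --- gene x condition true means ---
  z <- matrix(0, n_genes, cfg$n_conditions)
  for (gi in seq_len(n_genes)) for (ci in seq_len(cfg$n_conditions)) {
    set.seed(.subSeed(cfg$seed, gene = gi, cond = ci, stream = 3L))
    z[gi, ci] <- rnorm(1L)
  }
  L <- beta + plast_scale * z   # recycles beta/plast_scale down columns

  # --- per-population events ---
  cs <- cfg$cellsize_model; mm <- cfg$measurement_model
  n_ev <- cfg$events_per_population
  n_pops <- (n_genes + 1L) * cfg$n_conditions * cfg$n_replicates
  # preallocated columns: no per-population tables, no rbind
  fsc <- numeric(n_pops * n_ev)
  ssc <- numeric(n_pops * n_ev)
  yfp <- numeric(n_pops * n_ev)
  pop_strain <- character(n_pops); pop_cond <- character(n_pops)
  pop_rep <- character(n_pops); pop_batch <- character(n_pops)
  k <- 0L
  for (ci in seq_len(cfg$n_conditions)) {
    for (ri in seq_len(cfg$n_replicates)) {
      for (gi in seq_len(n_genes + 1L)) {   # last index: control strain
        control <- gi > n_genes
        set.seed(.subSeed(cfg$seed, gene = gi, cond = ci, rep = ri,
                          stream = 4L))
        ev <- .popEvents(n_ev,
                         L = if (control) 0 else L[gi, ci],
                         eta = if (control) 0 else eta[gi],
                         burst = cfg$noise_model$burst_size,
                         phi = phi[ci], cs = cs, mm = mm,
                         control = control)
        at <- k * n_ev + seq_len(n_ev)
        fsc[at] <- ev$fsc; ssc[at] <- ev$ssc; yfp[at] <- ev$yfp_raw
        k <- k + 1L
        pop_strain[k] <- if (control) cfg$control_strain else gene_ids[gi]
        pop_cond[k] <- cond_ids[ci]
        pop_rep[k] <- paste0("r", ri)
        pop_batch[k] <- paste0("b", ri)
      }
    }
  }
  events <- data.frame(
    strain_id = rep(pop_strain, each = n_ev),
    condition_id = rep(pop_cond, each = n_ev),
    replicate_id = rep(pop_rep, each = n_ev),
    batch_id = rep(pop_batch, each = n_ev),
    fsc = fsc, ssc = ssc, yfp_raw = yfp)
  rm(fsc, ssc, yfp)

  af_mean <- exp(mm[["autofluorescence_meanlog"]] +
                   mm[["autofluorescence_sdlog"]]^2 / 2)
  truth <- list(
    genes = data.frame(gene_id = gene_ids, class = classes,
                       essential = classes == "essential",
                       msr_count = msr, tr_count = msr + tr_extra,
                       beta = beta, plasticity_scale = plast_scale,
                       extrinsic_sd = eta),
    gene_condition = data.frame(
      gene_id = rep(gene_ids, times = cfg$n_conditions),
      condition_id = rep(cond_ids, each = n_genes),
      true_mean = as.numeric(L)),
    conditions = data.frame(condition_id = cond_ids,
                            fsc_mode_log10 = phi,
                            autofluorescence_mean = af_mean))

  gene_meta <- truth$genes[, c("gene_id", "essential", "msr_count",
                               "tr_count")]
  set.seed(.subSeed(cfg$seed, stream = 5L))
  condition_meta <- data.frame(
    condition_id = cond_ids,
    carbon_source = rep(c("glucose", "glycerol", "mannose"),
                        length.out = cfg$n_conditions),
    environment_id = sprintf("%02d", seq_len(cfg$n_conditions)),
    supplement_richness = sample(1:8, cfg$n_conditions, replace = TRUE))

  new("FlowSimulation", events = EventTable(events), truth = truth,
      gene_meta = gene_meta, condition_meta = condition_meta,
      config = unclass(cfg))
}

#' @rdname simTruth
#' @export
setMethod("simTruth", "FlowSimulation", function(object) object@truth)

#' @describeIn simulateDataset events accessor.
#' @aliases eventData,FlowSimulation-method
#' @param x a FlowSimulation.
#' @export
setMethod("eventData", "FlowSimulation", function(x) eventData(x@events))

setMethod("show", "FlowSimulation", function(object) {
  g <- object@truth$genes
  cat(sprintf(
    "FlowSimulation: %d genes (%d nonessential, %d essential), %d conditions, %d replicates, %d events/population (seed %d)\n",
    nrow(g), sum(!g$essential), sum(g$essential),
    object@config$n_conditions, object@config$n_replicates,
    object@config$events_per_population, object@config$seed))
})

#' Simulate a microplate growth assay with planted labels
#'
#' Growing wells draw OD595 from `Normal(grow_mean, grow_sd)` and
#' non-growing and sterile wells from `Normal(sterile_mean, sterile_sd)`
#' (clipped at 0; means sit many SDs above 0).  The first `n_conditional`
#' strains fail in a random nonempty proper subset of conditions, the next
#' `n_never` fail everywhere, and the rest grow everywhere.
#'
#' @param n_strains,n_conditions design sizes.
#' @param n_conditional,n_never planted label counts.
#' @param n_replicates biological replicates per strain x condition
#'   (default 4).
#' @param grow_mean,grow_sd,sterile_mean,sterile_sd OD595 parameters.
#' @param n_sterile_wells sterile control wells per condition (default 4).
#' @param seed integer seed.
#' @return a list: `assay` (rows for all strains plus `"STERILE"` wells),
#'   `truth` (per strain x condition planted growth), `labels` (per-strain
#'   planted label).
#' @export
simulateGrowthAssay <- function(n_strains = 100L, n_conditions = 6L,
                                n_conditional = 5L, n_never = 0L,
                                n_replicates = 4L,
                                grow_mean = 0.5, grow_sd = 0.05,
                                sterile_mean = 0.05, sterile_sd = 0.005,
                                n_sterile_wells = 4L, seed = 1L) {
  stopifnot(n_conditional + n_never <= n_strains, n_conditions >= 2L,
            n_replicates >= 1L, n_sterile_wells >= 2L)
  if (grow_mean <= sterile_mean + 5 * sterile_sd)
    warning("grow_mean is within 5 sterile SDs of the sterile mean; ",
            "planted labels may be unrecoverable by design")
  set.seed(.subSeed(seed, stream = 6L))
  strains <- sprintf("s%03d", seq_len(n_strains))
  conds <- sprintf("c%02d", seq_len(n_conditions))
  grows <- matrix(TRUE, n_strains, n_conditions,
                  dimnames = list(strains, conds))
  for (i in seq_len(n_conditional)) {
    n_fail <- sample(seq_len(n_conditions - 1L), 1L)
    grows[i, sample(n_conditions, n_fail)] <- FALSE
  }
  if (n_never > 0L)
    grows[n_conditional + seq_len(n_never), ] <- FALSE

  rows <- vector("list", n_strains * n_conditions + n_conditions)
  k <- 0L
  for (ci in seq_len(n_conditions)) {
    for (si in seq_len(n_strains)) {
      mu <- if (grows[si, ci]) grow_mean else sterile_mean
      sdv <- if (grows[si, ci]) grow_sd else sterile_sd
      k <- k + 1L
      rows[[k]] <- data.frame(
        strain_id = strains[si], condition_id = conds[ci],
        replicate_id = paste0("r", seq_len(n_replicates)),
        od595 = pmax(0, rnorm(n_replicates, mu, sdv)))
    }
    k <- k + 1L
    rows[[k]] <- data.frame(
      strain_id = "STERILE", condition_id = conds[ci],
      replicate_id = paste0("w", seq_len(n_sterile_wells)),
      od595 = pmax(0, rnorm(n_sterile_wells, sterile_mean, sterile_sd)))
  }
  label <- ifelse(rowSums(grows) == n_conditions, "grows_everywhere",
                  ifelse(rowSums(grows) == 0L, "no_growth_all",
                         "conditionally_essential"))
  list(assay = do.call(rbind, rows),
       truth = data.frame(strain_id = rep(strains, n_conditions),
                          condition_id = rep(conds, each = n_strains),
                          grows_true = as.logical(grows)),
       labels = data.frame(strain_id = strains, label_true = label))
}
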