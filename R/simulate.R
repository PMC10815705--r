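# synthetic data: TPM matrices with planted gene classes, and damped-cosine
# bioluminescence traces with known rhythm parameters

#' Planted gene-class labels
#'
#' The regulatory regimes a simulated gene can be planted in, expressed as a
#' triple of log2 fold changes (delta_N1, delta_N2, delta_ND) applied in the
#' single and double knockouts relative to WT:
#' \describe{
#'   \item{null}{(0, 0, 0) — unaffected by either knockout.}
#'   \item{ndko_exclusive_up/_down}{(0, 0, ±delta) — responds only when both
#'     paralogs are ablated (redundant/compensatory regulation).}
#'   \item{additive_up/_down}{(±delta/2, ±delta/2, ±delta) — each single
#'     knockout contributes half the double-knockout effect.}
#'   \item{alpha_dominant_up/_down}{(±delta, 0, ±delta) — the first paralog
#'     carries the effect; the second knockout leaves the gene unchanged.}
#'   \item{beta_dominant_up/_down}{(0, ±delta, ±delta) — mirror image.}
#' }
#'
#' @format Character vector of the nine labels.
#' @export
PLANTED_CLASSES <- c(
  "null",
  "ndko_exclusive_up", "ndko_exclusive_down",
  "additive_up", "additive_down",
  "alpha_dominant_up", "alpha_dominant_down",
  "beta_dominant_up", "beta_dominant_down"
)

# log2 effect triple (N1KO, N2KO, NDKO) for one class label
class_effects <- function(label, delta) {
  switch(label,
    null                = c(0, 0, 0),
    ndko_exclusive_up   = c(0, 0, delta),
    ndko_exclusive_down = c(0, 0, -delta),
    additive_up         = c(delta / 2, delta / 2, delta),
    additive_down       = c(-delta / 2, -delta / 2, -delta),
    alpha_dominant_up   = c(delta, 0, delta),
    alpha_dominant_down = c(-delta, 0, -delta),
    beta_dominant_up    = c(0, delta, delta),
    beta_dominant_down  = c(0, -delta, -delta),
    stop("unknown planted class: ", label, call. = FALSE)
  )
}

#' Simulation configuration for planted-class TPM matrices
#'
#' @param n_genes Number of genes to simulate.
#' @param class_fractions Named numeric vector mapping [PLANTED_CLASSES]
#'   labels to fractions; must sum to 1. Gene counts per class are allocated
#'   deterministically by the largest-remainder method, then classes are
#'   assigned to gene indices in the order the fractions are given
#'   (downstream stages are permutation-invariant over genes, so random
#'   assignment would add nothing).
#' @param baseline_log2_mean,baseline_log2_sd Mean and sd of the per-gene
#'   baseline expression on the log2-TPM scale.
#' @param replicate_sd Between-replicate noise sd in log2 units.
#' @param n_replicates Replicates per genotype (>= 2).
#' @param delta Planted effect magnitude in log2 units; default `log2(3)`,
#'   i.e. a 3-fold change, comfortably past a 1.5-fold DEG threshold.
#' @param seed Integer seed; a single seed drives all randomness so the same
#'   configuration is bit-reproducible.
#' @param tpm_rescale If `TRUE`, rescale every sample column to sum to 1e6
#'   (true TPM normalisation). Off by default because compositional
#'   rescaling perturbs the planted fold changes; turn it on to stress-test
#'   downstream stages against renormalisation.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       class_fractions = c(null = 0.80,
                                           ndko_exclusive_up = 0.04,
                                           ndko_exclusive_down = 0.04,
                                           additive_up = 0.02,
                                           additive_down = 0.02,
                                           alpha_dominant_up = 0.02,
                                           alpha_dominant_down = 0.02,
                                           beta_dominant_up = 0.02,
                                           beta_dominant_down = 0.02),
                       baseline_log2_mean = 4,
                       baseline_log2_sd = 2,
                       replicate_sd = 0.15,
                       n_replicates = 4,
                       delta = log2(3),
                       seed = 1L,
                       tpm_rescale = FALSE) {
  if (is.null(names(class_fractions)) ||
      !all(names(class_fractions) %in% PLANTED_CLASSES)) {
    stop("class_fractions must be named with planted class labels",
         call. = FALSE)
  }
  if (abs(sum(class_fractions) - 1) > 1e-8) {
    stop("class_fractions must sum to 1", call. = FALSE)
  }
  if (n_replicates < 2) stop("n_replicates must be >= 2", call. = FALSE)
  if (replicate_sd < 0) stop("replicate_sd must be >= 0", call. = FALSE)
  structure(list(n_genes = as.integer(n_genes),
                 class_fractions = class_fractions,
                 baseline_log2_mean = baseline_log2_mean,
                 baseline_log2_sd = baseline_log2_sd,
                 replicate_sd = replicate_sd,
                 n_replicates = as.integer(n_replicates),
                 delta = delta,
                 seed = as.integer(seed),
                 tpm_rescale = isTRUE(tpm_rescale)),
            class = "sim_config")
}

# largest-remainder allocation of n items to the given fractions;
# ties on the remainder are broken by order of appearance
allocate_classes <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac_part <- raw - base
    take <- order(-frac_part, seq_along(fractions))[seq_len(rem)]
    base[take] <- base[take] + 1
  }
  counts <- as.integer(base)
  names(counts) <- names(fractions)
  counts
}

#' Simulate a knockout-panel TPM matrix with planted gene classes
#'
#' Generates a 4-genotype (WT, N1KO, N2KO, NDKO) by `n_replicates` TPM
#' matrix. For gene g in sample s of genotype G,
#' `log2 TPM = baseline_g + delta_G(class_g) + Normal(0, replicate_sd^2)`,
#' with `delta_WT = 0`, and `TPM = 2^log2`. Effects are applied on the log2
#' scale before exponentiation so the planted fold changes are exact and
#' direction-symmetric.
#'
#' @param config A [sim_config()].
#' @return A list with elements `study` (an [expression_study()]) and
#'   `truth`, a data frame with one row per gene: `gene`, `class`,
#'   `delta_n1`, `delta_n2`, `delta_nd` (the planted log2 effects).
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, seed = 7))
#' table(sim$truth$class)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  counts <- allocate_classes(config$class_fractions, n)
  dropped <- names(counts)[counts == 0L & config$class_fractions > 0]
  if (length(dropped) > 0L) {
    warning("class(es) dropped (fraction too small for n_genes): ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  labels <- rep(names(counts), times = counts)
  gene_ids <- sprintf("gene%05d", seq_len(n))

  genotype <- rep(GENOTYPES, each = config$n_replicates)
  replicate <- rep(seq_len(config$n_replicates), times = length(GENOTYPES))
  samples <- paste(genotype, replicate, sep = "_")
  design <- data.frame(sample = samples, genotype = genotype,
                       replicate = replicate, stringsAsFactors = FALSE)

  eff <- t(vapply(labels, class_effects, numeric(3), delta = config$delta))
  colnames(eff) <- MUTANT_GENOTYPES
  # per-genotype log2 offset per gene (WT = 0)
  shift <- cbind(WT = 0, eff)[, genotype, drop = FALSE]

  set.seed(config$seed)
  baseline <- stats::rnorm(n, config$baseline_log2_mean,
                           config$baseline_log2_sd)
  noise <- matrix(stats::rnorm(n * length(samples), 0, config$replicate_sd),
                  nrow = n)
  log2tpm <- baseline + shift + noise
  tpm <- 2^log2tpm
  dimnames(tpm) <- list(gene_ids, samples)
  if (config$tpm_rescale) {
    tpm <- sweep(tpm, 2L, colSums(tpm), "/") * 1e6
  }

  truth <- data.frame(gene = gene_ids, class = labels,
                      delta_n1 = eff[, "N1KO"], delta_n2 = eff[, "N2KO"],
                      delta_nd = eff[, "NDKO"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(study = expression_study(tpm, design), truth = truth)
}

#' Configuration for a simulated bioluminescence trace
#'
#' Emulates a plate-reader recording of a clock-gene reporter after
#' synchronisation: a damped cosine riding on a mesor plus linear trend,
#' sampled every 20 min by default.
#'
#' @param mesor Rhythm-adjusted mean, in signal units.
#' @param trend_slope Linear drift, units per hour.
#' @param amplitude Initial half peak-to-trough amplitude, signal units.
#' @param damping_rate Exponential damping of the oscillation, 1/h.
#' @param period Oscillation period in hours.
#' @param acrophase Peak time in hours.
#' @param noise_sd Additive Gaussian noise sd, signal units.
#' @param duration Recording length in hours.
#' @param sampling_interval Sampling step in hours (default 1/3, i.e. 20 min).
#' @param seed Integer seed.
#' @return A list of class `biolum_sim_config`.
#' @export
biolum_sim_config <- function(mesor = 100, trend_slope = 0, amplitude = 30,
                              damping_rate = 0.01, period = 24,
                              acrophase = 6, noise_sd = 1.5,
                              duration = 96, sampling_interval = 1 / 3,
                              seed = 1L) {
  if (period <= 0) stop("period must be > 0", call. = FALSE)
  if (duration <= 0) stop("duration must be > 0", call. = FALSE)
  if (sampling_interval <= 0) {
    stop("sampling_interval must be > 0", call. = FALSE)
  }
  structure(list(mesor = mesor, trend_slope = trend_slope,
                 amplitude = amplitude, damping_rate = damping_rate,
                 period = period, acrophase = acrophase, noise_sd = noise_sd,
                 duration = duration, sampling_interval = sampling_interval,
                 seed = as.integer(seed)),
            class = "biolum_sim_config")
}

#' Simulate a bioluminescence reporter time series
#'
#' `y(t) = mesor + trend_slope * t +
#'   amplitude * exp(-damping_rate * t) * cos(2 * pi * (t - acrophase) / period)
#'   + Normal(0, noise_sd^2)`
#' on the grid `t = 0, dt, 2 dt, ..., <= duration`.
#'
#' @param config A [biolum_sim_config()].
#' @return Data frame with columns `time_h` and `signal`.
#' @examples
#' ts <- simulate_bioluminescence(biolum_sim_config(noise_sd = 0))
#' nrow(ts) # 289 points: 96 h at 20-min intervals, t = 0 inclusive
#' @export
simulate_bioluminescence <- function(config) {
  stopifnot(inherits(config, "biolum_sim_config"))
  n_steps <- round(config$duration / config$sampling_interval)
  t <- (0:n_steps) * config$sampling_interval
  set.seed(config$seed)
  y <- config$mesor + config$trend_slope * t +
    config$amplitude * exp(-config$damping_rate * t) *
      cos(2 * pi * (t - config$acrophase) / config$period) +
    stats::rnorm(length(t), 0, config$noise_sd)
  data.frame(time_h = t, signal = y)
}
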