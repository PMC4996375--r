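#' Configuration for the synthetic two-cohort generator
#'
#' Describes a pair of platform-distinct expression cohorts sharing one
#' gene-symbol universe, with a subset of "signal" genes whose expression
#' modulates the survival hazard. Defaults are the desk-scale study
#' conditions used throughout the package's own validation.
#'
#' @param n_samples_1,n_samples_2 Samples per cohort.
#' @param n_probes_1,n_probes_2 Probes per platform. Platforms draw probe
#'   sets independently; a gene may be measured by several probes on one
#'   platform and by none on the other (signal genes always have at least one
#'   probe on both).
#' @param n_genes Size of the shared gene-symbol universe.
#' @param n_signal_genes Number of planted survival-signal genes.
#' @param effect_size Marginal log-hazard change per 1 SD of a signal gene's
#'   expression. Signal genes co-vary through one latent per-sample factor
#'   (see `signal_cor`), so their joint hazard contribution stays realistic
#'   while each gene's marginal effect is exactly `effect_size`.
#' @param signal_cor Loading of each signal gene on the latent prognostic
#'   factor, in (0, 1]. Default 0.7.
#' @param baseline_scale Weibull scale of the baseline survival time, months.
#' @param baseline_shape Weibull shape (dimensionless).
#' @param censoring_rate Target marginal fraction of right-censored samples,
#'   in `[0, 1)`; achieved by calibrating an independent exponential
#'   censoring distribution.
#' @param noise_sd SD of per-probe measurement noise around the gene-level
#'   signal (log-intensity units).
#' @param probes_per_gene_range Integer `c(min, max)` per-gene probe counts.
#' @param seed Integer seed; identical configs (incl. seed) give
#'   bit-identical cohorts.
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(n_samples_1 = 150, n_samples_2 = 150,
                       n_probes_1 = 2000, n_probes_2 = 1500,
                       n_genes = 1000, n_signal_genes = 20,
                       effect_size = 1.0, signal_cor = 0.7,
                       baseline_scale = 30, baseline_shape = 1.2,
                       censoring_rate = 0.2, noise_sd = 0.5,
                       probes_per_gene_range = c(1L, 3L), seed = 1L) {
  cfg <- list(n_samples_1 = as.integer(n_samples_1),
              n_samples_2 = as.integer(n_samples_2),
              n_probes_1 = as.integer(n_probes_1),
              n_probes_2 = as.integer(n_probes_2),
              n_genes = as.integer(n_genes),
              n_signal_genes = as.integer(n_signal_genes),
              effect_size = as.numeric(effect_size),
              signal_cor = as.numeric(signal_cor),
              baseline_scale = as.numeric(baseline_scale),
              baseline_shape = as.numeric(baseline_shape),
              censoring_rate = as.numeric(censoring_rate),
              noise_sd = as.numeric(noise_sd),
              probes_per_gene_range = as.integer(probes_per_gene_range),
              seed = as.integer(seed))
  counts <- c(cfg$n_samples_1, cfg$n_samples_2, cfg$n_probes_1, cfg$n_probes_2,
              cfg$n_genes, cfg$n_signal_genes)
  if (any(counts <= 0L)) stopf("all counts in the simulation config must be positive")
  if (cfg$n_signal_genes > cfg$n_genes)
    stopf("n_signal_genes (%d) exceeds n_genes (%d)", cfg$n_signal_genes, cfg$n_genes)
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1)
    stopf("censoring_rate must lie in [0, 1)")
  if (cfg$noise_sd < 0) stopf("noise_sd must be >= 0")
  if (cfg$signal_cor <= 0 || cfg$signal_cor > 1) stopf("signal_cor must lie in (0, 1]")
  if (cfg$baseline_scale <= 0 || cfg$baseline_shape <= 0)
    stopf("Weibull baseline scale and shape must be positive")
  r <- cfg$probes_per_gene_range
  if (length(r) != 2L || r[1] < 1L || r[2] < r[1])
    stopf("probes_per_gene_range must be c(min, max) with 1 <= min <= max")
  for (np in c(cfg$n_probes_1, cfg$n_probes_2)) {
    if (np < cfg$n_signal_genes)
      stopf("each platform needs at least one probe per signal gene")
    if (np > cfg$n_genes * r[2])
      stopf("n_probes (%d) exceeds n_genes * max probes per gene (%d)",
            np, cfg$n_genes * r[2])
  }
  class(cfg) <- "sim_config"
  cfg
}

# distribute n_probes over genes: every signal gene gets >= 1 probe, per-gene
# counts capped at the configured maximum, remainder spread at random
alloc_probe_counts <- function(n_genes, n_probes, max_per_gene, signal_idx) {
  counts <- integer(n_genes)
  counts[signal_idx] <- 1L
  cap <- pmax(max_per_gene - counts, 0L)
  remaining <- n_probes - sum(counts)
  slots <- rep.int(seq_len(n_genes), cap)
  if (remaining > 0) {
    add <- slots[sample.int(length(slots), remaining)]
    counts <- counts + tabulate(add, n_genes)
  }
  counts
}

simulate_one_cohort <- function(cfg, which, genes, signal_idx, signs) {
  n <- if (which == 1L) cfg$n_samples_1 else cfg$n_samples_2
  n_probes <- if (which == 1L) cfg$n_probes_1 else cfg$n_probes_2
  set.seed(substream_seed(cfg$seed, "cohort", which))

  counts <- alloc_probe_counts(cfg$n_genes, n_probes, cfg$probes_per_gene_range[2],
                               signal_idx)
  gene_of_probe <- rep.int(seq_len(cfg$n_genes), counts)
  probe_ids <- sprintf("P%d_%05d", which, seq_len(n_probes))
  sample_ids <- sprintf("C%d_S%03d", which, seq_len(n))

  # latent prognostic factor and gene-level scores (SD 1 per gene)
  f <- rnorm(n)
  rho <- cfg$signal_cor
  z <- matrix(rnorm(cfg$n_genes * n), cfg$n_genes, n)
  if (length(signal_idx))
    z[signal_idx, ] <- rho * outer(signs, f) + sqrt(1 - rho^2) * z[signal_idx, ]

  mu_gene <- rnorm(cfg$n_genes, mean = 8, sd = 1)
  offset <- rnorm(n_probes, sd = 0.5)
  x <- z[gene_of_probe, , drop = FALSE] +
    matrix(rnorm(n_probes * n, sd = cfg$noise_sd), n_probes, n)
  x <- x + mu_gene[gene_of_probe] + offset
  dimnames(x) <- list(probe_ids, sample_ids)

  # Weibull PH survival: hazard scaled by exp(eta); marginal effect of a
  # signal gene's expression on the log hazard is effect_size per SD
  eta <- if (cfg$effect_size > 0) (cfg$effect_size / rho) * f else rep(0, n)
  tt <- cfg$baseline_scale * (-log(runif(n)) / exp(eta))^(1 / cfg$baseline_shape)
  tt <- pmax(tt, 1e-6)
  if (cfg$censoring_rate > 0) {
    target <- cfg$censoring_rate
    rate <- uniroot(function(r) mean(1 - exp(-r * tt)) - target,
                    lower = 1e-12, upper = 1e6, tol = 1e-12)$root
    cens <- rexp(n, rate)
    time <- pmin(tt, cens)
    event <- as.integer(tt <= cens)
  } else {
    time <- tt
    event <- rep(1L, n)
  }

  expr_cohort(matrix = x,
              annotation = data.frame(probe_id = probe_ids,
                                      gene_symbol = genes[gene_of_probe],
                                      stringsAsFactors = FALSE),
              survival = data.frame(sample_id = sample_ids,
                                    time_months = time, event = event,
                                    stringsAsFactors = FALSE),
              cohort_id = sprintf("cohort%d", which))
}

#' Generate a pair of platform-distinct cohorts with planted signal genes
#'
#' Both cohorts share one gene-symbol universe but draw probe sets (IDs,
#' counts per gene, offsets, noise) independently, emulating two microarray
#' platforms. A chosen subset of signal genes co-varies with a latent
#' per-sample prognostic factor that scales the Weibull hazard, so their
#' expression associates with survival in both cohorts with a consistent
#' direction; censoring times are drawn independently and calibrated to the
#' requested marginal rate.
#'
#' @param config A [sim_config()].
#' @return A list of class `cohort_pair` with elements `cohort1`, `cohort2`
#'   (each an [expr_cohort()]), `signal_genes` (character), and
#'   `signal_signs` (named -1/+1: the planted direction, +1 meaning higher
#'   expression shortens survival).
#' @examples
#' pair <- generate_cohort_pair(sim_config(n_samples_1 = 40, n_samples_2 = 40,
#'   n_probes_1 = 60, n_probes_2 = 50, n_genes = 30, n_signal_genes = 5))
#' pair$cohort1
#' @export
generate_cohort_pair <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  set.seed(substream_seed(config$seed, "universe"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  signal_idx <- sort(sample.int(config$n_genes, config$n_signal_genes))
  signs <- sample(c(-1L, 1L), config$n_signal_genes, replace = TRUE)
  names(signs) <- genes[signal_idx]

  c1 <- simulate_one_cohort(config, 1L, genes, signal_idx, signs)
  c2 <- simulate_one_cohort(config, 2L, genes, signal_idx, signs)
  structure(list(cohort1 = c1, cohort2 = c2,
                 signal_genes = genes[signal_idx], signal_signs = signs,
                 config = config),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("Synthetic cohort pair\n")
  print(x$cohort1); print(x$cohort2)
  cat(sprintf("  planted signal genes: %d (effect %.2f per SD)\n",
              length(x$signal_genes), x$config$effect_size))
  invisible(x)
}

#' Invert a gene's survival association in cohort 2 only
#'
#' Produces a known-drop fixture for the direction-consistency filter: the
#' gene's probes in cohort 2 are reflected around their per-probe means, so
#' its expression trend against survival flips sign there while the marginal
#' expression distribution is preserved. Cohort 1 is untouched.
#'
#' @param pair A `cohort_pair`.
#' @param gene Gene symbol present on both platforms, or `NULL` for a no-op.
#' @return The modified pair, with the conflicted gene recorded in
#'   `pair$conflict_gene`.
#' @export
plant_direction_conflict <- function(pair, gene) {
  stopifnot(inherits(pair, "cohort_pair"))
  if (is.null(gene) || length(gene) == 0L) return(pair)
  gene <- as.character(gene)
  for (ch in c("cohort1", "cohort2")) {
    if (!gene %in% pair[[ch]]$annotation$gene_symbol)
      stopf("gene '%s' has no probe in %s", gene, ch)
  }
  idx <- which(pair$cohort2$annotation$gene_symbol == gene)
  m <- pair$cohort2$matrix
  m[idx, ] <- 2 * rowMeans(m[idx, , drop = FALSE]) - m[idx, , drop = FALSE]
  pair$cohort2$matrix <- m
  pair$conflict_gene <- gene
  pair
}
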