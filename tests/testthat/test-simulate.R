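test_that("identical config and seed reproduce cohorts bit-identically", {
  cfg <- sim_config(n_probes_1 = 120, n_probes_2 = 100, n_genes = 60,
                    n_signal_genes = 6, n_samples_1 = 50, n_samples_2 = 50,
                    seed = 9)
  p1 <- generate_cohort_pair(cfg)
  p2 <- generate_cohort_pair(cfg)
  expect_identical(p1$cohort1$matrix, p2$cohort1$matrix)
  expect_identical(p1$cohort2$matrix, p2$cohort2$matrix)
  expect_identical(p1$cohort1$survival, p2$cohort1$survival)
  expect_identical(p1$signal_genes, p2$signal_genes)
})

test_that("generated cohorts satisfy the structural invariants", {
  pair <- small_pair()
  cfg <- pair$config
  for (ch in list(pair$cohort1, pair$cohort2)) {
    expect_identical(dim(ch$matrix),
                     c(length(ch$annotation$probe_id), nrow(ch$survival)))
    expect_identical(rownames(ch$matrix), ch$annotation$probe_id)
    expect_false(anyNA(ch$annotation$gene_symbol))
    expect_true(all(ch$survival$time_months > 0))
    counts <- table(ch$annotation$gene_symbol)
    expect_lte(max(counts), cfg$probes_per_gene_range[2])
    # every planted signal gene is measured on this platform
    expect_true(all(pair$signal_genes %in% ch$annotation$gene_symbol))
  }
  # platforms are distinct: disjoint probe IDs, shared gene universe
  expect_length(intersect(rownames(pair$cohort1$matrix),
                          rownames(pair$cohort2$matrix)), 0)
})

test_that("censoring calibration achieves roughly the requested rate", {
  pair <- generate_cohort_pair(sim_config(
    n_samples_1 = 150, n_samples_2 = 150, n_probes_1 = 500, n_probes_2 = 400,
    n_genes = 1000, n_signal_genes = 20, effect_size = 0.7,
    censoring_rate = 0.2, seed = 1))
  for (ch in list(pair$cohort1, pair$cohort2)) {
    frac <- mean(ch$survival$event == 0)
    expect_gte(frac, 0.10)
    expect_lte(frac, 0.30)
  }
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_signal_genes = 50, n_genes = 10), "exceeds n_genes")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(sim_config(noise_sd = -1), "noise_sd")
  expect_error(sim_config(n_probes_1 = 10, n_signal_genes = 20, n_genes = 30),
               "at least one probe per signal gene")
  expect_error(sim_config(n_probes_1 = 1e6), "exceeds n_genes")
})

test_that("stronger planted effects yield stronger recovered Cox coefficients", {
  med_beta <- vapply(c(0.3, 1.0), function(eff) {
    pair <- generate_cohort_pair(sim_config(
      n_probes_1 = 300, n_probes_2 = 100, n_genes = 150, n_signal_genes = 10,
      effect_size = eff, seed = 5))
    ch <- pair$cohort1
    signal_probes <- ch$annotation$probe_id[
      ch$annotation$gene_symbol %in% pair$signal_genes]
    betas <- vapply(signal_probes, function(p)
      abs(fit_cox_univariate(ch$matrix[p, ], ch$survival)$beta), numeric(1))
    median(betas)
  }, numeric(1))
  expect_gt(med_beta[2], med_beta[1])
})

test_that("plant_direction_conflict inverts the trend in cohort 2 only", {
  pair <- small_pair()
  gene <- pair$signal_genes[2]
  mod <- plant_direction_conflict(pair, gene)
  expect_identical(mod$cohort1$matrix, pair$cohort1$matrix)

  mean_diff <- function(ch, g, cutoff = 23) {
    d <- dichotomize(ch$survival, cutoff)
    probes <- ch$annotation$probe_id[ch$annotation$gene_symbol == g]
    x <- ch$matrix[probes, , drop = FALSE]
    mean(rowMeans(x[, d$included & d$label == 1, drop = FALSE])) -
      mean(rowMeans(x[, d$included & d$label == 0, drop = FALSE]))
  }
  d1 <- mean_diff(mod$cohort1, gene)
  d2_before <- mean_diff(pair$cohort2, gene)
  d2_after <- mean_diff(mod$cohort2, gene)
  expect_equal(sign(d2_after), -sign(d2_before))
  expect_true(sign(d1) != sign(d2_after))

  expect_error(plant_direction_conflict(pair, "NOT_A_GENE"), "no probe")
  expect_identical(plant_direction_conflict(pair, NULL), pair)
})
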