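# Independent oracles and small fixtures shared across tests. Everything here
# is deliberately written as plain brute force, separate from the package's
# own code paths.

# Breslow partial log-likelihood by direct risk-set enumeration
breslow_loglik_direct <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid-search maximizer of the Breslow partial likelihood
cox_grid_beta <- function(x, time, event, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  E <- exp(outer(x, grid))
  ll <- numeric(length(grid))
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + x[i] * grid - log(colSums(E[risk, , drop = FALSE]))
  }
  grid[which.max(ll)]
}

# Cohen's kappa by direct per-category marginal products (no contingency table)
kappa_direct <- function(a, b) {
  cats <- unique(c(a, b))
  p_o <- mean(a == b)
  p_e <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), numeric(1)))
  (p_o - p_e) / (1 - p_e)
}

# random small survival dataset with at least 2 events and a continuous covariate
random_toy_surv <- function(n, seed) {
  set.seed(seed)
  repeat {
    event <- rbinom(n, 1, 0.7)
    if (sum(event) >= 2) break
  }
  list(x = rnorm(n),
       survival = data.frame(time_months = sort(rexp(n, 0.1)) + 0.5,
                             event = event))
}

# small simulated cohort pair, cached per options so repeated tests reuse it
.pair_cache <- new.env(parent = emptyenv())
small_pair <- function(seed = 3, effect_size = 1.0, n_probes_1 = 400,
                       n_probes_2 = 300, n_genes = 200, n_signal_genes = 10,
                       n_samples = 150) {
  key <- paste(seed, effect_size, n_probes_1, n_probes_2, n_genes,
               n_signal_genes, n_samples, sep = "_")
  if (is.null(.pair_cache[[key]])) {
    .pair_cache[[key]] <- generate_cohort_pair(sim_config(
      n_samples_1 = n_samples, n_samples_2 = n_samples,
      n_probes_1 = n_probes_1, n_probes_2 = n_probes_2,
      n_genes = n_genes, n_signal_genes = n_signal_genes,
      effect_size = effect_size, seed = seed))
  }
  .pair_cache[[key]]
}
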