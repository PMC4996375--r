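test_that("Newton-Raphson matches the likelihood-grid oracle on toy data", {
  s <- data.frame(time_months = 1:6, event = c(1, 1, 0, 1, 1, 0))
  x <- c(0.5, -1, 2, 0, -0.5, 1)
  fit <- fit_cox_univariate(x, s, standardize = FALSE)
  expect_true(fit$converged)
  oracle <- cox_grid_beta(x, s$time_months, s$event)
  expect_lt(abs(fit$beta - oracle), 1e-3)
  # and the fitted beta is the likelihood maximizer locally
  ll <- breslow_loglik_direct(fit$beta, x, s$time_months, s$event)
  expect_gte(ll, breslow_loglik_direct(fit$beta + 0.01, x, s$time_months, s$event))
  expect_gte(ll, breslow_loglik_direct(fit$beta - 0.01, x, s$time_months, s$event))
})

test_that("a monotone partial likelihood is flagged, not 'converged' at a boundary", {
  # here the partial log-likelihood increases in beta without bound: deaths
  # occur in strict order of descending expression, so the risk ordering is
  # perfectly separated and no finite maximizer exists
  s <- data.frame(time_months = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 0))
  x <- c(2, 1, 1, 0, 0)
  b <- seq(1, 9, by = 2)
  ll <- vapply(b, breslow_loglik_direct, numeric(1),
               x = x, time = s$time_months, event = s$event)
  expect_true(all(diff(ll) > 0))
  fit <- fit_cox_univariate(x, s, standardize = FALSE)
  expect_false(fit$converged)
  expect_true(is.na(fit$p_value))
})

test_that("Newton-Raphson agrees with grid search across random toy datasets", {
  compared <- 0
  for (seed in 1:25) {
    d <- random_toy_surv(n = sample(5:8, 1), seed = seed)
    fit <- fit_cox_univariate(d$x, d$survival, standardize = FALSE)
    if (!fit$converged || abs(fit$beta) > 4.9) next  # separation cases excluded
    oracle <- cox_grid_beta(d$x, d$survival$time_months, d$survival$event)
    expect_lt(abs(fit$beta - oracle), 1e-3)
    compared <- compared + 1
  }
  expect_gte(compared, 15)
})

test_that("fits agree with the survival package under both tie methods", {
  skip_if_not_installed("survival")
  set.seed(33)
  n <- 80
  x <- rnorm(n)
  time <- round(rexp(n, 0.05)) + 1  # integer times -> ties
  event <- rbinom(n, 1, 0.7)
  s <- data.frame(time_months = time, event = event)
  for (ties in c("breslow", "efron")) {
    ours <- fit_cox_univariate(x, s, standardize = FALSE, ties = ties)
    ref <- survival::coxph(survival::Surv(time, event) ~ x, ties = ties)
    expect_equal(ours$beta, unname(coef(ref)), tolerance = 1e-6)
    expect_equal(ours$se, unname(sqrt(vcov(ref)[1, 1])), tolerance = 1e-6)
  }
})

test_that("standardization makes the fit scale-invariant", {
  set.seed(2)
  d <- random_toy_surv(30, seed = 14)
  f1 <- fit_cox_univariate(d$x, d$survival)
  f2 <- fit_cox_univariate(2 * d$x, d$survival)
  expect_equal(f1$beta, f2$beta)
  expect_equal(f1$p_value, f2$p_value)
})

test_that("degenerate inputs are flagged with reason codes, not p-values", {
  s <- data.frame(time_months = 1:10, event = rep(1, 10))
  f <- fit_cox_univariate(rep(3, 10), s)
  expect_false(f$converged)
  expect_match(f$reason, "constant")
  expect_true(is.na(f$p_value))

  s2 <- data.frame(time_months = 1:10, event = c(1, rep(0, 9)))
  f <- fit_cox_univariate(rnorm(10), s2)
  expect_false(f$converged)
  expect_match(f$reason, "fewer than 2 events")

  # perfect risk-order separation -> monotone likelihood, excluded
  s3 <- data.frame(time_months = 1:20, event = rep(1, 20))
  f <- fit_cox_univariate(20:1, s3, standardize = FALSE)
  expect_false(f$converged)
  expect_true(is.na(f$p_value))
})

test_that("the screen is chunk-invariant and thresholds genes correctly", {
  pair <- small_pair(n_probes_1 = 120, n_probes_2 = 80, n_genes = 60,
                     n_signal_genes = 6, n_samples = 80, seed = 17)
  a <- cox_screen(pair$cohort1, chunk_size = 25)
  b <- cox_screen(pair$cohort1, chunk_size = 4000)
  expect_identical(a$results, b$results)
  # passing genes recount
  r <- a$results
  manual <- sort(unique(r$gene_symbol[r$converged & r$p_value <= 0.05]))
  expect_identical(a$passing_genes, manual)
  # q-values are Benjamini-Hochberg over converged probes
  expect_equal(r$q_value[r$converged],
               p.adjust(r$p_value[r$converged], "BH"))
})

test_that("planted signal genes are recovered with high power", {
  pair <- small_pair()  # effect 1.0, n = 150
  cx1 <- cox_screen(pair$cohort1)
  cx2 <- cox_screen(pair$cohort2)
  for (cx in list(cx1, cx2)) {
    hit <- mean(pair$signal_genes %in% cx$passing_genes)
    expect_gte(hit, 0.8)
  }
  # hazard-increasing genes get positive coefficients in the median
  r <- cx1$results
  up_genes <- names(pair$signal_signs)[pair$signal_signs > 0]
  up_beta <- r$beta[r$gene_symbol %in% up_genes & r$converged]
  expect_gt(median(up_beta), 0)
})
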