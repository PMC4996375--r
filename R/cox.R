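# Partial log-likelihood, score and information for a single covariate,
# Breslow or Efron handling of tied event times. x, time, event must be
# sorted by ascending time before calling.
cox_pl_parts <- function(beta, x, time, event, ties = "breslow") {
  w <- exp(beta * x)
  n <- length(x)
  # reverse cumulative sums: sums over the risk set {j : time_j >= t}
  R0 <- rev(cumsum(rev(w)))
  R1 <- rev(cumsum(rev(x * w)))
  R2 <- rev(cumsum(rev(x^2 * w)))
  first <- match(time, time)  # first index sharing each (sorted) time value

  ev <- which(event == 1)
  if (ties == "breslow" || !anyDuplicated(time[ev])) {
    S0 <- R0[first[ev]]; S1 <- R1[first[ev]]; S2 <- R2[first[ev]]
    m1 <- S1 / S0
    loglik <- sum(beta * x[ev] - log(S0))
    score <- sum(x[ev] - m1)
    info <- sum(S2 / S0 - m1^2)
    return(list(loglik = loglik, score = score, info = info))
  }
  # Efron: within a group of d tied events, the k-th event (k = 0..d-1) uses
  # denominator S0 - (k/d) * D0 where D* sum over the tied events themselves
  loglik <- score <- info <- 0
  for (tt in unique(time[ev])) {
    g <- ev[time[ev] == tt]
    d <- length(g)
    f <- first[g[1]]
    S0 <- R0[f]; S1 <- R1[f]; S2 <- R2[f]
    D0 <- sum(w[g]); D1 <- sum(x[g] * w[g]); D2 <- sum(x[g]^2 * w[g])
    k <- (seq_len(d) - 1) / d
    a0 <- S0 - k * D0; a1 <- S1 - k * D1; a2 <- S2 - k * D2
    loglik <- loglik + beta * sum(x[g]) - sum(log(a0))
    score <- score + sum(x[g]) - sum(a1 / a0)
    info <- info + sum(a2 / a0 - (a1 / a0)^2)
  }
  list(loglik = loglik, score = score, info = info)
}

#' Univariate Cox proportional-hazards fit for one probe
#'
#' Maximizes the partial likelihood of a single-covariate Cox model by
#' Newton-Raphson with step-halving, Breslow (default) or Efron handling of
#' tied event times. By default the covariate is z-scored first so the
#' coefficient is the log-hazard change per 1 SD of expression, comparable
#' across probes; the Wald statistic `z = beta/se` gives a two-sided normal
#' p-value.
#'
#' @param x Expression values, one per sample.
#' @param survival `data.frame` with columns `time_months` and `event`.
#' @param standardize z-score `x` before fitting (default `TRUE`).
#' @param ties `"breslow"` or `"efron"`.
#' @param tol Convergence tolerance on the score.
#' @param max_iter Newton-Raphson iteration cap.
#' @return A list of class `cox_probe_fit`: `beta`, `se`, `z`, `p_value`,
#'   `n_used`, `n_events`, `loglik`, `iterations`, `converged`, `reason`.
#'   Degenerate inputs (constant covariate, fewer than 2 events) and monotone
#'   likelihoods (risk ordering perfectly separated; `|beta|` capped at 15)
#'   return `converged = FALSE` with a reason code and no p-value.
#' @examples
#' s <- data.frame(time_months = c(1, 2, 3, 4, 5), event = c(1, 1, 0, 1, 0))
#' fit_cox_univariate(c(2, 1, 1, 0, 0), s, standardize = FALSE)
#' @export
fit_cox_univariate <- function(x, survival, standardize = TRUE,
                               ties = c("breslow", "efron"),
                               tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  stopifnot(length(x) == nrow(survival))
  time <- survival$time_months
  event <- survival$event
  keep <- is.finite(x) & is.finite(time)
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  n <- length(x)

  failed <- function(reason) {
    structure(list(beta = NA_real_, se = NA_real_, z = NA_real_,
                   p_value = NA_real_, n_used = n, n_events = sum(event == 1),
                   loglik = NA_real_, iterations = 0L, converged = FALSE,
                   reason = reason),
              class = "cox_probe_fit")
  }
  if (sum(event == 1) < 2L) return(failed("fewer than 2 events"))
  if (sd(x) == 0 || !is.finite(sd(x))) return(failed("constant covariate"))
  if (standardize) x <- (x - mean(x)) / sd(x)

  ord <- order(time)
  x <- x[ord]; time <- time[ord]; event <- event[ord]

  beta <- 0
  parts <- cox_pl_parts(beta, x, time, event, ties)
  converged <- FALSE
  reason <- NA_character_
  iter <- 0L
  while (iter < max_iter) {
    if (abs(parts$score) < tol) { converged <- TRUE; break }
    if (!is.finite(parts$info) || parts$info <= 0) {
      reason <- "singular information"; break
    }
    step <- parts$score / parts$info
    new_beta <- beta + step
    new_parts <- cox_pl_parts(new_beta, x, time, event, ties)
    halvings <- 0L
    while ((!is.finite(new_parts$loglik) ||
            new_parts$loglik < parts$loglik - 1e-12) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new_parts <- cox_pl_parts(new_beta, x, time, event, ties)
      halvings <- halvings + 1L
    }
    beta <- new_beta
    parts <- new_parts
    iter <- iter + 1L
    if (abs(beta) > 15) { reason <- "monotone likelihood"; break }
  }
  if (!converged && is.na(reason)) {
    if (abs(parts$score) < tol) converged <- TRUE else reason <- "iteration limit"
  }
  if (!converged && identical(reason, "monotone likelihood")) beta <- sign(beta) * 15

  se <- if (is.finite(parts$info) && parts$info > 0) 1 / sqrt(parts$info) else NA_real_
  z <- if (converged && is.finite(se)) beta / se else NA_real_
  structure(list(beta = beta, se = se, z = z,
                 p_value = if (converged) 2 * pnorm(-abs(z)) else NA_real_,
                 n_used = n, n_events = sum(event == 1), loglik = parts$loglik,
                 iterations = iter, converged = converged, reason = reason),
            class = "cox_probe_fit")
}

#' @export
print.cox_probe_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("Cox univariate fit: beta = %.4f (se %.4f), z = %.3f, p = %.4g\n",
                x$beta, x$se, x$z, x$p_value))
    cat(sprintf("  n = %d (%d events), %d iterations\n", x$n_used, x$n_events,
                x$iterations))
  } else {
    cat(sprintf("Cox univariate fit: not converged (%s); n = %d (%d events)\n",
                x$reason, x$n_used, x$n_events))
  }
  invisible(x)
}

#' Cox screen over all probes of a cohort
#'
#' Fits [fit_cox_univariate()] to every probe and takes forward the gene
#' symbols of probes with Wald p-value at or below `alpha`. Probes are
#' processed in chunks purely for progress reporting, mirroring batch-limited
#' legacy workflows; results are chunk-invariant. Benjamini-Hochberg q-values
#' are reported informatively but not used for the screen.
#'
#' @param cohort An [expr_cohort()].
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @param ties,standardize Passed to [fit_cox_univariate()].
#' @param chunk_size Probes per progress chunk (default 4000).
#' @param verbose Print chunk progress.
#' @return A list of class `cox_screen`: `results` (`data.frame` with
#'   `probe_id`, `gene_symbol`, `beta`, `se`, `z`, `p_value`, `q_value`,
#'   `n_used`, `converged`, `reason`) and `passing_genes` (unique symbols of
#'   converged probes with `p <= alpha`).
#' @export
cox_screen <- function(cohort, alpha = 0.05, ties = "breslow",
                       standardize = TRUE, chunk_size = 4000L, verbose = FALSE) {
  stopifnot(inherits(cohort, "expr_cohort"), alpha > 0, alpha < 1)
  probe_ids <- rownames(cohort$matrix)
  np <- length(probe_ids)
  fits <- vector("list", np)
  for (start in seq(1L, np, by = chunk_size)) {
    end <- min(start + chunk_size - 1L, np)
    for (p in start:end)
      fits[[p]] <- fit_cox_univariate(cohort$matrix[p, ], cohort$survival,
                                      standardize = standardize, ties = ties)
    if (verbose)
      message(sprintf("[%s] Cox screen: probes %d-%d of %d done",
                      cohort$cohort_id, start, end, np))
  }
  pull <- function(f) vapply(fits, function(z) z[[f]], numeric(1))
  res <- data.frame(
    probe_id = probe_ids,
    gene_symbol = cohort$annotation$gene_symbol[match(probe_ids,
                                                      cohort$annotation$probe_id)],
    beta = pull("beta"), se = pull("se"), z = pull("z"), p_value = pull("p_value"),
    n_used = vapply(fits, function(z) as.integer(z$n_used), integer(1)),
    converged = vapply(fits, function(z) isTRUE(z$converged), logical(1)),
    reason = vapply(fits, function(z) as.character(z$reason), character(1)),
    stringsAsFactors = FALSE)
  res$q_value <- NA_real_
  res$q_value[res$converged] <- p.adjust(res$p_value[res$converged], "BH")
  pass <- res$converged & !is.na(res$p_value) & res$p_value <= alpha
  genes <- sort(unique(stats::na.omit(res$gene_symbol[pass])))
  structure(list(results = res, passing_genes = genes, alpha = alpha,
                 cohort_id = cohort$cohort_id, ties = ties),
            class = "cox_screen")
}

#' @export
print.cox_screen <- function(x, ...) {
  r <- x$results
  cat(sprintf("Cox screen [%s]: %d probes, %d converged, %d with p <= %.3g\n",
              x$cohort_id, nrow(r), sum(r$converged),
              sum(r$converged & r$p_value <= x$alpha, na.rm = TRUE), x$alpha))
  cat(sprintf("  passing genes: %d\n", length(x$passing_genes)))
  invisible(x)
}
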