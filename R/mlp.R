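#' Hyperparameters for the per-probe neural-network screen
#'
#' Each probe is modelled by a three-layer perceptron with one input node,
#' `hidden_nodes` sigmoid hidden nodes and one sigmoid output node, trained by
#' full-batch backpropagation (MSE loss with momentum) to classify short
#' versus long survivors. Training halts when the error on a held-out
#' early-stopping split (20% of the included samples by default) stops
#' improving; probes are then ranked by root-mean-squared error on a second,
#' blind validation split never used during training.
#'
#' @param cutoffs Survival dichotomization cut-offs in months, strictly
#'   increasing. Default `c(16, 23, 30)`.
#' @param hidden_nodes Hidden layer size (1-8). Default 2.
#' @param learning_rate Positive backpropagation step size.
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param max_epochs Hard cap on training epochs.
#' @param patience Epochs without early-stopping-set improvement before halt.
#' @param fractions Named train/stop/validation split fractions; must sum
#'   to 1. Default `c(train = 0.6, stop = 0.2, validation = 0.2)`.
#' @param top_fraction Fraction of evaluated probes kept per cut-off, in
#'   (0, 1). Default 0.0005 (0.05%); the selection count is
#'   `ceiling(top_fraction * n_evaluated)` so at least one probe survives.
#' @param n_restarts Independent weight initializations per probe; the
#'   restart with the best early-stopping error is kept.
#' @return An `ann_control` list.
#' @export
ann_control <- function(cutoffs = c(16, 23, 30), hidden_nodes = 2L,
                        learning_rate = 0.3, momentum = 0.9,
                        max_epochs = 300L, patience = 25L,
                        fractions = c(train = 0.6, stop = 0.2, validation = 0.2),
                        top_fraction = 0.0005, n_restarts = 3L) {
  if (length(cutoffs) < 1L || any(cutoffs <= 0) || is.unsorted(cutoffs, strictly = TRUE))
    stopf("`cutoffs` must be positive and strictly increasing")
  if (hidden_nodes < 1L || hidden_nodes > 8L) stopf("hidden_nodes must be 1-8")
  if (learning_rate <= 0) stopf("learning_rate must be positive")
  if (momentum < 0 || momentum >= 1) stopf("momentum must lie in [0, 1)")
  if (abs(sum(fractions) - 1) > 1e-8 || length(fractions) != 3L || any(fractions <= 0))
    stopf("`fractions` must be three positive values summing to 1")
  if (top_fraction <= 0 || top_fraction >= 1) stopf("top_fraction must lie in (0, 1)")
  structure(list(cutoffs = as.numeric(cutoffs), hidden_nodes = as.integer(hidden_nodes),
                 learning_rate = as.numeric(learning_rate), momentum = as.numeric(momentum),
                 max_epochs = as.integer(max_epochs), patience = as.integer(patience),
                 fractions = fractions, top_fraction = as.numeric(top_fraction),
                 n_restarts = as.integer(n_restarts)),
            class = "ann_control")
}

#' Number of probes selected by the top-fraction rule
#'
#' `ceiling(top_fraction * n_evaluated)`: keeping the top 0.05% of 37,632
#' evaluated probes selects 19; of 22,283, selects 12.
#'
#' @param n_evaluated Number of probes that received a rank.
#' @param top_fraction Fraction kept, in (0, 1).
#' @return Integer selection count (at least 1).
#' @export
selection_count <- function(n_evaluated, top_fraction) {
  stopifnot(n_evaluated >= 1, top_fraction > 0, top_fraction < 1)
  as.integer(ceiling(top_fraction * n_evaluated))
}

# stratified train/stop/validation split: within each class, shuffle and cut
# by the configured fractions (validation and stop sizes rounded, remainder
# trains). Returns 1-based index vectors.
make_split <- function(labels, fractions, seed) {
  set.seed(seed)
  train <- stop_ <- val <- integer(0)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    n <- length(idx)
    n_val <- max(1L, round(fractions[["validation"]] * n))
    n_stop <- max(1L, round(fractions[["stop"]] * n))
    if (n_val + n_stop >= n) stopf("too few samples in a class to split (%d)", n)
    val <- c(val, idx[seq_len(n_val)])
    stop_ <- c(stop_, idx[n_val + seq_len(n_stop)])
    train <- c(train, idx[(n_val + n_stop + 1):n])
  }
  list(train = sort(train), stop = sort(stop_), validation = sort(val))
}

#' Forward pass of the per-probe perceptron
#'
#' @param weights Flat weight vector `c(w1, b1, w2, b2)` of length
#'   `3 * hidden + 1`, as returned by [train_probe_mlp()].
#' @param x Numeric input vector (standardized expression).
#' @param hidden Hidden layer size.
#' @return Network outputs in (0, 1).
#' @export
mlp_forward <- function(weights, x, hidden = 2L) {
  stopifnot(length(weights) == 3L * hidden + 1L)
  sig <- function(z) 1 / (1 + exp(-z))
  w1 <- weights[seq_len(hidden)]
  b1 <- weights[hidden + seq_len(hidden)]
  w2 <- weights[2L * hidden + seq_len(hidden)]
  b2 <- weights[3L * hidden + 1L]
  h <- sig(outer(x, w1) + rep(b1, each = length(x)))
  as.vector(sig(h %*% w2 + b2))
}

#' Train one probe's survival classifier and score it by blind validation
#'
#' Standardizes the expression vector on training-split statistics, trains
#' `n_restarts` networks with early stopping, keeps the restart with the best
#' early-stopping-set error and reports its RMSE on the blind validation
#' split. Deterministic given `probe_seed` and the control settings.
#'
#' @param x Expression values across included samples.
#' @param y Binary labels (0 = short, 1 = long survivor).
#' @param control An [ann_control()].
#' @param probe_seed Integer seed for the split (when `split = NULL`) and the
#'   weight initializations.
#' @param split Optional precomputed list with integer index vectors `train`,
#'   `stop`, `validation` (as from the cohort-level split used by
#'   [ann_screen()]); when `NULL` a stratified split is drawn from
#'   `probe_seed`.
#' @return A list: `ok` (logical), `validation_rmse`, `stop_rmse`, `weights`
#'   (flat vector, see [mlp_forward()]), `epochs`, `restart`, and `reason`
#'   when flagged (`ok = FALSE`, probe not rankable).
#' @export
train_probe_mlp <- function(x, y, control = ann_control(), probe_seed = 1L,
                            split = NULL) {
  stopifnot(length(x) == length(y))
  flagged <- function(reason) list(ok = FALSE, validation_rmse = NA_real_,
                                   reason = reason)
  if (length(x) < 10L) return(flagged("fewer than 10 samples"))
  if (length(unique(y)) < 2L) return(flagged("single-class labels"))
  if (is.null(split)) split <- make_split(y, control$fractions, probe_seed)
  mu <- mean(x[split$train]); s <- sd(x[split$train])
  if (!is.finite(s) || s == 0) return(flagged("zero variance on training split"))
  if (length(unique(y[split$train])) < 2L) return(flagged("single-class training split"))
  xs <- (x - mu) / s
  fit <- .mlp_train_cpp(xs, as.numeric(y),
                        as.integer(split$train) - 1L,
                        as.integer(split$stop) - 1L,
                        as.integer(split$validation) - 1L,
                        control$hidden_nodes, control$learning_rate,
                        control$momentum, control$max_epochs, control$patience,
                        control$n_restarts, as.integer(probe_seed))
  c(list(ok = TRUE, reason = NA_character_), fit)
}
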