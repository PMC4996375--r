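#' Neural-network probe screen for one cohort
#'
#' For every probe and every survival cut-off, trains a single-input
#' perceptron (see [train_probe_mlp()]) to classify short versus long
#' survivors, ranks probes within each cut-off by ascending blind-validation
#' RMSE (ties at the selection boundary broken by probe ID, lexicographic),
#' and flags the top fraction as selected. Samples censored at or before a
#' cut-off are excluded from that cut-off's analysis. The train/stop/
#' validation split is drawn once per cut-off from a seed substream and
#' shared across probes; weight initializations are seeded per probe.
#'
#' @param cohort An [expr_cohort()].
#' @param control An [ann_control()].
#' @param seed Global integer seed for this screen.
#' @param verbose Print per-cutoff progress.
#' @return A `data.frame` of class `ann_screen` with one row per probe and
#'   cut-off: `probe_id`, `gene_symbol`, `cutoff`, `validation_rmse`, `rank`
#'   (1-based, a permutation of the evaluated probes within each cut-off),
#'   `selected`, `evaluated`, `reason`. Attributes: `control`, `seed`,
#'   `cohort_id`, `n_evaluated` and `n_selected` per cut-off.
#' @export
ann_screen <- function(cohort, control = ann_control(), seed = 1L, verbose = FALSE) {
  stopifnot(inherits(cohort, "expr_cohort"))
  probe_ids <- rownames(cohort$matrix)
  gene_of <- cohort$annotation$gene_symbol[match(probe_ids, cohort$annotation$probe_id)]
  out <- vector("list", length(control$cutoffs))
  n_eval <- n_sel <- integer(length(control$cutoffs))
  names(n_eval) <- names(n_sel) <- as.character(control$cutoffs)

  for (ci in seq_along(control$cutoffs)) {
    cutoff <- control$cutoffs[ci]
    d <- dichotomize(cohort$survival, cutoff)
    idx <- which(d$included)
    if (length(idx) < 10L)
      stopf("cut-off %.0f months leaves %d classifiable samples (< 10)",
            cutoff, length(idx))
    y <- d$label[idx]
    if (length(unique(y)) < 2L)
      stopf("cut-off %.0f months yields a single survivor class", cutoff)
    split <- make_split(y, control$fractions,
                        substream_seed(seed, cohort$cohort_id, cutoff, "split"))
    if (verbose)
      message(sprintf("[%s] cutoff %.0f: %d samples (%d short / %d long)",
                      cohort$cohort_id, cutoff, length(y), sum(y == 0), sum(y == 1)))

    rmse <- rep(NA_real_, length(probe_ids))
    reason <- rep(NA_character_, length(probe_ids))
    for (p in seq_along(probe_ids)) {
      fit <- train_probe_mlp(cohort$matrix[p, idx], y, control,
                             probe_seed = substream_seed(seed, cohort$cohort_id,
                                                         cutoff, probe_ids[p]),
                             split = split)
      if (fit$ok) rmse[p] <- fit$validation_rmse else reason[p] <- fit$reason
    }
    evaluated <- !is.na(rmse)
    n_eval[ci] <- sum(evaluated)
    n_sel[ci] <- selection_count(n_eval[ci], control$top_fraction)
    rank <- rep(NA_integer_, length(probe_ids))
    ord <- order(rmse[evaluated], probe_ids[evaluated])  # ties -> probe_id order
    rank[which(evaluated)[ord]] <- seq_len(n_eval[ci])
    selected <- !is.na(rank) & rank <= n_sel[ci]
    if (sum(!evaluated) > 0 && verbose)
      message(sprintf("  skipped %d probe(s): %s", sum(!evaluated),
                      paste(unique(stats::na.omit(reason)), collapse = "; ")))

    out[[ci]] <- data.frame(probe_id = probe_ids, gene_symbol = gene_of,
                            cutoff = cutoff, validation_rmse = rmse,
                            rank = rank, selected = selected,
                            evaluated = evaluated, reason = reason,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, control = control, seed = seed, cohort_id = cohort$cohort_id,
            n_evaluated = n_eval, n_selected = n_sel,
            class = c("ann_screen", "data.frame"))
}

#' Gene-name frequency weights from a neural-network screen
#'
#' Cross-references the selected probes of the per-cut-off rankings: a gene's
#' weight is the number of cut-offs whose selected set contains at least one
#' probe of that gene (1-3 with the default three cut-offs). Genes with
#' weight >= 1 form the cohort's candidate set for the meta-analysis.
#'
#' @param results An [ann_screen()] result (or a compatible `data.frame` with
#'   columns `gene_symbol`, `cutoff`, `selected`).
#' @return `data.frame` with `gene_symbol` and integer `weight`, ordered by
#'   decreasing weight then symbol. Selected probes lacking an annotation are
#'   excluded with a warning.
#' @export
weight_genes <- function(results) {
  stopifnot(all(c("gene_symbol", "cutoff", "selected") %in% names(results)))
  sel <- results[results$selected %in% TRUE, , drop = FALSE]
  if (anyNA(sel$gene_symbol)) {
    warnf("%d selected probe(s) lack a gene annotation and are excluded",
          sum(is.na(sel$gene_symbol)))
    sel <- sel[!is.na(sel$gene_symbol), , drop = FALSE]
  }
  if (nrow(sel) == 0L)
    return(data.frame(gene_symbol = character(0), weight = integer(0),
                      stringsAsFactors = FALSE))
  hit <- unique(sel[, c("gene_symbol", "cutoff")])
  w <- table(hit$gene_symbol)
  out <- data.frame(gene_symbol = names(w), weight = as.integer(w),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$weight, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  out
}
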