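#' Two-cohort consensus screen for survival-associated genes
#'
#' The central fitting function: runs the per-probe neural-network screen and
#' the univariate Cox screen on both cohorts, intersects the four candidate
#' gene sets, applies the t-test and expression-direction consistency
#' filters, ranks the surviving genes and computes the chance-probability
#' statistic from the final gene count and the two probe-universe sizes.
#'
#' @param cohort1,cohort2 Two [expr_cohort()]s on (typically) different
#'   platforms sharing gene symbols.
#' @param ann An [ann_control()]; its `cutoffs` drive the dichotomizations
#'   used by the neural-network screen and the t-test filter.
#' @param cox_alpha Cox screen p-value threshold (default 0.05).
#' @param ttest_alpha t-test filter threshold (default 0.05).
#' @param ttest_var_equal Pooled-variance Student t-tests instead of Welch.
#' @param ttest_rule `"any"` (default) or `"all"` cut-offs; see
#'   [ttest_filter()].
#' @param ties Tie handling for the Cox fits.
#' @param seed Global seed; all stage randomness derives from it via
#'   [substream_seed()].
#' @param verbose Progress messages.
#' @return An object of class `consensus_screen`; see [print.consensus_screen()]
#'   and [summary.consensus_screen()]. Key components: `final` (ranked
#'   `data.frame`), `chance_probability`, `candidates` (the four gene sets),
#'   `intersection`, `ttest_survivors`, `directions`, `audit` (per-gene drop
#'   log), `ann` / `cox` (full per-probe result tables), `gene_weights`.
#' @examples
#' \donttest{
#' pair <- generate_cohort_pair(sim_config(n_probes_1 = 200, n_probes_2 = 150,
#'   n_genes = 100, n_signal_genes = 8, seed = 7))
#' fit <- consensus_screen(pair$cohort1, pair$cohort2,
#'                         ann = ann_control(top_fraction = 0.05), seed = 7)
#' print(fit)
#' }
#' @export
consensus_screen <- function(cohort1, cohort2, ann = ann_control(),
                             cox_alpha = 0.05, ttest_alpha = 0.05,
                             ttest_var_equal = FALSE, ttest_rule = "any",
                             ties = "breslow", seed = 1L, verbose = FALSE) {
  stopifnot(inherits(cohort1, "expr_cohort"), inherits(cohort2, "expr_cohort"))
  if (identical(cohort1$cohort_id, cohort2$cohort_id))
    stopf("the two cohorts must carry distinct cohort_id labels")

  if (verbose) message("Neural-network screen, ", cohort1$cohort_id)
  ann1 <- ann_screen(cohort1, ann, seed = substream_seed(seed, "ann", 1L),
                     verbose = verbose)
  if (verbose) message("Neural-network screen, ", cohort2$cohort_id)
  ann2 <- ann_screen(cohort2, ann, seed = substream_seed(seed, "ann", 2L),
                     verbose = verbose)
  w1 <- weight_genes(ann1)
  w2 <- weight_genes(ann2)

  if (verbose) message("Cox screen, both cohorts")
  cox1 <- cox_screen(cohort1, alpha = cox_alpha, ties = ties, verbose = verbose)
  cox2 <- cox_screen(cohort2, alpha = cox_alpha, ties = ties, verbose = verbose)

  candidates <- list(ann_cohort1 = norm_symbols(w1$gene_symbol),
                     ann_cohort2 = norm_symbols(w2$gene_symbol),
                     cox_cohort1 = norm_symbols(cox1$passing_genes),
                     cox_cohort2 = norm_symbols(cox2$passing_genes))
  inter <- intersect_four_way(candidates$ann_cohort1, candidates$ann_cohort2,
                              candidates$cox_cohort1, candidates$cox_cohort2)

  tt <- ttest_filter(inter, cohort1, cohort2, cutoffs = ann$cutoffs,
                     alpha = ttest_alpha, var_equal = ttest_var_equal,
                     rule = ttest_rule)
  dir <- direction_filter(tt$summary, genes = tt$survivors)

  # filters only ever remove genes
  stopifnot(all(dir$final %in% tt$survivors),
            all(tt$survivors %in% inter),
            all(inter %in% candidates$ann_cohort1),
            all(inter %in% candidates$cox_cohort2))

  final <- rank_final_genes(dir$final, w1, w2, cox1, cox2)
  cp <- chance_probability(nrow(final), nrow(cohort1$matrix), nrow(cohort2$matrix))

  audit <- rbind(
    if (length(setdiff(inter, tt$survivors)))
      data.frame(gene_symbol = setdiff(inter, tt$survivors),
                 stage = "ttest_filter",
                 reason = sprintf("no probe with p <= %g in both cohorts", ttest_alpha),
                 stringsAsFactors = FALSE),
    if (!is.null(dir$dropped) && nrow(dir$dropped))
      data.frame(gene_symbol = dir$dropped$gene_symbol, stage = "direction_filter",
                 reason = dir$dropped$reason, stringsAsFactors = FALSE))
  if (is.null(audit))
    audit <- data.frame(gene_symbol = character(0), stage = character(0),
                        reason = character(0), stringsAsFactors = FALSE)

  structure(list(
    candidates = candidates, intersection = inter,
    ttest_survivors = tt$survivors, ttest_summary = tt$summary,
    directions = dir$directions, final = final, audit = audit,
    chance_probability = cp,
    gene_weights = list(cohort1 = w1, cohort2 = w2),
    ann = list(cohort1 = ann1, cohort2 = ann2),
    cox = list(cohort1 = cox1, cohort2 = cox2),
    params = list(cutoffs = ann$cutoffs, ann = ann, cox_alpha = cox_alpha,
                  ttest_alpha = ttest_alpha, ttest_var_equal = ttest_var_equal,
                  ttest_rule = ttest_rule, ties = ties, seed = seed,
                  n_probes = c(nrow(cohort1$matrix), nrow(cohort2$matrix)),
                  cohort_ids = c(cohort1$cohort_id, cohort2$cohort_id),
                  rank_criterion = paste("descending summed ANN weight,",
                                         "ascending min Cox p, alphabetical")),
    call = match.call()),
    class = "consensus_screen")
}

#' @describeIn consensus_screen Compact stage-by-stage report.
#' @param x,object A `consensus_screen` object.
#' @param ... Unused.
#' @export
print.consensus_screen <- function(x, ...) {
  cat("Two-cohort consensus survival screen\n")
  cat(sprintf("  probes: %d / %d; cut-offs: %s months\n",
              x$params$n_probes[1], x$params$n_probes[2],
              paste(x$params$cutoffs, collapse = ", ")))
  n <- vapply(x$candidates, length, integer(1))
  cat(sprintf("  candidates  ANN: %d / %d   Cox (p <= %g): %d / %d\n",
              n[1], n[2], x$params$cox_alpha, n[3], n[4]))
  cat(sprintf("  four-way intersection: %d genes\n", length(x$intersection)))
  cat(sprintf("  after t-test filter:   %d genes\n", length(x$ttest_survivors)))
  cat(sprintf("  final (direction-consistent): %d genes\n", nrow(x$final)))
  cat(sprintf("  chance probability (as defined in source publication): %.5e\n",
              x$chance_probability))
  if (nrow(x$final)) {
    cat("  top genes:\n")
    print(head(x$final, 10), row.names = FALSE)
  }
  invisible(x)
}

#' @describeIn consensus_screen Full report including the audit trail.
#' @export
summary.consensus_screen <- function(object, ...) {
  print(object)
  if (!is.null(object$audit) && nrow(object$audit)) {
    cat("\nDropped after the intersection:\n")
    print(object$audit, row.names = FALSE)
  }
  cat(sprintf("\nRanking criterion: %s\n", object$params$rank_criterion))
  invisible(object)
}

#' @describeIn consensus_screen Scatter of per-gene best Cox evidence in the
#'   two cohorts (`-log10` minimum p), intersected genes as open circles and
#'   final consensus genes filled.
#' @export
plot.consensus_screen <- function(x, ...) {
  inter <- x$intersection
  if (!length(inter)) {
    warnf("empty intersection; nothing to plot")
    return(invisible(x))
  }
  df <- rank_final_genes(inter, x$gene_weights$cohort1, x$gene_weights$cohort2,
                         x$cox$cohort1, x$cox$cohort2)
  is_final <- df$gene_symbol %in% x$final$gene_symbol
  graphics::plot(-log10(df$min_cox_p_cohort1), -log10(df$min_cox_p_cohort2),
                 pch = ifelse(is_final, 19, 1),
                 col = ifelse(is_final, "firebrick", "grey40"),
                 xlab = expression(-log[10] ~ "min Cox p, cohort 1"),
                 ylab = expression(-log[10] ~ "min Cox p, cohort 2"),
                 main = "Consensus candidates", ...)
  graphics::abline(h = -log10(x$params$cox_alpha),
                   v = -log10(x$params$cox_alpha), lty = 3)
  invisible(x)
}
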