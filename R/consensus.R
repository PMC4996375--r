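#' Four-way candidate intersection
#'
#' Genes taken forward are those present in all four candidate sets: the
#' neural-network candidates of both cohorts and the Cox-significant genes of
#' both cohorts. Symbols are matched case-insensitively after whitespace
#' trimming.
#'
#' @param ann_genes_1,ann_genes_2,cox_genes_1,cox_genes_2 Character vectors of
#'   gene symbols.
#' @return Sorted character vector of symbols present in all four sets.
#' @export
intersect_four_way <- function(ann_genes_1, ann_genes_2, cox_genes_1, cox_genes_2) {
  sets <- lapply(list(ann_genes_1, ann_genes_2, cox_genes_1, cox_genes_2),
                 function(s) unique(norm_symbols(s)))
  sort(Reduce(intersect, sets))
}

# per-(gene, cohort, cutoff, probe) long/short group means and t-test p-value
gene_group_summary <- function(genes, cohort, cutoffs, var_equal = FALSE) {
  ann <- cohort$annotation
  ann$norm <- norm_symbols(ann$gene_symbol)
  rows <- list()
  for (cutoff in cutoffs) {
    d <- dichotomize(cohort$survival, cutoff)
    long <- which(d$included & d$label == 1L)
    short <- which(d$included & d$label == 0L)
    for (g in genes) {
      probes <- ann$probe_id[!is.na(ann$norm) & ann$norm == g]
      for (p in probes) {
        xl <- cohort$matrix[p, long]
        xs <- cohort$matrix[p, short]
        pv <- NA_real_
        if (length(xl) >= 2L && length(xs) >= 2L) {
          pv <- tryCatch(t.test(xl, xs, var.equal = var_equal)$p.value,
                         error = function(e) NA_real_)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          gene_symbol = g, cohort_id = cohort$cohort_id, cutoff = cutoff,
          probe_id = p,
          mean_long = if (length(xl)) mean(xl) else NA_real_,
          mean_short = if (length(xs)) mean(xs) else NA_real_,
          p_value = pv, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' t-test filter over the intersected genes
#'
#' For each candidate gene, compares mean expression between long and short
#' survivors (groups from [dichotomize()], same exclusion of early-censored
#' samples) for every probe of the gene at every cut-off, in both cohorts.
#' A gene is kept only if it is significant in *both* cohorts: under
#' `rule = "any"` (default) at least one probe reaches `p <= alpha` at at
#' least one cut-off per cohort; under `rule = "all"` every cut-off must have
#' at least one significant probe. Cells with an empty survivor group are
#' undefined and ignored for the decision.
#'
#' @param genes Character vector (normalized symbols), typically the
#'   [intersect_four_way()] output.
#' @param cohort1,cohort2 The two [expr_cohort()]s.
#' @param cutoffs Dichotomization cut-offs in months.
#' @param alpha Significance threshold.
#' @param var_equal `FALSE` (default) for Welch, `TRUE` for pooled-variance
#'   Student t-tests.
#' @param rule `"any"` or `"all"` cut-offs (see above).
#' @return A list: `survivors` (character), `summary` (the per-cell
#'   `data.frame`: gene, cohort, cutoff, probe, group means, p-value).
#' @export
ttest_filter <- function(genes, cohort1, cohort2, cutoffs = c(16, 23, 30),
                         alpha = 0.05, var_equal = FALSE,
                         rule = c("any", "all")) {
  rule <- match.arg(rule)
  genes <- unique(norm_symbols(genes))
  if (length(genes) == 0L)
    return(list(survivors = character(0), summary = NULL))
  summ <- rbind(gene_group_summary(genes, cohort1, cutoffs, var_equal),
                gene_group_summary(genes, cohort2, cutoffs, var_equal))
  keep <- vapply(genes, function(g) {
    all(vapply(c(cohort1$cohort_id, cohort2$cohort_id), function(cid) {
      s <- summ[summ$gene_symbol == g & summ$cohort_id == cid, , drop = FALSE]
      if (rule == "any") {
        any(s$p_value <= alpha, na.rm = TRUE)
      } else {
        all(vapply(cutoffs, function(ct) {
          any(s$p_value[s$cutoff == ct] <= alpha, na.rm = TRUE)
        }, logical(1)))
      }
    }, logical(1)))
  }, logical(1))
  list(survivors = sort(genes[keep]), summary = summ)
}

#' Expression-direction consistency filter
#'
#' A gene's direction in a cohort is the sign of its (mean long - mean short)
#' expression difference, averaged over the gene's probes within each cut-off
#' and then over cut-offs with defined groups. Genes whose directions differ
#' between the cohorts - expression trends pointing opposite ways against
#' survival - are disregarded, as are genes with an undefined direction in
#' either cohort.
#'
#' @param summary The `summary` table from [ttest_filter()].
#' @param genes Genes to assess (default: all genes in `summary`).
#' @return A list: `final` (concordant genes, sorted), `directions`
#'   (`data.frame` gene, cohort, mean_diff, direction), `dropped`
#'   (`data.frame` gene, reason).
#' @export
direction_filter <- function(summary, genes = NULL) {
  if (is.null(summary) || nrow(summary) == 0L)
    return(list(final = character(0), directions = NULL, dropped = NULL))
  if (is.null(genes)) genes <- unique(summary$gene_symbol)
  genes <- unique(norm_symbols(genes))
  cohorts <- unique(summary$cohort_id)
  stopifnot(length(cohorts) == 2L)

  dirs <- list(); dropped <- list()
  final <- character(0)
  for (g in genes) {
    sign_of <- numeric(0)
    for (cid in cohorts) {
      s <- summary[summary$gene_symbol == g & summary$cohort_id == cid, , drop = FALSE]
      diff <- s$mean_long - s$mean_short
      # average over probes within each cutoff, then over defined cutoffs
      by_cutoff <- tapply(diff, s$cutoff, mean, na.rm = TRUE)
      m <- mean(by_cutoff[is.finite(by_cutoff)])
      dirs[[length(dirs) + 1L]] <- data.frame(
        gene_symbol = g, cohort_id = cid, mean_diff = m,
        direction = if (is.finite(m) && m != 0) sign(m) else NA_real_,
        stringsAsFactors = FALSE)
      sign_of[cid] <- if (is.finite(m) && m != 0) sign(m) else NA_real_
    }
    if (anyNA(sign_of)) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        gene_symbol = g, reason = "undefined direction", stringsAsFactors = FALSE)
    } else if (length(unique(sign_of)) > 1L) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        gene_symbol = g, reason = "direction conflict between cohorts",
        stringsAsFactors = FALSE)
    } else {
      final <- c(final, g)
    }
  }
  list(final = sort(final),
       directions = do.call(rbind, dirs),
       dropped = if (length(dropped)) do.call(rbind, dropped) else NULL)
}

#' Chance probability of the consensus list
#'
#' The combined probability that `k` genes emerge from all four screens by
#' chance, computed as the squared product of the two per-cohort ratios of
#' the final gene count to the probe-universe size:
#' `((k/p1) * (k/p2))^2`. With the published values k = 56, p1 = 37,632 and
#' p2 = 22,283 this equals 1.39859e-11. The source publication labels this
#' quantity an FDR; it is reported here as "chance probability (as defined in
#' source publication)" without endorsing that reading.
#'
#' @param k Final consensus gene count, `0 <= k <= min(p1, p2)`.
#' @param p1,p2 Probe-universe sizes of the two cohorts, positive.
#' @return The probability (0 when `k = 0`).
#' @examples
#' chance_probability(56, 37632, 22283)
#' @export
chance_probability <- function(k, p1, p2) {
  if (length(k) != 1L || length(p1) != 1L || length(p2) != 1L)
    stopf("k, p1, p2 must be scalars")
  if (p1 <= 0 || p2 <= 0) stopf("probe counts must be positive")
  if (k < 0 || k > min(p1, p2)) stopf("k must lie in [0, min(p1, p2)]")
  ((k / p1) * (k / p2))^2
}

#' Rank the final consensus genes
#'
#' Orders the final gene list by descending summed neural-network weight
#' across the two cohorts, then ascending minimum Cox p-value across cohorts,
#' then alphabetically. This composite key is a package convention (recorded
#' in the report); the corresponding ordering criterion in the source
#' analysis was never published.
#'
#' @param genes Final gene symbols.
#' @param weights1,weights2 [weight_genes()] tables for cohorts 1 and 2.
#' @param cox1,cox2 [cox_screen()] objects for cohorts 1 and 2.
#' @return `data.frame`: `gene_symbol`, `rank`, `weight_cohort1`,
#'   `weight_cohort2`, `min_cox_p_cohort1`, `min_cox_p_cohort2`.
#' @export
rank_final_genes <- function(genes, weights1, weights2, cox1, cox2) {
  genes <- unique(norm_symbols(genes))
  if (length(genes) == 0L)
    return(data.frame(gene_symbol = character(0), rank = integer(0),
                      weight_cohort1 = integer(0), weight_cohort2 = integer(0),
                      min_cox_p_cohort1 = numeric(0), min_cox_p_cohort2 = numeric(0),
                      stringsAsFactors = FALSE))
  wt <- function(w, g) {
    i <- match(g, norm_symbols(w$gene_symbol))
    ifelse(is.na(i), 0L, w$weight[i])
  }
  minp <- function(cx, g) {
    r <- cx$results
    r <- r[r$converged & !is.na(r$gene_symbol), , drop = FALSE]
    r$norm <- norm_symbols(r$gene_symbol)
    vapply(g, function(gg) {
      p <- r$p_value[r$norm == gg]
      if (length(p)) min(p) else NA_real_
    }, numeric(1))
  }
  out <- data.frame(gene_symbol = genes,
                    weight_cohort1 = wt(weights1, genes),
                    weight_cohort2 = wt(weights2, genes),
                    min_cox_p_cohort1 = minp(cox1, genes),
                    min_cox_p_cohort2 = minp(cox2, genes),
                    stringsAsFactors = FALSE)
  total_w <- out$weight_cohort1 + out$weight_cohort2
  best_p <- pmin(out$min_cox_p_cohort1, out$min_cox_p_cohort2, na.rm = TRUE)
  ord <- order(-total_w, best_p, out$gene_symbol)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out[, c("gene_symbol", "rank", "weight_cohort1", "weight_cohort2",
          "min_cox_p_cohort1", "min_cox_p_cohort2")]
}
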