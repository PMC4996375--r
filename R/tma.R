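#' Read a tissue-microarray score table
#'
#' Expects a TSV with columns `core_id`, `stage`, `grade`, `histotype`,
#' `tumor_cells`, `score_a` and optionally `score_b`. Scores are categorical
#' staining intensities 0 (negative), 1 (weak), 2 (moderate), 3 (intense).
#' Cores with fewer than `min_tumor_cells` tumour cells are not viable for
#' scoring and are excluded before any statistic.
#'
#' @param path TSV file.
#' @param min_tumor_cells Viability threshold (default 100).
#' @return `data.frame` of viable cores; the number excluded is in
#'   `attr(, "n_excluded")`.
#' @export
read_score_table <- function(path, min_tumor_cells = 100) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("core_id", "stage", "grade", "histotype", "tumor_cells", "score_a")
  missing <- setdiff(need, names(df))
  if (length(missing)) stopf("score table lacks column(s): %s",
                             paste(missing, collapse = ", "))
  if (!"score_b" %in% names(df)) df$score_b <- NA_integer_
  chk <- c(df$score_a, df$score_b)
  if (!all(is.na(chk) | chk %in% 0:3))
    stopf("scores must be integers 0-3 (0 negative ... 3 intense)")
  viable <- df$tumor_cells >= min_tumor_cells
  out <- df[viable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- sum(!viable)
  out
}

#' Cohen's kappa for two categorical raters
#'
#' Unweighted chance-corrected agreement: `(p_o - p_e) / (1 - p_e)`, with
#' observed agreement `p_o` from the paired scores and expected agreement
#' `p_e` from the raters' marginal category frequencies.
#'
#' @param scores_a,scores_b Paired categorical vectors of equal length
#'   (>= 2). The category universe is the union of values seen in either.
#' @return Kappa in `[-1, 1]`. When both raters are constant with identical
#'   marginals, chance agreement is 1 and kappa is undefined: returns `NA`
#'   with a warning (distinct from kappa = 1).
#' @examples
#' cohen_kappa(c(0, 0, 1, 1), c(1, 1, 0, 0)) # -1
#' @export
cohen_kappa <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b)) stopf("paired vectors differ in length")
  keep <- !is.na(scores_a) & !is.na(scores_b)
  a <- scores_a[keep]; b <- scores_b[keep]
  n <- length(a)
  if (n < 2L) stopf("need at least 2 scored pairs")
  cats <- sort(unique(c(a, b)))
  tab <- table(factor(a, levels = cats), factor(b, levels = cats))
  p_o <- sum(diag(tab)) / n
  p_e <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (abs(1 - p_e) < .Machine$double.eps * 4) {
    warnf("both raters constant with identical marginals; kappa undefined")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Pairwise group t-tests on categorical scores
#'
#' Two-sample t-test of score values for every pair of groups (Welch by
#' default; a rank-based Wilcoxon alternative is available for the ordinal
#' 0-3 scale). Groups with fewer than 2 cores, and pairs where both groups
#' have zero variance, are reported as `NA`.
#'
#' @param scores Numeric score vector.
#' @param grouping Group labels, same length.
#' @param var_equal Pooled-variance instead of Welch.
#' @param method `"t"` (default) or `"wilcox"`.
#' @return Symmetric matrix of p-values with group names on both dimensions,
#'   `NA` on the diagonal.
#' @export
pairwise_group_ttests <- function(scores, grouping, var_equal = FALSE,
                                  method = c("t", "wilcox")) {
  method <- match.arg(method)
  stopifnot(length(scores) == length(grouping))
  keep <- !is.na(scores) & !is.na(grouping)
  scores <- scores[keep]; grouping <- as.character(grouping)[keep]
  groups <- sort(unique(grouping))
  if (length(groups) < 2L) stopf("need at least 2 groups")
  m <- matrix(NA_real_, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i) next
      xi <- scores[grouping == groups[i]]
      xj <- scores[grouping == groups[j]]
      if (length(xi) < 2L || length(xj) < 2L) next
      p <- tryCatch({
        if (method == "t") t.test(xi, xj, var.equal = var_equal)$p.value
        else stats::wilcox.test(xi, xj, exact = FALSE)$p.value
      }, error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- p
    }
  }
  m
}

#' Concordance and group-comparison statistics for a TMA score table
#'
#' Computes inter-rater Cohen's kappa on the doubly-scored cores and pairwise
#' group-comparison p-value matrices of the primary score by stage, grade and
#' histotype.
#'
#' @param scores A `data.frame` as returned by [read_score_table()] (viable
#'   cores only).
#' @param var_equal,method Passed to [pairwise_group_ttests()].
#' @return An object of class `tma_concordance`: `kappa`, `n_double_scored`,
#'   and `by_stage` / `by_grade` / `by_histotype` p-value matrices.
#' @export
tma_concordance <- function(scores, var_equal = FALSE, method = "t") {
  dbl <- !is.na(scores$score_b)
  kappa <- if (sum(dbl) >= 2L)
    cohen_kappa(scores$score_a[dbl], scores$score_b[dbl]) else NA_real_
  mats <- lapply(c(stage = "stage", grade = "grade", histotype = "histotype"),
                 function(col) {
                   if (length(unique(stats::na.omit(scores[[col]]))) < 2L) return(NULL)
                   pairwise_group_ttests(scores$score_a, scores[[col]],
                                         var_equal = var_equal, method = method)
                 })
  structure(list(kappa = kappa, n_double_scored = sum(dbl),
                 by_stage = mats$stage, by_grade = mats$grade,
                 by_histotype = mats$histotype),
            class = "tma_concordance")
}

#' @export
print.tma_concordance <- function(x, ...) {
  cat("TMA scoring concordance\n")
  if (is.na(x$kappa)) {
    cat(sprintf("  kappa: undefined (%d doubly scored cores)\n", x$n_double_scored))
  } else {
    cat(sprintf("  Cohen's kappa = %.3f on %d doubly scored cores\n",
                x$kappa, x$n_double_scored))
  }
  for (nm in c("by_stage", "by_grade", "by_histotype")) {
    if (is.null(x[[nm]])) next
    cat(sprintf("  pairwise p-values %s (upper triangle):\n", sub("by_", "by ", nm)))
    up <- x[[nm]]
    up[lower.tri(up, diag = TRUE)] <- NA
    print(signif(up, 4), na.print = "-")
  }
  invisible(x)
}

#' Write TMA concordance outputs as TSV
#'
#' @param x A [tma_concordance()] object.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_tma_report <- function(x, dir) {
  stopifnot(inherits(x, "tma_concordance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(c(sprintf("cohen_kappa\t%s",
                       ifelse(is.na(x$kappa), "NA", format(x$kappa, digits = 15))),
               sprintf("n_double_scored\t%d", x$n_double_scored)),
             file.path(dir, "kappa.tsv"))
  for (nm in c("by_stage", "by_grade", "by_histotype")) {
    if (is.null(x[[nm]])) next
    m <- x[[nm]]
    m[lower.tri(m, diag = TRUE)] <- NA
    df <- data.frame(group = rownames(m), m, check.names = FALSE)
    write_tsv(df, file.path(dir, paste0("pairwise_", sub("by_", "", nm), ".tsv")))
  }
  invisible(dir)
}
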