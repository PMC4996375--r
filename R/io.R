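write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a cohort as its TSV trio
#'
#' Persists `expression.tsv` (first column `probe_id`, one column per
#' sample), `annotation.tsv` (`probe_id`, `gene_symbol`) and `clinical.tsv`
#' (`sample_id`, `time_months`, `event`) under `dir`.
#'
#' @param cohort An [expr_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "expr_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  expr <- data.frame(probe_id = rownames(cohort$matrix),
                     cohort$matrix, check.names = FALSE,
                     stringsAsFactors = FALSE)
  write_tsv(expr, file.path(dir, "expression.tsv"))
  write_tsv(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_tsv(cohort$survival, file.path(dir, "clinical.tsv"))
  invisible(dir)
}

#' Read a cohort from its TSV trio
#'
#' Counterpart of [write_cohort()]: reads and validates the expression
#' matrix, annotation and clinical tables, reconciling dimensions and sample
#' IDs. Probes lacking an annotation row are kept with an `NA` symbol;
#' non-numeric expression cells and sample mismatches raise errors naming the
#' offenders.
#'
#' @param dir Directory containing `expression.tsv`, `annotation.tsv`,
#'   `clinical.tsv`.
#' @param cohort_id Cohort label (default: the directory's basename).
#' @return An [expr_cohort()].
#' @export
read_cohort <- function(dir, cohort_id = basename(normalizePath(dir))) {
  paths <- file.path(dir, c("expression.tsv", "annotation.tsv", "clinical.tsv"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stopf("missing cohort file(s): %s", paste(missing, collapse = ", "))

  expr <- read.delim(paths[1], check.names = FALSE, stringsAsFactors = FALSE)
  if (names(expr)[1] != "probe_id") stopf("expression.tsv must start with a probe_id column")
  probe_ids <- as.character(expr$probe_id)
  m <- as.matrix(expr[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!vapply(expr[, -1, drop = FALSE], is.numeric, logical(1)))[1]
    badrow <- which(is.na(suppressWarnings(as.numeric(expr[[bad + 1L]]))))[1]
    stopf("non-numeric expression value at row %s, column '%s'",
          ifelse(is.na(badrow), "?", badrow), names(expr)[bad + 1L])
  }
  rownames(m) <- probe_ids

  annotation <- read.delim(paths[2], stringsAsFactors = FALSE)
  clinical <- read.delim(paths[3], stringsAsFactors = FALSE)
  clinical$sample_id <- as.character(clinical$sample_id)

  in_matrix <- colnames(m)
  no_clin <- setdiff(in_matrix, clinical$sample_id)
  if (length(no_clin))
    stopf("clinical table lacks sample(s) present in the matrix: %s",
          paste(no_clin, collapse = ", "))
  expr_cohort(m, annotation, clinical[clinical$sample_id %in% in_matrix, , drop = FALSE],
              cohort_id = cohort_id)
}

#' Write a cohort pair plus ground truth
#'
#' Writes each simulated cohort as its TSV trio under `cohort1/` and
#' `cohort2/`, and the planted signal genes as a plain-text list
#' (`signal_genes.txt`, one symbol per line, the planted hazard direction in
#' a second column).
#'
#' @param pair A `cohort_pair` from [generate_cohort_pair()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort_pair <- function(pair, dir) {
  stopifnot(inherits(pair, "cohort_pair"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_cohort(pair$cohort1, file.path(dir, "cohort1"))
  write_cohort(pair$cohort2, file.path(dir, "cohort2"))
  write_tsv(data.frame(gene_symbol = pair$signal_genes,
                       hazard_sign = unname(pair$signal_signs),
                       stringsAsFactors = FALSE),
            file.path(dir, "signal_genes.txt"))
  invisible(dir)
}
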