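#' Construct an expression cohort
#'
#' The unit of data both screens consume: a probes-by-samples log-intensity
#' matrix, a probe-to-gene-symbol annotation (many probes may map to one
#' symbol) and one survival record per sample.
#'
#' @param matrix Numeric matrix, probes in rows, samples in columns. Row and
#'   column names are taken as probe and sample identifiers if `probe_ids` /
#'   `sample_ids` are not given.
#' @param annotation `data.frame` with columns `probe_id` and `gene_symbol`,
#'   one row per probe. Probes lacking a symbol carry `NA` and are flagged.
#' @param survival `data.frame` with columns `sample_id`, `time_months`
#'   (positive, finite) and `event` (1 = death observed, 0 = right-censored).
#' @param cohort_id Character scalar naming the cohort.
#' @return An object of class `expr_cohort`.
#' @seealso [generate_cohort_pair()], [read_cohort()], [write_cohort()]
#' @export
expr_cohort <- function(matrix, annotation, survival, cohort_id = "cohort") {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stopf("`matrix` must be a numeric matrix (probes x samples)")
  probe_ids <- rownames(matrix)
  sample_ids <- colnames(matrix)
  if (is.null(probe_ids) || is.null(sample_ids))
    stopf("`matrix` must carry probe IDs as rownames and sample IDs as colnames")
  if (anyDuplicated(probe_ids)) stopf("duplicated probe IDs in matrix")
  if (anyDuplicated(sample_ids)) stopf("duplicated sample IDs in matrix")

  annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
  if (!all(c("probe_id", "gene_symbol") %in% names(annotation)))
    stopf("`annotation` needs columns probe_id, gene_symbol")
  if (anyDuplicated(annotation$probe_id))
    stopf("`annotation` has duplicated probe IDs; every probe has exactly one gene symbol")
  miss <- setdiff(probe_ids, annotation$probe_id)
  if (length(miss)) {
    # keep unannotated probes, flagged with NA symbol
    annotation <- rbind(annotation,
                        data.frame(probe_id = miss, gene_symbol = NA_character_,
                                   stringsAsFactors = FALSE))
  }
  annotation <- annotation[match(probe_ids, annotation$probe_id), , drop = FALSE]
  rownames(annotation) <- NULL

  survival <- as.data.frame(survival, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "time_months", "event") %in% names(survival)))
    stopf("`survival` needs columns sample_id, time_months, event")
  missing_surv <- setdiff(sample_ids, survival$sample_id)
  if (length(missing_surv))
    stopf("survival records missing for sample(s): %s",
          paste(missing_surv, collapse = ", "))
  extra <- setdiff(survival$sample_id, sample_ids)
  if (length(extra))
    stopf("survival records for unknown sample(s): %s", paste(extra, collapse = ", "))
  survival <- survival[match(sample_ids, survival$sample_id), , drop = FALSE]
  rownames(survival) <- NULL
  if (!is.numeric(survival$time_months) || any(!is.finite(survival$time_months)) ||
      any(survival$time_months <= 0))
    stopf("survival times must be finite and positive (months)")
  if (!all(survival$event %in% c(0, 1)))
    stopf("event indicator must be 0 (censored) or 1 (death observed)")
  if (anyNA(matrix) || any(!is.finite(matrix)))
    stopf("expression matrix contains missing or non-finite values")

  structure(list(matrix = matrix, annotation = annotation, survival = survival,
                 cohort_id = as.character(cohort_id)),
            class = "expr_cohort")
}

#' @export
print.expr_cohort <- function(x, ...) {
  cat(sprintf("Expression cohort '%s': %d probes x %d samples\n",
              x$cohort_id, nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  genes annotated: %d unique symbols (%d unannotated probes)\n",
              length(unique(stats::na.omit(x$annotation$gene_symbol))),
              sum(is.na(x$annotation$gene_symbol))))
  ev <- x$survival$event
  cat(sprintf("  survival: median %.1f months, %d events, %d censored (%.0f%%)\n",
              stats::median(x$survival$time_months), sum(ev == 1), sum(ev == 0),
              100 * mean(ev == 0)))
  invisible(x)
}

#' Dichotomize survival at a cut-off
#'
#' Splits patients into short (0) and long (1) survivors around a cut-off time.
#' A death at or before the cut-off is short; any follow-up extending past the
#' cut-off (event or censored) is long; a patient censored at or before the
#' cut-off has an unknowable class and is excluded from the mask.
#'
#' @param survival `data.frame` with columns `time_months` and `event`.
#' @param cutoff Cut-off time in months, positive.
#' @return A list with `label` (integer 0/1, `NA` where excluded) and
#'   `included` (logical mask).
#' @examples
#' s <- data.frame(time_months = c(30, 10, 10), event = c(1, 1, 0))
#' dichotomize(s, 16)
#' @export
dichotomize <- function(survival, cutoff) {
  if (is.null(survival) || NROW(survival) == 0L) stopf("empty survival table")
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stopf("`cutoff` must be a single positive number of months")
  t <- survival$time_months
  e <- survival$event
  label <- ifelse(t > cutoff, 1L,
                  ifelse(e == 1, 0L, NA_integer_))
  list(label = as.integer(label), included = !is.na(label))
}
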