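#' @keywords internal
"_PACKAGE"

#' @useDynLib survconsensus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp sd pnorm p.adjust t.test uniroot
#' @importFrom utils head read.delim write.table packageVersion
NULL

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible substream seed
#'
#' All randomness in the package flows from one global seed; stage-, cohort-,
#' cutoff- and probe-level seeds are derived deterministically by hashing the
#' labels of the substream, so partial re-runs reproduce exactly without
#' storing per-probe state.
#'
#' @param ... Atomic labels (coerced to character) identifying the substream,
#'   typically starting with the global seed.
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @examples
#' substream_seed(1L, "cohort1", 23, "P00017")
#' @export
substream_seed <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 31 + cp) %% 2147483647
  as.integer(h)
}

# case-insensitive, whitespace-trimmed gene-symbol normalization used wherever
# symbols from the two platforms are matched
norm_symbols <- function(x) toupper(trimws(as.character(x)))
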