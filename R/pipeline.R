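#' Full-pipeline configuration
#'
#' Bundles either a simulation config or a pair of on-disk cohort
#' directories with the analysis settings consumed by [run_pipeline()].
#'
#' @param simulation A [sim_config()], or `NULL` when reading cohorts from
#'   disk.
#' @param cohort_dirs Character vector of two directories readable by
#'   [read_cohort()]; ignored when `simulation` is given.
#' @param ann An [ann_control()].
#' @param cox_alpha,ttest_alpha Significance thresholds in (0, 1).
#' @param ttest_var_equal,ttest_rule,ties Passed to [consensus_screen()].
#' @param seed Global pipeline seed.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, cohort_dirs = NULL,
                            ann = ann_control(), cox_alpha = 0.05,
                            ttest_alpha = 0.05, ttest_var_equal = FALSE,
                            ttest_rule = "any", ties = "breslow", seed = 1L) {
  if (is.null(simulation) == is.null(cohort_dirs))
    stopf("give exactly one of `simulation` or `cohort_dirs`")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    simulation <- do.call(sim_config, simulation)
  if (!is.null(cohort_dirs) && length(cohort_dirs) != 2L)
    stopf("`cohort_dirs` must name exactly two directories")
  for (a in c(cox_alpha, ttest_alpha))
    if (a <= 0 || a >= 1) stopf("alphas must lie in (0, 1)")
  structure(list(simulation = simulation, cohort_dirs = cohort_dirs,
                 ann = ann, cox_alpha = cox_alpha, ttest_alpha = ttest_alpha,
                 ttest_var_equal = ttest_var_equal, ttest_rule = ttest_rule,
                 ties = ties, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; `simulation` and
#' `ann` are nested maps passed to [sim_config()] and [ann_control()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stopf("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulation)) y$simulation <- do.call(sim_config, y$simulation)
  if (!is.null(y$ann)) y$ann <- do.call(ann_control, y$ann)
  do.call(pipeline_config, y)
}

#' Run the complete pipeline and persist every stage
#'
#' Simulates (or reads) the two cohorts, runs [consensus_screen()], and
#' writes each stage's outputs under `outdir`: the cohort TSV trios (for
#' simulated data, with the planted ground truth), per-cohort neural-network
#' result and gene-weight tables, per-cohort Cox tables, the ranked consensus
#' report, a JSON audit trail, a plain-text summary including the
#' chance-probability statistic, and a `manifest.json` recording package
#' version, seed and all parameters so the run can be reproduced exactly.
#' Identical configs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory, created if needed.
#' @param verbose Progress messages.
#' @return The [consensus_screen()] object, invisibly, with the output paths
#'   in `attr(, "paths")`.
#' @export
run_pipeline <- function(config, outdir, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (!is.null(config$simulation)) {
    pair <- generate_cohort_pair(config$simulation)
    write_cohort_pair(pair, file.path(outdir, "cohorts"))
    cohort1 <- pair$cohort1
    cohort2 <- pair$cohort2
  } else {
    cohort1 <- read_cohort(config$cohort_dirs[1], "cohort1")
    cohort2 <- read_cohort(config$cohort_dirs[2], "cohort2")
  }

  fit <- consensus_screen(cohort1, cohort2, ann = config$ann,
                          cox_alpha = config$cox_alpha,
                          ttest_alpha = config$ttest_alpha,
                          ttest_var_equal = config$ttest_var_equal,
                          ttest_rule = config$ttest_rule, ties = config$ties,
                          seed = config$seed, verbose = verbose)

  paths <- c()
  save_tsv <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv(df, p)
    paths[name] <<- p
  }
  save_tsv(as.data.frame(fit$ann$cohort1), "ann_screen_cohort1.tsv")
  save_tsv(as.data.frame(fit$ann$cohort2), "ann_screen_cohort2.tsv")
  save_tsv(fit$gene_weights$cohort1, "gene_weights_cohort1.tsv")
  save_tsv(fit$gene_weights$cohort2, "gene_weights_cohort2.tsv")
  save_tsv(fit$cox$cohort1$results, "cox_screen_cohort1.tsv")
  save_tsv(fit$cox$cohort2$results, "cox_screen_cohort2.tsv")
  save_tsv(fit$final, "consensus_report.tsv")
  if (!is.null(fit$ttest_summary)) save_tsv(fit$ttest_summary, "ttest_summary.tsv")

  audit_path <- file.path(outdir, "audit.json")
  jsonlite::write_json(list(candidates = fit$candidates,
                            intersection = fit$intersection,
                            ttest_survivors = fit$ttest_survivors,
                            final = fit$final$gene_symbol,
                            dropped = fit$audit,
                            rank_criterion = fit$params$rank_criterion),
                       audit_path, pretty = TRUE, auto_unbox = FALSE, digits = NA)
  paths["audit.json"] <- audit_path

  summary_path <- file.path(outdir, "summary.txt")
  con <- file(summary_path, "w")
  sink(con); print(fit); sink()
  close(con)
  paths["summary.txt"] <- summary_path

  manifest <- list(package = "survconsensus",
                   version = as.character(packageVersion("survconsensus")),
                   seed = config$seed,
                   simulation = if (!is.null(config$simulation))
                     unclass(config$simulation) else NULL,
                   cohort_dirs = config$cohort_dirs,
                   ann = unclass(config$ann),
                   cox_alpha = config$cox_alpha, ttest_alpha = config$ttest_alpha,
                   ttest_var_equal = config$ttest_var_equal,
                   ttest_rule = config$ttest_rule, ties = config$ties)
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, pretty = TRUE, auto_unbox = TRUE,
                       digits = NA)
  paths["manifest.json"] <- manifest_path

  attr(fit, "paths") <- paths
  invisible(fit)
}
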