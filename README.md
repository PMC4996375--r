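# survconsensus

Consensus screening of survival-associated gene expression across two
independent microarray cohorts.

## The problem

Single-cohort gene lists from expression–survival screens replicate poorly:
different platforms, preprocessing and statistics produce largely disjoint
"significant" gene sets from comparable patient populations. One way to gain
confidence is a stringent consensus design: require a gene to look prognostic
in **two** cohorts on **two different platforms** under **two unrelated
statistical methods**, and additionally demand consistent effect direction.
`survconsensus` implements that design as a reusable, tested R pipeline,
aimed at analysts screening bulk expression cohorts (e.g. ovarian-cancer
microarray studies) for survival-associated genes.

## The method

Given two cohorts — each a probes × samples log-intensity matrix, a
probe→gene-symbol annotation and per-sample survival (time in months, event
indicator) — the pipeline runs:

1. **Neural-network probe ranking.** Survival is dichotomized at cut-offs
   *c* ∈ {16, 23, 30} months: death at or before *c* is a *short* survivor,
   follow-up past *c* is *long*, censoring at or before *c* is excluded. For
   every probe a three-layer perceptron (1 input, 2 sigmoid hidden nodes, 1
   sigmoid output) is trained by backpropagation on 60% of the classifiable
   samples, early-stopped on a 20% split, and scored by RMSE on a blind 20%
   validation split. Within each (cohort, cut-off) run, probes are ranked by
   ascending validation RMSE and the top fraction (default 0.05%, count
   `ceiling(f·n)`) is selected. A gene's **weight** (1–3) is the number of
   cut-offs at which at least one of its probes is selected; genes with
   weight ≥ 1 form the cohort's ANN candidate set.
2. **Univariate Cox screening.** For every probe, an in-house
   Newton–Raphson maximizer of the Cox partial likelihood (Breslow ties;
   Efron optional) fits `h(t|x) = h₀(t)·exp(βx)` with x the z-scored
   expression, so β is the log-hazard per 1 SD. Genes with any probe at
   Wald p ≤ 0.05 form the cohort's Cox candidate set.
3. **Consensus filters.** Genes present in all four candidate sets are kept;
   then a gene must have, in *each* cohort, at least one probe with a
   significant long-vs-short Welch t-test (p ≤ 0.05) at some cut-off; then
   the sign of its probe- and cut-off-averaged (mean long − mean short)
   difference must agree between cohorts. Survivors are ranked by
   (descending summed ANN weight, ascending minimum Cox p, alphabetical).
4. **Chance probability.** For a final list of *k* genes from probe
   universes *p₁*, *p₂*, the combined chance probability is
   `((k/p₁)·(k/p₂))²`. With the published k = 56, p₁ = 37,632, p₂ = 22,283
   this is 1.39859 × 10⁻¹¹.

A synthetic-cohort generator (`sim_config()`, `generate_cohort_pair()`)
produces platform-distinct cohort pairs with planted survival-signal genes
and right-censoring, so the whole pipeline is testable end to end without
any download. `plant_direction_conflict()` inverts one gene's association in
cohort 2 to exercise the direction filter. A separate module
(`cohen_kappa()`, `pairwise_group_ttests()`, `tma_concordance()`) provides
inter-rater agreement and group-comparison statistics for categorical
immunohistochemistry score tables.

## Worked example

```r
library(survconsensus)

pair <- generate_cohort_pair(sim_config(
  n_probes_1 = 400, n_probes_2 = 300, n_genes = 200,
  n_signal_genes = 10, effect_size = 1.0, seed = 3))

fit <- consensus_screen(pair$cohort1, pair$cohort2,
                        ann = ann_control(top_fraction = 0.05), seed = 3)
fit
#> Two-cohort consensus survival screen
#>   probes: 400 / 300; cut-offs: 16, 23, 30 months
#>   candidates  ANN: 15 / 15   Cox (p <= 0.05): 27 / 19
#>   four-way intersection: 10 genes
#>   after t-test filter:   10 genes
#>   final (direction-consistent): 10 genes
#>   chance probability (as defined in source publication): 6.94444e-07
#>   top genes:
#>  gene_symbol rank weight_cohort1 weight_cohort2 min_cox_p_cohort1 min_cox_p_cohort2
#>       G00158    1              3              3      1.298436e-07      4.135659e-14
#>       G00167    2              3              3      1.269765e-10      1.422271e-12
#>       G00054    3              3              3      1.628850e-10      3.833217e-07
#>       ...

sum(fit$final$gene_symbol %in% pair$signal_genes)
#> [1] 10
```

All ten planted signal genes are recovered with no false positives: each
final gene was selected by the neural-network rankings of both cohorts
(weights ≥ 1 at up to three cut-offs), was Cox-significant in both, passed
the t-test filter in both and had a concordant expression direction. The
chance probability 6.9 × 10⁻⁷ is `((10/400)·(10/300))²`. `summary(fit)`
adds the per-gene audit trail; `plot(fit)` shows each candidate's best Cox
evidence in the two cohorts. `run_pipeline(pipeline_config(...), outdir)`
runs the same analysis from a config (YAML-loadable) and persists every
stage's tables plus a manifest for exact re-runs.

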