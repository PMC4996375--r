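test_that("four-way intersection follows set semantics", {
  expect_identical(intersect_four_way(c("A", "B", "C"), c("B", "C", "D"),
                                      c("B", "C"), "C"),
                   "C")
  expect_length(intersect_four_way(character(0), c("A"), c("A"), c("A")), 0)
  # case-insensitive, whitespace-trimmed matching
  expect_identical(intersect_four_way(" brca1 ", "BRCA1", "Brca1", "BRCA1\t"),
                   "BRCA1")
})

test_that("intersection matches a brute-force membership recount", {
  set.seed(19)
  universe <- sprintf("g%04d", 1:1000)
  sets <- replicate(4, sample(universe, 100), simplify = FALSE)
  got <- intersect_four_way(sets[[1]], sets[[2]], sets[[3]], sets[[4]])
  brute <- sort(toupper(Filter(function(g)
    all(vapply(sets, function(s) g %in% s, logical(1))), universe)))
  expect_identical(got, brute)
})

test_that("chance probability reproduces its defining arithmetic", {
  expect_identical(chance_probability(0, 100, 50), 0)
  expect_equal(chance_probability(10, 100, 100), 1e-4)
  expect_error(chance_probability(-1, 10, 10), "k must lie")
  expect_error(chance_probability(5, 0, 10), "positive")
  # strictly increasing in k, decreasing in each probe count
  set.seed(7)
  for (i in 1:20) {
    p1 <- sample(100:5000, 1); p2 <- sample(100:5000, 1)
    k <- sample(1:(min(p1, p2) - 1), 1)
    expect_gt(chance_probability(k + 1, p1, p2), chance_probability(k, p1, p2))
    expect_lt(chance_probability(k, p1 + 50, p2), chance_probability(k, p1, p2))
    expect_lt(chance_probability(k, p1, p2 + 50), chance_probability(k, p1, p2))
  }
})

make_fake_cox <- function(genes, p) {
  list(results = data.frame(probe_id = paste0("p", seq_along(genes)),
                            gene_symbol = genes, p_value = p,
                            converged = TRUE, stringsAsFactors = FALSE))
}

test_that("final ranking follows the declared composite key", {
  w1 <- data.frame(gene_symbol = c("A", "B", "C"), weight = c(3L, 2L, 2L))
  w2 <- data.frame(gene_symbol = c("A", "B", "C"), weight = c(3L, 3L, 3L))
  cox1 <- make_fake_cox(c("A", "B", "C"), c(0.01, 0.001, 0.01))
  cox2 <- make_fake_cox(c("A", "B", "C"), c(0.02, 0.01, 0.01))
  r <- rank_final_genes(c("A", "B", "C"), w1, w2, cox1, cox2)
  # A: weight 6; B and C tie at 5, B has smaller min p
  expect_identical(r$gene_symbol, c("A", "B", "C"))
  expect_identical(r$rank, 1:3)
})

test_that("ranking equals an independent sort by the composite key", {
  set.seed(23)
  genes <- sprintf("G%02d", 1:30)
  w1 <- data.frame(gene_symbol = genes, weight = sample(1:3, 30, TRUE))
  w2 <- data.frame(gene_symbol = genes, weight = sample(1:3, 30, TRUE))
  cox1 <- make_fake_cox(genes, runif(30, 0, 0.05))
  cox2 <- make_fake_cox(genes, runif(30, 0, 0.05))
  r <- rank_final_genes(genes, w1, w2, cox1, cox2)
  total <- w1$weight + w2$weight
  minp <- pmin(cox1$results$p_value, cox2$results$p_value)
  brute <- genes[order(-total, minp, genes)]
  expect_identical(r$gene_symbol, brute)
})

test_that("t-test filter demands significance in both cohorts", {
  pair <- small_pair()
  gene <- pair$signal_genes[3]
  # break the gene's association in cohort 2 by replacing its probes with noise
  broken <- pair
  idx <- which(broken$cohort2$annotation$gene_symbol == gene)
  set.seed(99)
  broken$cohort2$matrix[idx, ] <- rnorm(length(idx) * ncol(broken$cohort2$matrix))

  tt_ok <- ttest_filter(gene, pair$cohort1, pair$cohort2)
  tt_broken <- ttest_filter(gene, broken$cohort1, broken$cohort2)
  expect_true(gene %in% tt_ok$survivors)       # planted signal retained
  expect_false(gene %in% tt_broken$survivors)  # significant in cohort 1 only

  # result invariant to gene input ordering
  g3 <- pair$signal_genes[1:3]
  a <- ttest_filter(g3, pair$cohort1, pair$cohort2)$survivors
  b <- ttest_filter(rev(g3), pair$cohort1, pair$cohort2)$survivors
  expect_identical(a, b)
})

test_that("direction filter keeps concordant genes and drops planted conflicts", {
  pair <- small_pair()
  gene_ok <- pair$signal_genes[4]
  gene_bad <- pair$signal_genes[5]
  mod <- plant_direction_conflict(pair, gene_bad)
  tt <- ttest_filter(c(gene_ok, gene_bad), mod$cohort1, mod$cohort2)
  dir <- direction_filter(tt$summary)
  expect_true(gene_ok %in% dir$final)
  expect_false(gene_bad %in% dir$final)
  expect_match(dir$dropped$reason[dir$dropped$gene_symbol == gene_bad],
               "conflict")

  # decisions match a recomputation of group means from the raw matrices
  for (cid in c("cohort1", "cohort2")) {
    ch <- mod[[cid]]
    for (g in c(gene_ok, gene_bad)) {
      diffs <- vapply(c(16, 23, 30), function(ct) {
        d <- dichotomize(ch$survival, ct)
        probes <- ch$annotation$probe_id[ch$annotation$gene_symbol == g]
        mean(vapply(probes, function(p) {
          mean(ch$matrix[p, d$included & d$label == 1]) -
            mean(ch$matrix[p, d$included & d$label == 0])
        }, numeric(1)))
      }, numeric(1))
      expected_dir <- sign(mean(diffs))
      got <- dir$directions
      expect_equal(got$direction[got$gene_symbol == g & got$cohort_id == ch$cohort_id],
                   expected_dir)
    }
  }
})
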