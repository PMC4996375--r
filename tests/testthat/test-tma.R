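test_that("kappa hits its closed-form anchor points", {
  a <- c(0, 0, 1, 1, 2, 3)
  expect_identical(cohen_kappa(a, a), 1)
  expect_identical(cohen_kappa(c(0, 0, 1, 1), c(1, 1, 0, 0)), -1)
  expect_warning(k <- cohen_kappa(rep(2, 10), rep(2, 10)), "undefined")
  expect_true(is.na(k))
})

test_that("kappa matches the direct contingency computation on random raters", {
  set.seed(31)
  for (i in 1:20) {
    a <- sample(0:3, 200, replace = TRUE)
    b <- ifelse(runif(200) < 0.6, a, sample(0:3, 200, replace = TRUE))
    expect_equal(cohen_kappa(a, b), kappa_direct(a, b))
  }
})

test_that("kappa is invariant under consistent category relabeling", {
  set.seed(5)
  a <- sample(0:3, 100, replace = TRUE)
  b <- ifelse(runif(100) < 0.7, a, sample(0:3, 100, replace = TRUE))
  perm <- c(3, 0, 2, 1)  # relabel 0->3, 1->0, 2->2, 3->1
  expect_equal(cohen_kappa(a, b), cohen_kappa(perm[a + 1], perm[b + 1]))
})

test_that("pairwise score comparisons behave at the extremes and are symmetric", {
  set.seed(6)
  same <- c(rep(0:3, 5), rep(0:3, 5))
  g <- rep(c("x", "y"), each = 20)
  m <- pairwise_group_ttests(same, g)
  expect_gte(m["x", "y"], 0.99)

  scores <- c(rnorm(10, 0, 0.01), rnorm(10, 3, 0.01))
  g2 <- rep(c("lo", "hi"), each = 10)
  m2 <- pairwise_group_ttests(scores, g2)
  expect_lt(m2["lo", "hi"], 1e-6)
  expect_identical(m2["lo", "hi"], m2["hi", "lo"])

  # groups below the size floor and doubly-degenerate pairs are missing
  m3 <- pairwise_group_ttests(c(1, 1, 1, 2, 0, 3), c("a", "a", "a", "b", "c", "c"))
  expect_true(is.na(m3["a", "b"]))   # group b has one core
  m4 <- pairwise_group_ttests(c(1, 1, 2, 2), c("a", "a", "b", "b"))
  expect_true(is.na(m4["a", "b"]))   # zero variance in both groups
})

write_demo_scores <- function(path, extra = NULL) {
  set.seed(41)
  n <- 60
  df <- data.frame(
    core_id = sprintf("core%02d", 1:n),
    stage = sample(c("I", "II", "III"), n, replace = TRUE),
    grade = sample(c("G1", "G2", "G3"), n, replace = TRUE),
    histotype = sample(c("serous", "mucinous"), n, replace = TRUE),
    tumor_cells = sample(100:500, n, replace = TRUE),
    score_a = sample(0:3, n, replace = TRUE))
  df$score_b <- ifelse(seq_len(n) <= 8, df$score_a, NA)
  if (!is.null(extra)) df <- rbind(df, extra)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  df
}

test_that("cores below 100 tumor cells are excluded before any statistic", {
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_demo_scores(f1)
  # an extra non-viable core must change nothing
  write_demo_scores(f2, extra = data.frame(
    core_id = "coreXX", stage = "I", grade = "G1", histotype = "serous",
    tumor_cells = 99, score_a = 3, score_b = 0))
  s1 <- read_score_table(f1)
  s2 <- read_score_table(f2)
  expect_identical(attr(s2, "n_excluded"), 1L)
  r1 <- tma_concordance(s1)
  r2 <- tma_concordance(s2)
  expect_identical(r1$kappa, r2$kappa)
  expect_identical(r1$by_stage, r2$by_stage)
  expect_identical(r1$by_grade, r2$by_grade)
  expect_identical(r1$by_histotype, r2$by_histotype)
})

test_that("the concordance report assembles kappa and the three matrices", {
  f <- tempfile(fileext = ".tsv")
  write_demo_scores(f)
  s <- read_score_table(f)
  r <- tma_concordance(s)
  expect_identical(r$n_double_scored, 8L)
  expect_identical(r$kappa, cohen_kappa(s$score_a[1:8], s$score_b[1:8]))
  expect_identical(rownames(r$by_stage), c("I", "II", "III"))
  expect_true(isSymmetric(r$by_histotype))
  d <- tempfile()
  write_tma_report(r, d)
  expect_true(all(file.exists(file.path(d, c("kappa.tsv", "pairwise_stage.tsv",
                                             "pairwise_grade.tsv",
                                             "pairwise_histotype.tsv")))))
})

test_that("malformed score tables are rejected", {
  f <- tempfile(fileext = ".tsv")
  df <- data.frame(core_id = "c1", stage = "I", grade = "G1", histotype = "s",
                   tumor_cells = 200, score_a = 5)
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_score_table(f), "0-3")
})
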