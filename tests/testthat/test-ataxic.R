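# Core scorer: per-cell sample SD across genes of |z|, z-scored per gene
# with the n-1 denominator, zero-variance genes dropped and reported.

test_that("gene z-scores standardize each retained row to mean 0, sample SD 1", {
  em <- toy_matrix()
  zs <- gene_zscores(em)
  expect_equal(unname(zs$z["G1", ]), c(-1, 0, 1))
  expect_identical(zs$dropped_genes, "G2")
  set.seed(5)
  big <- random_expr_matrix(40, 15)
  z <- gene_zscores(big)$z
  expect_lt(max(abs(rowMeans(z))), 1e-9)
  expect_lt(max(abs(apply(z, 1, sd) - 1)), 1e-9)
})

test_that("z-scoring guards its preconditions", {
  one_cell <- expression_matrix(matrix(1:2, 2, 1, dimnames = list(c("G1", "G2"), "c1")),
                                norm_state = "log2p1")
  expect_error(gene_zscores(one_cell), "at least 2 cells",
               class = "ataxic_validation_error")
  flat <- expression_matrix(matrix(3, 2, 3, dimnames = list(c("G1", "G2"),
                                                            c("a", "b", "c"))),
                            norm_state = "log2p1")
  expect_error(gene_zscores(flat), "zero variance",
               class = "ataxic_validation_error")
  raw <- toy_matrix(norm_state = "raw")
  expect_error(gene_zscores(raw), class = "ataxic_state_error")
  expect_silent(gene_zscores(raw, allow_raw = TRUE))
})

test_that("worked fixture scores match the naive oracle and drop G2", {
  em <- toy_matrix()
  fit <- ataxic(em, scope = "cohort")
  expect_equal(fit$scores$score, naive_ataxic(em$values), tolerance = 1e-12)
  expect_equal(fit$scores$score, c(0.17258430, 0.26726124, 0.09467694),
               tolerance = 1e-7)
  expect_identical(fit$dropped_genes$cohort, "G2")
  expect_identical(fit$n_genes_used[["cohort"]], 2L)
})

test_that("with exactly two cells and no tied gene values every score is zero", {
  set.seed(11)
  for (i in 1:20) {
    em <- random_expr_matrix(30, 2)
    sc <- ataxic_scores(em, scope = "cohort")
    expect_lt(max(abs(sc$score)), 1e-12)
  }
})

test_that("a cell sitting at every gene mean scores exactly zero", {
  set.seed(3)
  v <- matrix(rnorm(20 * 4), 20, 4)
  # appending the mean of the first 4 cells leaves it equal to the mean of
  # all 5, so the new cell's z-scores are all zero
  v <- cbind(v, rowMeans(v))
  dimnames(v) <- list(sprintf("G%d", 1:20), sprintf("c%d", 1:5))
  em <- expression_matrix(v, norm_state = "log2p1")
  sc <- ataxic_scores(em, scope = "cohort")
  expect_lt(abs(sc$score[5]), 1e-12)
})

test_that("scores are invariant to per-gene affine maps and gene order", {
  set.seed(21)
  em <- random_expr_matrix(50, 12)
  base <- ataxic_scores(em, scope = "cohort")$score
  a <- runif(50, 0.2, 3) * sample(c(-1, 1), 50, replace = TRUE)
  b <- rnorm(50, 0, 5)
  em2 <- expression_matrix(em$values * a + b, em$samples, norm_state = "log2p1")
  expect_equal(ataxic_scores(em2, scope = "cohort")$score, base, tolerance = 1e-9)

  perm <- sample(50)
  em3 <- expression_matrix(em$values[perm, ], em$samples, norm_state = "log2p1")
  expect_equal(ataxic_scores(em3, scope = "cohort")$score, base, tolerance = 1e-12)
})

test_that("cell permutation permutes scores (equivariance)", {
  set.seed(22)
  em <- random_expr_matrix(40, 10)
  base <- ataxic_scores(em, scope = "cohort")
  perm <- sample(10)
  emp <- expression_matrix(em$values[, perm], em$samples[perm],
                           norm_state = "log2p1")
  permuted <- ataxic_scores(emp, scope = "cohort")
  expect_equal(setNames(permuted$score, permuted$cell_id)[base$cell_id],
               setNames(base$score, base$cell_id), tolerance = 1e-12)
})

test_that("vectorized scorer matches the naive double-loop reference", {
  set.seed(31)
  for (i in 1:5) {
    em <- random_expr_matrix(50, 20)
    expect_equal(ataxic_scores(em, scope = "cohort")$score,
                 naive_ataxic(em$values), tolerance = 1e-10)
  }
})

test_that("per-sample scope standardizes within each patient independently", {
  set.seed(41)
  v <- matrix(runif(30 * 8, 0, 10), 30, 8,
              dimnames = list(sprintf("G%d", 1:30), sprintf("c%d", 1:8)))
  samples <- setNames(rep(c("P1", "P2"), each = 4), colnames(v))
  em <- expression_matrix(v, samples, norm_state = "log2p1")
  fit <- ataxic(em, scope = "sample")
  for (p in c("P1", "P2")) {
    idx <- which(samples == p)
    expect_equal(fit$scores$score[idx], naive_ataxic(v[, idx]), tolerance = 1e-10)
  }
  expect_error(
    ataxic(expression_matrix(v, setNames(c("solo", rep("P", 7)), colnames(v)),
                             norm_state = "log2p1")),
    "solo", class = "ataxic_validation_error")
})

test_that("scores are non-negative and zero only for equal |z| profiles", {
  set.seed(51)
  em <- random_expr_matrix(60, 15)
  sc <- ataxic_scores(em, scope = "cohort")$score
  expect_true(all(sc >= 0))
  expect_true(all(is.finite(sc)))
})

test_that("score summaries match brute-force accumulation", {
  tab <- data.frame(cell_id = sprintf("c%d", 1:5),
                    sample_id = c("A", "A", "B", "B", "B"),
                    score = c(0.1, 0.3, 0.2, 0.5, 0.35))
  s <- summarize_scores(tab)
  expect_equal(s$mean[s$group == "A"], 0.2)
  expect_equal(s$variation[s$group == "A"], 0.2)
  expect_equal(s$mean[s$group == "B"], mean(c(0.2, 0.5, 0.35)))
  expect_equal(s$variation[s$group == "B"], 0.3)
  expect_equal(s$sd[s$group == "B"], sd(c(0.2, 0.5, 0.35)))
  single <- summarize_scores(tab[1, ])
  expect_equal(single$variation, 0)
})

test_that("the ataxic object prints, summarizes and coerces", {
  fit <- ataxic(toy_matrix(), scope = "cohort")
  expect_output(print(fit), "scope: cohort")
  expect_s3_class(summary(fit), "summary.ataxic")
  expect_identical(as.data.frame(fit), fit$scores)
})
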