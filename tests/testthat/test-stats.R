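# Association statistics checked against independent routes: explicit
# rank-then-Pearson sums for Spearman, the textbook step-up formula for BH,
# stats::wilcox.test for Mann-Whitney, and monotone-transform invariance.

test_that("Spearman handles perfect monotone, reversal and tied fixtures", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(30, 20, 10))$rho, -1)
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_cor(x, y)$rho, brute_spearman_rho(x, y), tolerance = 1e-12)
  set.seed(2)
  for (i in 1:10) {
    x <- sample(1:6, 8, replace = TRUE)
    y <- sample(1:6, 8, replace = TRUE)
    if (length(unique(x)) == 1 || length(unique(y)) == 1) next
    expect_equal(spearman_cor(x, y)$rho, brute_spearman_rho(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Spearman rho is invariant under strictly monotone transforms", {
  set.seed(12)
  x <- rnorm(25); y <- rnorm(25)
  r0 <- spearman_cor(x, y)
  expect_equal(spearman_cor(exp(x), y)$rho, r0$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(x, y^3 + 5 * y)$rho, r0$rho, tolerance = 1e-12)
  expect_equal(spearman_cor(exp(x), y)$p, r0$p, tolerance = 1e-12)
})

test_that("exact Spearman p for small untied samples matches cor.test", {
  set.seed(13)
  for (n in c(5, 7, 8)) {
    x <- sample(100, n); y <- sample(100, n)
    mine <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(mine$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("large-sample Spearman p uses the t approximation", {
  set.seed(14)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  mine <- spearman_cor(x, y)
  rho <- cor(rank(x), rank(y))
  tt <- rho * sqrt(38 / (1 - rho^2))
  expect_equal(mine$p, 2 * pt(-abs(tt), 38), tolerance = 1e-12)
})

test_that("constant input yields a flagged record, not a number", {
  r <- spearman_cor(rep(1, 5), 1:5)
  expect_true(is.na(r$rho))
  expect_identical(r$note, "constant input")
  expect_error(spearman_cor(1:2, 1:2), class = "ataxic_validation_error")
  expect_error(spearman_cor(c(1, NA, 3), 1:3), class = "ataxic_validation_error")
})

test_that("BH adjustment equals the step-up definition and p.adjust edge cases", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(9)
  for (i in 1:50) {
    p <- runif(sample(1:12, 1))
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    expect_true(all(bh_adjust(p) >= p - 1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "ataxic_validation_error")
})

test_that("one-tailed Mann-Whitney: exact enumeration on the textbook case", {
  r <- mann_whitney_one_tailed(c(1, 2), c(3, 4), direction = "a_less")
  expect_equal(r$p, 1 / 6)
  expect_identical(r$method, "exact")
  expect_equal(r$u, 0)

  same <- mann_whitney_one_tailed(c(1, 2, 3), c(1, 2, 3), "a_greater")
  expect_gte(same$p, 0.5)

  a <- c(1.2, 3.4, 2.2); b <- c(0.5, 2.9, 4.1, 1.1)
  expect_equal(mann_whitney_one_tailed(a, b, "a_greater")$p,
               mann_whitney_one_tailed(b, a, "a_less")$p, tolerance = 1e-12)
  expect_error(mann_whitney_one_tailed(numeric(0), 1:3),
               class = "ataxic_validation_error")
})

test_that("exact Mann-Whitney matches wilcox.test over all small sizes", {
  set.seed(17)
  for (na in 1:5) for (nb in 1:5) {
    a <- sample(1000, na); b <- sample(1000, nb)
    for (dir in c("a_greater", "a_less")) {
      alt <- if (dir == "a_greater") "greater" else "less"
      ref <- wilcox.test(a, b, alternative = alt, exact = TRUE)
      mine <- mann_whitney_one_tailed(a, b, dir)
      expect_equal(mine$u, unname(ref$statistic))
      expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    }
  }
})

test_that("tied Mann-Whitney uses the corrected normal approximation", {
  set.seed(18)
  a <- sample(1:5, 20, replace = TRUE)
  b <- sample(2:6, 25, replace = TRUE)
  for (dir in c("a_greater", "a_less")) {
    alt <- if (dir == "a_greater") "greater" else "less"
    ref <- suppressWarnings(wilcox.test(a, b, alternative = alt, exact = FALSE,
                                        correct = TRUE))
    mine <- mann_whitney_one_tailed(a, b, dir)
    expect_identical(mine$method, "normal_approx")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Shapiro check flags non-Gaussian data and passes Gaussian data", {
  set.seed(19)
  jitter_const <- c(rep(1, 95), 1 + rnorm(5, 0, 1e-3))
  expect_lt(shapiro_check(jitter_const)$p, 0.05)
  hits <- sum(vapply(1:200, function(i) {
    set.seed(1000 + i)
    shapiro_check(rnorm(100))$p > 0.05
  }, logical(1)))
  expect_gte(hits, 190)
  expect_error(shapiro_check(c(1, 2)), class = "ataxic_validation_error")
})

test_that("per-group correlation composes spearman and BH, excluding flagged groups", {
  scores <- data.frame(cell_id = sprintf("c%d", 1:12),
                       sample_id = rep(c("P1", "P2", "P3"), each = 4),
                       score = c(1, 2, 3, 4, 4, 3, 2, 1, 5, 5, 5, 5))
  cov <- data.frame(cell_id = sprintf("c%d", 1:12),
                    score = c(10, 20, 30, 40, 1, 2, 3, 4, 1, 2, 3, 4))
  out <- correlate_by_group(scores, cov)
  expect_equal(out$rho[out$group_id == "P1"], 1)
  expect_equal(out$rho[out$group_id == "P2"], -1)
  expect_true(is.na(out$rho[out$group_id == "P3"]))
  ok <- !is.na(out$p_raw)
  expect_equal(out$p_adj[ok], bh_adjust(out$p_raw[ok]), tolerance = 1e-12)
  expect_true(is.na(out$p_adj[!ok]))

  none <- correlate_by_group(scores, cov, fdr_scope = "none")
  expect_true(all(is.na(none$p_adj)))
  expect_error(correlate_by_group(scores, data.frame(cell_id = "zz", score = 1)),
               class = "ataxic_validation_error")
})

test_that("star annotations follow the FDR ladder", {
  scores <- data.frame(cell_id = sprintf("c%d", 1:30),
                       sample_id = rep("P1", 30),
                       score = 1:30)
  cov <- data.frame(cell_id = sprintf("c%d", 1:30), score = (1:30)^2)
  out <- correlate_by_group(scores, cov)
  expect_identical(out$significance, "***")
})

test_that("drug screen counts significant signs and honors pairwise deletion", {
  set.seed(23)
  lines <- sprintf("L%02d", 1:20)
  sc <- data.frame(cell_id = lines, score = seq(0, 1, length.out = 20))
  viab <- rbind(
    pos = seq(1, 2, length.out = 20),                  # rho = +1
    neg = seq(2, 1, length.out = 20),                  # rho = -1
    noise = rnorm(20),
    sparse = c(1, 2, NA, rep(NA, 17)),                 # < 3 shared lines
    gappy = c(NA, NA, seq(1, 2, length.out = 18)))     # still monotone
  colnames(viab) <- lines
  res <- drug_screen(sc, viab, fdr_threshold = 0.05)
  expect_identical(res$skipped$compound, "sparse")
  expect_equal(res$records$n[res$records$compound == "gappy"], 18)
  pos_sig <- res$records$p_adj < 0.05 & res$records$rho > 0
  neg_sig <- res$records$p_adj < 0.05 & res$records$rho < 0
  expect_identical(res$n_significant_positive, sum(pos_sig, na.rm = TRUE))
  expect_identical(res$n_significant_negative, sum(neg_sig, na.rm = TRUE))
  expect_lte(res$n_significant_positive + res$n_significant_negative,
             nrow(res$records))

  perm <- sample(20)
  res2 <- drug_screen(sc[perm, ], viab[, perm], fdr_threshold = 0.05)
  expect_equal(res2$records$rho, res$records$rho, tolerance = 1e-12)
  expect_identical(res2$n_significant_positive, res$n_significant_positive)
})
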