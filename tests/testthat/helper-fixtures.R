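# Shared fixtures and independent oracles. The oracles deliberately use the
# most naive formulation available (explicit loops, stats::sd, the textbook
# step-up formula) so they stay independent of the vectorized paths they
# check.

# The 3-gene x 3-cell worked fixture: G2 is constant and must be dropped.
toy_matrix <- function(norm_state = "log2p1") {
  v <- matrix(c(1, 2, 3,
                2, 2, 2,
                0, 1, 5),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("G1", "G2", "G3"), c("c1", "c2", "c3")))
  expression_matrix(v, norm_state = norm_state)
}

random_expr_matrix <- function(m, t, norm_state = "log2p1", min = 0, max = 10) {
  v <- matrix(runif(m * t, min, max), m, t,
              dimnames = list(sprintf("G%d", seq_len(m)),
                              sprintf("c%d", seq_len(t))))
  expression_matrix(v, norm_state = norm_state)
}

# Naive double-loop reference scorer: per-gene z via mean()/sd(), per-cell
# score via sd() of the absolute z column.
naive_ataxic <- function(values) {
  z <- NULL
  for (i in seq_len(nrow(values))) {
    s <- stats::sd(values[i, ])
    if (s > 0) z <- rbind(z, (values[i, ] - mean(values[i, ])) / s)
  }
  out <- numeric(ncol(values))
  for (j in seq_len(ncol(values))) out[j] <- stats::sd(abs(z[, j]))
  out
}

# Textbook BH: adjusted p_i = min over k with p_(k) >= p_(i)... computed as
# min_{k >= rank(i)} p_(k) * m / k, capped at 1.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, min(ps[i:m] * m / (i:m)))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Average ranks computed by explicit definition (mean position of tied
# values), then Pearson by explicit sums -- an independent route to Spearman.
brute_spearman_rho <- function(x, y) {
  avg_rank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) r[i] <- mean(which(sort(v) == v[i]))
    r
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}
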