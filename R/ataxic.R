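#' Per-gene z-scores of an expression matrix
#'
#' Standardizes every gene (row) across cells: z = (x - row mean) / row
#' sample SD, with the n-1 denominator. Genes whose sample SD is zero are
#' dropped (their z-score is undefined) and reported.
#'
#' @param mat An [expression_matrix()], normally log2(TPM+1); set
#'   `allow_raw = TRUE` to standardize a raw matrix.
#' @param allow_raw Permit `norm_state = "raw"` input.
#' @return List with `z` (matrix of z-scores over the retained genes) and
#'   `dropped_genes` (character vector of zero-variance gene ids).
#' @examples
#' v <- matrix(c(1, 2, 3, 2, 2, 2), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("G1", "G2"), c("c1", "c2", "c3")))
#' em <- expression_matrix(v, norm_state = "log2p1")
#' gene_zscores(em)
#' @export
gene_zscores <- function(mat, allow_raw = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$norm_state == "raw" && !allow_raw)
    err_state("matrix is raw; normalize with normalize_log2() or set allow_raw = TRUE")
  v <- mat$values
  t_cells <- ncol(v)
  if (t_cells < 2)
    err_validate("z-scoring needs at least 2 cells")
  mu <- rowMeans(v)
  dev <- v - mu
  sdv <- sqrt(rowSums(dev^2) / (t_cells - 1))
  keep <- sdv > 0
  if (!any(keep))
    err_validate("every gene has zero variance across cells; nothing to standardize")
  z <- dev[keep, , drop = FALSE] / sdv[keep]
  list(z = z, dropped_genes = rownames(v)[!keep])
}

#' ATAXIC transcriptomic-perturbation heterogeneity scores
#'
#' Scores each cell by the sample standard deviation, across genes, of its
#' absolute per-gene z-scored expression. A cell whose genes all deviate from
#' their population means by a similar number of standard deviations (a
#' synchronous perturbation) scores low; a cell whose deviations are very
#' unequal in magnitude (asynchronous perturbation) scores high.
#'
#' Within each scope group the genes are z-scored across that group's cells
#' (zero-variance genes dropped), the absolute values taken, and each cell's
#' score is the sample SD (n-1 denominator over the retained genes) of its
#' absolute z-scores.
#'
#' @param mat An [expression_matrix()], normally log2(TPM+1).
#' @param scope `"sample"` (default) standardizes and scores within each
#'   sample/patient independently; `"cohort"` scores across all cells at
#'   once, as when comparing cells of one cancer type on a common footing.
#' @param allow_raw Permit scoring a raw matrix (for experimentation; no
#'   internal re-normalization is performed either way).
#' @return An object of class `ataxic`: list with `scores` (data.frame
#'   `cell_id`, `sample_id`, `score`, in input cell order), `scope`,
#'   `dropped_genes` (named list per group), `n_genes_used` (named integer
#'   vector per group), `norm_state` and `call`. Methods: `print`, `summary`,
#'   `plot`, `as.data.frame`.
#' @examples
#' v <- matrix(c(1, 2, 3, 2, 2, 2, 0, 1, 5), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("G1", "G2", "G3"), c("c1", "c2", "c3")))
#' em <- expression_matrix(v, norm_state = "log2p1")
#' fit <- ataxic(em, scope = "cohort")
#' fit$scores
#' summary(fit)
#' @export
ataxic <- function(mat, scope = c("sample", "cohort"), allow_raw = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  scope <- match.arg(scope)
  cells <- colnames(mat$values)
  groups <- if (scope == "sample") mat$samples else
    stats::setNames(rep("cohort", length(cells)), cells)

  score <- stats::setNames(rep(NA_real_, length(cells)), cells)
  dropped <- list()
  n_used <- integer(0)
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2)
      err_validate(sprintf("group '%s' has fewer than 2 cells; cannot z-score", g))
    sub <- em_subset_cells(mat, idx)
    zs <- tryCatch(gene_zscores(sub, allow_raw = allow_raw),
                   ataxic_validation_error = function(e)
                     err_validate(sprintf("group '%s': %s", g, conditionMessage(e))))
    if (nrow(zs$z) < 2)
      err_validate(sprintf("group '%s' retains fewer than 2 genes after dropping zero-variance genes", g))
    az <- abs(zs$z)
    m_prime <- nrow(az)
    # two-pass column SD: numerically matches the naive per-cell sd()
    dev <- az - rep(colMeans(az), each = m_prime)
    score[idx] <- sqrt(colSums(dev^2) / (m_prime - 1))
    dropped[[g]] <- zs$dropped_genes
    n_used[g] <- m_prime
  }
  structure(list(
    scores = data.frame(cell_id = cells, sample_id = unname(mat$samples),
                        score = unname(score), stringsAsFactors = FALSE),
    scope = scope, dropped_genes = dropped, n_genes_used = n_used,
    norm_state = mat$norm_state, call = match.call()
  ), class = "ataxic")
}

#' ATAXIC scores as a plain table
#'
#' Convenience wrapper around [ataxic()] returning just the per-cell score
#' table.
#'
#' @inheritParams ataxic
#' @return data.frame with columns `cell_id`, `sample_id`, `score`.
#' @export
ataxic_scores <- function(mat, scope = c("sample", "cohort"), allow_raw = FALSE) {
  ataxic(mat, scope = scope, allow_raw = allow_raw)$scores
}

#' @export
print.ataxic <- function(x, ...) {
  cat("ATAXIC transcriptomic-perturbation heterogeneity scores\n")
  cat(sprintf("  scope: %s   cells: %d   groups: %d\n",
              x$scope, nrow(x$scores), length(x$n_genes_used)))
  cat(sprintf("  score range: [%.4g, %.4g]   dropped zero-variance genes: %d\n",
              min(x$scores$score), max(x$scores$score),
              sum(lengths(x$dropped_genes))))
  invisible(x)
}

#' Summarize per-cell scores by group
#'
#' Per group: number of cells, mean score, variation (max minus min, the
#' spread statistic used when contrasting cancer types), and sample SD.
#'
#' @param table data.frame with columns `cell_id`, `sample_id`, `score` (or
#'   an `ataxic` object's `scores` element).
#' @param grouping Either the name of the grouping column (default
#'   `"sample_id"`) or a vector of group labels aligned with the rows.
#' @return data.frame with columns `group`, `n`, `mean`, `variation`, `sd`.
#' @export
summarize_scores <- function(table, grouping = "sample_id") {
  if (inherits(table, "ataxic")) table <- table$scores
  g <- if (is.character(grouping) && length(grouping) == 1 &&
           grouping %in% names(table)) table[[grouping]] else grouping
  if (length(g) != nrow(table))
    err_validate("grouping length does not match the score table")
  keep <- !is.na(g)
  if (any(!keep)) warning("rows with empty group omitted from summary")
  sp <- split(table$score[keep], g[keep])
  out <- data.frame(
    group = names(sp),
    n = vapply(sp, length, integer(1)),
    mean = vapply(sp, mean, numeric(1)),
    variation = vapply(sp, function(s) max(s) - min(s), numeric(1)),
    sd = vapply(sp, function(s) if (length(s) > 1) stats::sd(s) else NA_real_,
                numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' @export
summary.ataxic <- function(object, ...) {
  out <- summarize_scores(object$scores)
  class(out) <- c("summary.ataxic", "data.frame")
  out
}

#' @export
print.summary.ataxic <- function(x, ...) {
  cat("Per-group ATAXIC score summary (variation = max - min):\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.ataxic <- function(x, ...) x$scores

#' @export
plot.ataxic <- function(x, ...) {
  boxplot(score ~ sample_id, data = x$scores,
          xlab = "sample", ylab = "ATAXIC score", las = 2, ...)
  invisible(x)
}
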