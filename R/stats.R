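# Association statistics: Spearman correlation (average ranks for ties;
# exact permutation p for n <= 9 without ties, t approximation otherwise),
# Benjamini-Hochberg FDR, one-tailed Mann-Whitney U (exact enumeration for
# small untied problems, tie-corrected normal approximation otherwise),
# Shapiro-Wilk normality annotation, and the per-compound viability screen.

# All permutations of 1..n as rows. Only invoked for n <= 9 (362,880 rows).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- setdiff(seq_len(n), i)
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation using average ranks for ties. The two-sided p-value is
#' computed by exact enumeration of the permutation null for n <= 9 when
#' neither vector is tied (the only regime where the S = sum(d^2) shortcut
#' is valid), and by the t approximation with n - 2 degrees of freedom
#' otherwise.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, all finite.
#' @return List with `rho`, `p`, `n`, and `note` (NA, or the reason the
#'   record is flagged: a constant input leaves rho undefined, reported as a
#'   flagged record rather than a number).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) err_validate("x and y must have equal length")
  n <- length(x)
  if (n < 3) err_validate("Spearman correlation needs n >= 3")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    err_validate("Spearman inputs must be finite; remove missing values first")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    return(list(rho = NA_real_, p = NA_real_, n = n, note = "constant input"))
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tied <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  if (n <= 9 && !tied) {
    perms <- all_perms(n)
    s_obs <- sum((rx - ry)^2)
    s_all <- rowSums((perms - rep(seq_len(n), each = nrow(perms)))^2)
    rho_all <- 1 - 6 * s_all / (n * (n^2 - 1))
    p <- mean(abs(rho_all) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = min(p, 1), n = n, note = NA_character_)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment (monotone, capped at 1), in input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1))
    err_validate("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Per-group Spearman correlations with shared FDR adjustment
#'
#' Correlates two per-cell score tables (e.g. ATAXIC scores against a
#' signature's enrichment scores) within each group, then applies
#' Benjamini-Hochberg adjustment across the groups of this call. Records
#' flagged for constant input or fewer than 3 shared cells are excluded from
#' the adjustment (their adjusted p is NA).
#'
#' @param scores data.frame with columns `cell_id`, `score` (e.g. an ATAXIC
#'   score table).
#' @param covariate data.frame with columns `cell_id`, `score` (the
#'   covariate, e.g. signature enrichment).
#' @param grouping Character vector of group labels named by cell id, or
#'   NULL to group by the `sample_id` column of `scores`.
#' @param fdr_scope `"within_call"` (default) adjusts across this call's
#'   groups; `"none"` leaves `p_adj` NA so the caller can pool tests from
#'   several calls before adjusting.
#' @return data.frame with columns `group_id`, `n`, `rho`, `p_raw`, `p_adj`,
#'   `significance` (star annotation: `***` FDR < 0.001, `**` < 0.01, `*`
#'   < 0.05, `ns` otherwise) and `note`.
#' @export
correlate_by_group <- function(scores, covariate, grouping = NULL,
                               fdr_scope = c("within_call", "none")) {
  fdr_scope <- match.arg(fdr_scope)
  shared <- intersect(scores$cell_id, covariate$cell_id)
  if (!length(shared)) err_validate("score and covariate tables share no cells")
  if (is.null(grouping)) {
    if (!"sample_id" %in% names(scores))
      err_validate("no grouping given and the score table has no sample_id column")
    grouping <- stats::setNames(scores$sample_id, scores$cell_id)
  }
  xs <- stats::setNames(scores$score, scores$cell_id)[shared]
  ys <- stats::setNames(covariate$score, covariate$cell_id)[shared]
  gs <- grouping[shared]
  recs <- lapply(unique(gs[!is.na(gs)]), function(g) {
    cid <- shared[which(gs == g)]
    if (length(cid) < 3)
      return(data.frame(group_id = g, n = length(cid), rho = NA_real_,
                        p_raw = NA_real_, note = "fewer than 3 shared cells",
                        stringsAsFactors = FALSE))
    r <- spearman_cor(xs[cid], ys[cid])
    data.frame(group_id = g, n = r$n, rho = r$rho, p_raw = r$p, note = r$note,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p_raw)
  if (fdr_scope == "within_call" && any(ok))
    out$p_adj[ok] <- bh_adjust(out$p_raw[ok])
  out$significance <- ifelse(is.na(out$p_adj), NA_character_,
                      ifelse(out$p_adj < 0.001, "***",
                      ifelse(out$p_adj < 0.01, "**",
                      ifelse(out$p_adj < 0.05, "*", "ns"))))
  out[, c("group_id", "n", "rho", "p_raw", "p_adj", "significance", "note")]
}

#' One-tailed Mann-Whitney U test
#'
#' U is the number of (a, b) pairs with a > b, counting ties as 1/2. The
#' one-tailed p-value is computed by exact enumeration over all rank
#' assignments when `n_a * n_b <= 100` and there are no ties across the
#' pooled sample, and by the tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param direction The alternative hypothesis: `"a_greater"` (a tends to
#'   exceed b) or `"a_less"`.
#' @return List with `u` (the U statistic for group a), `p`, `n_a`, `n_b`,
#'   `direction` and `method` ("exact" or "normal_approx").
#' @export
mann_whitney_one_tailed <- function(a, b, direction = c("a_greater", "a_less")) {
  direction <- match.arg(direction)
  if (!length(a) || !length(b)) err_validate("both groups must be non-empty")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    err_validate("inputs must be finite")
  n_a <- length(a)
  n_b <- length(b)
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  tied <- anyDuplicated(pooled) > 0
  if (!tied && n_a * n_b <= 100) {
    idx <- utils::combn(n_a + n_b, n_a)
    u_all <- colSums(matrix(r[idx], nrow = n_a)) - n_a * (n_a + 1) / 2
    p <- if (direction == "a_greater") mean(u_all >= u - 1e-9)
         else mean(u_all <= u + 1e-9)
    method <- "exact"
  } else {
    n <- n_a + n_b
    ties <- table(pooled)
    mu <- n_a * n_b / 2
    sigma <- sqrt(n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1))))
    z <- if (direction == "a_greater") (u - mu - 0.5) / sigma
         else (u - mu + 0.5) / sigma
    p <- if (direction == "a_greater") stats::pnorm(z, lower.tail = FALSE)
         else stats::pnorm(z)
    method <- "normal_approx"
  }
  list(u = u, p = min(max(p, 0), 1), n_a = n_a, n_b = n_b,
       direction = direction, method = method)
}

#' Shapiro-Wilk normality check
#'
#' Annotation-only wrapper: per-cell heterogeneity scores are usually
#' non-Gaussian, which motivates rank-based tests; the check records this
#' but never switches methods silently.
#'
#' @param x Numeric vector, 3 <= n <= 5000.
#' @return List with `statistic` (W) and `p`.
#' @export
shapiro_check <- function(x) {
  n <- length(x[is.finite(x)])
  if (n < 3 || n > 5000)
    err_validate("Shapiro-Wilk check needs 3 <= n <= 5000")
  sw <- stats::shapiro.test(x[is.finite(x)])
  list(statistic = unname(sw$statistic), p = sw$p.value)
}

#' Compound-sensitivity correlation screen
#'
#' For each compound, Spearman-correlates per-line heterogeneity scores with
#' viability over the cell lines that have both values (pairwise deletion of
#' missing viability), applies Benjamini-Hochberg adjustment across all
#' tested compounds, and counts significant positive and negative
#' correlations at the FDR threshold. A positive correlation means higher
#' heterogeneity accompanies higher viability under treatment, i.e. lower
#' drug sensitivity.
#'
#' @param cell_line_scores data.frame with columns `cell_id` (cell-line id)
#'   and `score`.
#' @param viability Numeric matrix, compounds in rows and cell lines in
#'   columns (NA = not measured).
#' @param fdr_threshold Significance threshold on the adjusted p; default
#'   0.05.
#' @return List of class `drug_screen` with `records` (per-compound
#'   data.frame: `compound`, `n`, `rho`, `p_raw`, `p_adj`, `note`),
#'   `n_significant_positive`, `n_significant_negative`, `fdr_threshold`,
#'   and `skipped` (compounds with fewer than 3 shared lines, with reasons).
#' @export
drug_screen <- function(cell_line_scores, viability, fdr_threshold = 0.05) {
  if (!all(c("cell_id", "score") %in% names(cell_line_scores)))
    err_validate("cell_line_scores needs columns cell_id and score")
  if (!is.matrix(viability) || is.null(rownames(viability)) || is.null(colnames(viability)))
    err_validate("viability must be a compounds x lines matrix with dimnames")
  sc <- stats::setNames(cell_line_scores$score, cell_line_scores$cell_id)
  lines <- intersect(names(sc), colnames(viability))
  recs <- list(); skipped <- list()
  for (cmp in rownames(viability)) {
    vi <- viability[cmp, lines]
    ok <- is.finite(vi) & is.finite(sc[lines])
    if (sum(ok) < 3) {
      skipped[[cmp]] <- data.frame(compound = cmp, n = sum(ok),
                                   reason = "fewer than 3 shared lines",
                                   stringsAsFactors = FALSE)
      next
    }
    r <- spearman_cor(sc[lines][ok], vi[ok])
    recs[[cmp]] <- data.frame(compound = cmp, n = r$n, rho = r$rho,
                              p_raw = r$p, note = r$note, stringsAsFactors = FALSE)
  }
  if (!length(recs))
    err_validate("no compound has >= 3 cell lines shared with the score table")
  records <- do.call(rbind, c(recs, list(make.row.names = FALSE)))
  records$p_adj <- NA_real_
  ok <- !is.na(records$p_raw)
  records$p_adj[ok] <- bh_adjust(records$p_raw[ok])
  sig <- ok & records$p_adj < fdr_threshold
  out <- list(records = records[, c("compound", "n", "rho", "p_raw", "p_adj", "note")],
              n_significant_positive = sum(sig & records$rho > 0),
              n_significant_negative = sum(sig & records$rho < 0),
              fdr_threshold = fdr_threshold,
              skipped = if (length(skipped))
                do.call(rbind, c(skipped, list(make.row.names = FALSE)))
              else NULL)
  class(out) <- "drug_screen"
  out
}

#' @export
print.drug_screen <- function(x, ...) {
  cat(sprintf("drug screen: %d compound(s) tested, %d skipped\n",
              nrow(x$records), if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  cat(sprintf("  FDR < %g: %d positive, %d negative correlations\n",
              x$fdr_threshold, x$n_significant_positive, x$n_significant_negative))
  invisible(x)
}
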