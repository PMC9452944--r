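# Quality-control filters and normalization, applied in the order:
# low-complexity cells, high-mitochondrial cells, small samples, log2(TPM+1).
# All thresholds are strict inequalities exactly as worded ("smaller than
# 300", "larger than 10 percent", "less than ten cells"). "Expressed" means
# value strictly > 0: TPM matrices are non-negative and zero means
# undetected. Mitochondrial fractions are computed on the raw linear scale,
# where percent-of-expression is meaningful.

qc_step <- function(step, kind, removed, before, after, note = NA_character_) {
  data.frame(step = step, entity = kind, removed = removed,
             genes_in = before[1], cells_in = before[2], samples_in = before[3],
             genes_out = after[1], cells_out = after[2], samples_out = after[3],
             note = note, stringsAsFactors = FALSE)
}

em_dims <- function(x) c(n_genes(x), n_cells(x), length(unique(x$samples)))

as_qc_report <- function(df) {
  class(df) <- c("qc_report", "data.frame")
  df
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report:\n")
  print.data.frame(x)
  invisible(x)
}

check_any_kept <- function(keep, step) {
  if (!any(keep))
    err_empty(sprintf("QC step '%s' removed every remaining cell", step))
  keep
}

#' Remove low-complexity cells
#'
#' Discards cells whose number of expressed genes (value strictly greater
#' than zero) is smaller than `min_genes`. A cell expressing exactly
#' `min_genes` genes is retained.
#'
#' @param mat A raw [expression_matrix()].
#' @param min_genes Minimum number of expressed genes; default 300.
#' @return List with elements `matrix` (filtered `expr_matrix`) and `report`
#'   (a `qc_report` data.frame).
#' @export
filter_low_complexity_cells <- function(mat, min_genes = 300) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$norm_state != "raw")
    err_state("cell QC filters operate on raw (pre-log) matrices")
  before <- em_dims(mat)
  expressed <- colSums(mat$values > 0)
  keep <- check_any_kept(expressed >= min_genes, "low_complexity_cells")
  out <- em_subset_cells(mat, keep)
  list(matrix = out,
       report = as_qc_report(qc_step("low_complexity_cells", "cell",
                                     sum(!keep), before, em_dims(out))))
}

#' Remove cells with high mitochondrial expression
#'
#' Discards cells whose mitochondrial share of total expression is larger
#' than `max_frac`; a cell at exactly `max_frac` is retained. Cells with zero
#' total expression (for which the fraction is undefined) are removed under a
#' distinct reason code. If the pattern matches no gene, a warning is
#' recorded in the report and no cells are removed by this step.
#'
#' @param mat A raw [expression_matrix()].
#' @param max_frac Maximum mitochondrial fraction; default 0.10.
#' @param mito_pattern Regular expression identifying mitochondrial genes;
#'   default the conventional `"^MT-"` symbol prefix.
#' @param ignore_case Match the pattern case-insensitively (default TRUE,
#'   since symbol casing varies between annotation sources).
#' @return List with `matrix` and `report`, as in
#'   [filter_low_complexity_cells()].
#' @export
filter_high_mito_cells <- function(mat, max_frac = 0.10, mito_pattern = "^MT-",
                                   ignore_case = TRUE) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$norm_state != "raw")
    err_state("mitochondrial fractions are computed on raw (pre-log) values")
  before <- em_dims(mat)
  mito <- grepl(mito_pattern, rownames(mat$values), ignore.case = ignore_case)
  if (!any(mito)) {
    warning(sprintf("mito pattern '%s' matches no gene; no cells removed", mito_pattern))
    rep <- qc_step("high_mito_cells", "cell", 0L, before, before,
                   note = sprintf("pattern '%s' matched 0 genes", mito_pattern))
    return(list(matrix = mat, report = as_qc_report(rep)))
  }
  total <- colSums(mat$values)
  zero_total <- total == 0
  frac <- ifelse(zero_total, NA_real_, colSums(mat$values[mito, , drop = FALSE]) / total)
  high <- !zero_total & frac > max_frac
  keep <- check_any_kept(!high & !zero_total, "high_mito_cells")
  out <- em_subset_cells(mat, keep)
  rep <- rbind(
    qc_step("high_mito_cells", "cell", sum(high), before,
            c(before[1], before[2] - sum(high), before[3])),
    qc_step("zero_total_expression", "cell", sum(zero_total),
            c(before[1], before[2] - sum(high), before[3]), em_dims(out))
  )
  list(matrix = out, report = as_qc_report(rep))
}

#' Remove samples with too few cells
#'
#' Discards every cell of any sample (patient) with fewer than `min_cells`
#' cells; a sample with exactly `min_cells` cells is retained.
#'
#' @param mat An [expression_matrix()] (any normalization state).
#' @param min_cells Minimum cells per sample; default 10.
#' @return List with `matrix` and `report`.
#' @export
filter_small_samples <- function(mat, min_cells = 10) {
  stopifnot(inherits(mat, "expr_matrix"))
  before <- em_dims(mat)
  counts <- table(mat$samples)
  small <- names(counts)[counts < min_cells]
  keep <- check_any_kept(!(mat$samples %in% small), "small_samples")
  out <- em_subset_cells(mat, keep)
  # two rows so that summing the cell-entity rows always reproduces the
  # total number of cells removed across the report
  rep <- rbind(
    qc_step("small_samples", "sample", length(small), before, em_dims(out)),
    qc_step("small_samples", "cell", sum(!keep), before, em_dims(out),
            note = "cells removed with their sample"))
  list(matrix = out, report = as_qc_report(rep))
}

#' Normalize a raw TPM-like matrix to log2(TPM+1)
#'
#' Replaces every value v by log2(v + 1) and flips the normalization state to
#' `"log2p1"`. Applying it to an already-normalized matrix is an error.
#'
#' @param mat A raw [expression_matrix()].
#' @return The normalized `expr_matrix`.
#' @export
normalize_log2 <- function(mat) {
  stopifnot(inherits(mat, "expr_matrix"))
  if (mat$norm_state != "raw")
    err_state("matrix is already log2(TPM+1)-normalized")
  expression_matrix(log2(mat$values + 1), mat$samples, norm_state = "log2p1")
}

#' Run the full quality-control and normalization pipeline
#'
#' Applies, in order: the low-complexity cell filter, the mitochondrial
#' fraction filter, the per-sample minimum-cell filter, and (optionally)
#' log2(TPM+1) normalization. Cell-level filters run before the per-sample
#' filter so that a sample is judged on the cells that survive cell QC.
#'
#' @param mat A raw [expression_matrix()].
#' @param min_genes,max_mito_frac,mito_pattern,min_cells Filter parameters;
#'   see the individual filter functions.
#' @param normalize Apply [normalize_log2()] at the end (default TRUE).
#' @return List with `matrix` (the filtered, optionally normalized
#'   `expr_matrix`) and `report` (concatenated `qc_report`).
#' @export
run_qc_pipeline <- function(mat, min_genes = 300, max_mito_frac = 0.10,
                            mito_pattern = "^MT-", min_cells = 10,
                            normalize = TRUE) {
  s1 <- filter_low_complexity_cells(mat, min_genes = min_genes)
  s2 <- withCallingHandlers(
    filter_high_mito_cells(s1$matrix, max_frac = max_mito_frac,
                           mito_pattern = mito_pattern),
    warning = function(w) invokeRestart("muffleWarning"))
  s3 <- filter_small_samples(s2$matrix, min_cells = min_cells)
  out <- if (normalize) normalize_log2(s3$matrix) else s3$matrix
  list(matrix = out,
       report = as_qc_report(rbind(s1$report, s2$report, s3$report)))
}
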