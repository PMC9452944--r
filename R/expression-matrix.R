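#' Construct a validated expression matrix
#'
#' The central container of the package: a genes x cells matrix of expression
#' values together with a cell-to-sample (patient) mapping and a normalization
#' state flag. Raw matrices are expected to be TPM or TPM-like (non-negative);
#' after [normalize_log2()] the state becomes `"log2p1"`.
#'
#' @param values Numeric matrix, genes in rows and cells in columns, with
#'   unique rownames (gene ids) and colnames (cell ids). All values must be
#'   finite; raw matrices must be non-negative.
#' @param samples Cell-to-sample mapping: either a character vector named by
#'   cell id, a two-column data.frame (`cell_id`, `sample_id`), or `NULL`, in
#'   which case each cell is treated as its own sample. When a mapping is
#'   supplied it must cover every cell; unlabeled cells are rejected rather
#'   than silently defaulted.
#' @param norm_state `"raw"` (TPM-like, linear scale) or `"log2p1"`
#'   (log2(TPM+1)).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `samples` (character vector named by cell id) and `norm_state`.
#' @examples
#' v <- matrix(c(1, 2, 3, 2, 2, 2, 0, 1, 5), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("G1", "G2", "G3"), c("c1", "c2", "c3")))
#' em <- expression_matrix(v)
#' em
#' @export
expression_matrix <- function(values, samples = NULL,
                              norm_state = c("raw", "log2p1")) {
  norm_state <- match.arg(norm_state)
  if (!is.matrix(values) || !is.numeric(values))
    err_validate("'values' must be a numeric matrix (genes x cells)")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    err_validate("'values' must carry gene ids as rownames and cell ids as colnames")
  gene_ids <- rownames(values)
  cell_ids <- colnames(values)
  if (anyDuplicated(gene_ids))
    err_validate(sprintf("duplicate gene id(s): %s",
                         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", ")))
  if (anyDuplicated(cell_ids))
    err_validate(sprintf("duplicate cell id(s): %s",
                         paste(unique(cell_ids[duplicated(cell_ids)]), collapse = ", ")))
  if (any(!is.finite(values)))
    err_validate("expression values must all be finite (no NA/NaN/Inf)")
  if (norm_state == "raw" && any(values < 0))
    err_validate("raw (TPM-like) expression values must be non-negative")

  samples <- resolve_samples(samples, cell_ids)
  structure(list(values = values, samples = samples, norm_state = norm_state),
            class = "expr_matrix")
}

resolve_samples <- function(samples, cell_ids) {
  if (is.null(samples)) {
    out <- cell_ids
    names(out) <- cell_ids
    return(out)
  }
  if (is.data.frame(samples)) {
    if (ncol(samples) < 2)
      err_validate("sample label table must have two columns (cell_id, sample_id)")
    out <- as.character(samples[[2]])
    names(out) <- as.character(samples[[1]])
    samples <- out
  }
  if (!is.character(samples) || is.null(names(samples)))
    err_validate("'samples' must be a character vector named by cell id")
  if (anyDuplicated(names(samples)))
    err_validate("sample label table assigns a cell id more than once")
  missing <- setdiff(cell_ids, names(samples))
  if (length(missing))
    err_validate(sprintf("%d cell(s) have no sample label (e.g. %s); unlabeled cells are rejected",
                         length(missing), missing[1]))
  samples[cell_ids]
}

n_genes <- function(x) nrow(x$values)
n_cells <- function(x) ncol(x$values)

# Keep a subset of cells (logical or index vector over columns), preserving
# order and the sample mapping.
em_subset_cells <- function(x, keep) {
  v <- x$values[, keep, drop = FALSE]
  expression_matrix(v, x$samples[colnames(v)], norm_state = x$norm_state)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d cells, %d sample(s), state=%s\n",
              n_genes(x), n_cells(x), length(unique(x$samples)), x$norm_state))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
as.matrix.expr_matrix <- function(x, ...) x$values

#' Construct a gene set
#'
#' @param name Non-empty set name.
#' @param genes Character vector of gene identifiers; duplicates are removed
#'   (first occurrence kept). Must be non-empty after deduplication.
#' @return An object of class `gene_set` with elements `name` and `genes`.
#' @export
gene_set <- function(name, genes) {
  if (!is.character(name) || length(name) != 1 || !nzchar(name))
    err_validate("gene set name must be a non-empty string")
  genes <- unique(as.character(genes))
  genes <- genes[nzchar(genes)]
  if (!length(genes))
    err_validate(sprintf("gene set '%s' has no genes", name))
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("gene_set '%s': %d genes\n", x$name, length(x$genes)))
  invisible(x)
}
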