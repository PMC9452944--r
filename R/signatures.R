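# Signature enrichment: the enrichment score of a gene set in a cell is the
# arithmetic mean of the cell's expression over the set's genes present in
# the matrix. Missing genes are handled by intersection, not zero-imputation,
# and matching is exact and case-sensitive by default (a case-insensitive
# fallback exists because symbol casing differs between annotation sources).

match_set_genes <- function(gs, gene_ids, ignore_case = FALSE) {
  if (ignore_case) {
    hit <- match(toupper(gs$genes), toupper(gene_ids))
    matched <- hit[!is.na(hit)]
    unmatched <- gs$genes[is.na(hit)]
  } else {
    hit <- match(gs$genes, gene_ids)
    matched <- hit[!is.na(hit)]
    unmatched <- gs$genes[is.na(hit)]
  }
  list(idx = matched, unmatched = unmatched)
}

#' Per-cell enrichment score of one gene set
#'
#' Scores each cell by the mean expression of the gene set's members present
#' in the matrix.
#'
#' @param mat An [expression_matrix()]; by convention the log2(TPM+1) matrix
#'   used for ATAXIC scoring.
#' @param gs A [gene_set()].
#' @param ignore_case Match gene identifiers case-insensitively (default
#'   FALSE: exact, case-sensitive matching).
#' @return data.frame with columns `cell_id`, `sample_id`, `score`, carrying
#'   attributes `signature` (set name), `n_matched` (intersection size) and
#'   `unmatched_genes`.
#' @export
enrichment_scores <- function(mat, gs, ignore_case = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"), inherits(gs, "gene_set"))
  mm <- match_set_genes(gs, rownames(mat$values), ignore_case = ignore_case)
  if (!length(mm$idx))
    err_validate(sprintf("gene set '%s' shares no genes with the matrix", gs$name))
  sub <- mat$values[mm$idx, , drop = FALSE]
  out <- data.frame(cell_id = colnames(mat$values),
                    sample_id = unname(mat$samples),
                    score = unname(colMeans(sub)),
                    stringsAsFactors = FALSE)
  attr(out, "signature") <- gs$name
  attr(out, "n_matched") <- length(mm$idx)
  attr(out, "unmatched_genes") <- mm$unmatched
  out
}

#' Per-cell enrichment scores for a collection of gene sets
#'
#' One column per gene set; sets sharing no genes with the matrix are skipped
#' with a warning, and duplicated set names are deterministically suffixed
#' (`.2`, `.3`, ...).
#'
#' @inheritParams enrichment_scores
#' @param sets List of [gene_set()] objects (e.g. from [read_gmt()]).
#' @return data.frame with columns `cell_id`, `sample_id`, then one score
#'   column per retained set.
#' @export
score_all_signatures <- function(mat, sets, ignore_case = FALSE) {
  stopifnot(inherits(mat, "expr_matrix"))
  nm <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(nm)) {
    warning("duplicated gene set name(s) suffixed deterministically")
    nm <- make.unique(nm, sep = ".")
  }
  cols <- list()
  for (i in seq_along(sets)) {
    res <- tryCatch(enrichment_scores(mat, sets[[i]], ignore_case = ignore_case),
                    ataxic_validation_error = function(e) NULL)
    if (is.null(res)) {
      warning(sprintf("gene set '%s' shares no genes with the matrix; skipped",
                      sets[[i]]$name))
      next
    }
    cols[[nm[i]]] <- res$score
  }
  if (!length(cols))
    err_validate("no gene set shares any gene with the matrix")
  out <- data.frame(cell_id = colnames(mat$values),
                    sample_id = unname(mat$samples),
                    stringsAsFactors = FALSE)
  for (n in names(cols)) out[[n]] <- cols[[n]]
  out
}
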