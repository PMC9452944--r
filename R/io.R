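# Readers and writers for the on-disk formats the toolkit touches:
# dense TSV/CSV matrices, MatrixMarket triplets, GMT gene sets, two-column
# sample label tables, and TSV score tables. All reader/writer pairs are
# lossless round trips; readers never reorder genes or cells.

sep_for <- function(path) if (grepl("\\.csv(\\.gz)?$", path)) "," else "\t"

# Internal: read a dense numeric matrix with one id column and a header row,
# without any expr_matrix validation (used for viability tables too, which
# may hold negatives and NAs).
read_numeric_grid <- function(path, what = "matrix", allow_na = FALSE) {
  if (!file.exists(path)) err_parse(sprintf("file not found: %s", path))
  if (file.size(path) == 0) err_parse(sprintf("empty file: %s", path))
  dt <- tryCatch(
    data.table::fread(path, header = TRUE, sep = sep_for(path),
                      data.table = FALSE, colClasses = list(character = 1)),
    error = function(e) err_parse(sprintf("cannot parse %s: %s", path, conditionMessage(e)))
  )
  if (ncol(dt) < 2)
    err_parse(sprintf("%s: expected an id column plus at least one data column", path))
  ids <- as.character(dt[[1]])
  for (j in seq(2, ncol(dt))) {
    col <- dt[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      row <- if (length(bad)) bad[1] else which(is.na(as.numeric(col)))[1]
      err_parse(sprintf("%s: malformed numeric value at row '%s', column '%s'",
                        path, ids[row], colnames(dt)[j]))
    }
    if (!allow_na && anyNA(col)) {
      row <- which(is.na(col))[1]
      err_parse(sprintf("%s: missing value at row '%s', column '%s'",
                        path, ids[row], colnames(dt)[j]))
    }
  }
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- ids
  m
}

#' Read a dense expression matrix from TSV/CSV
#'
#' Expects one header row of ids and one leading id column. The field
#' separator is taken from the extension (`.csv` means comma, anything else
#' tab).
#'
#' @param path Path to the matrix file.
#' @param orientation `"genes"` if genes are in rows (the default and the
#'   conventional layout for scRNA-seq TPM matrices) or `"cells"` if cells
#'   are in rows, in which case the matrix is transposed after reading. The
#'   flag is explicit because silent transposition is the classic failure
#'   mode with dense expression tables.
#' @param labels Optional path to a two-column TSV (`cell_id`, `sample_id`)
#'   assigning each cell to a sample/patient; see [read_labels()]. Without
#'   it each cell is its own sample.
#' @return An [expression_matrix()] with `norm_state = "raw"`.
#' @export
read_dense_matrix <- function(path, orientation = c("genes", "cells"),
                              labels = NULL) {
  orientation <- match.arg(orientation)
  m <- read_numeric_grid(path)
  if (orientation == "cells") m <- t(m)
  samples <- if (is.null(labels)) NULL else read_labels(labels)
  expression_matrix(m, samples = samples, norm_state = "raw")
}

#' Write a dense expression matrix as TSV/CSV
#'
#' @param mat An `expr_matrix` or plain numeric matrix with dimnames.
#' @param path Output path; `.csv` selects comma separation.
#' @param id_col Name of the leading identifier column in the header.
#' @export
write_dense_matrix <- function(mat, path, id_col = "gene_id") {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  sep <- sep_for(path)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c(id_col, colnames(v)), collapse = sep), con)
  body <- vapply(seq_len(nrow(v)), function(i) {
    paste(c(rownames(v)[i], sprintf("%.17g", v[i, ])), collapse = sep)
  }, character(1))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Read a cell-to-sample label table
#'
#' Two-column TSV with header (`cell_id`, `sample_id`).
#'
#' @param path Path to the label file.
#' @return Character vector of sample ids named by cell id.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) err_parse(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE,
                          colClasses = "character")
  if (ncol(dt) < 2)
    err_parse(sprintf("%s: label table needs two columns (cell_id, sample_id)", path))
  out <- as.character(dt[[2]])
  names(out) <- as.character(dt[[1]])
  if (anyDuplicated(names(out)))
    err_validate(sprintf("%s: duplicate cell id(s) in label table", path))
  out
}

#' Write a cell-to-sample label table
#' @param samples Character vector of sample ids named by cell id.
#' @param path Output TSV path.
#' @export
write_labels <- function(samples, path) {
  utils::write.table(
    data.frame(cell_id = names(samples), sample_id = unname(samples)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a MatrixMarket triplet matrix with feature and barcode files
#'
#' The standard three-file layout of sparse single-cell matrices: a
#' coordinate-format `.mtx` (1-based indices per the MatrixMarket standard)
#' plus one-id-per-line feature (gene) and barcode (cell) files. Entries
#' absent from the triplet list are zero.
#'
#' @param matrix_path Path to the `.mtx` file.
#' @param features_path Path to the gene id file (one id per line; if the
#'   lines are tab-separated, the first field is used).
#' @param barcodes_path Path to the cell id file.
#' @param labels Optional label-table path, as in [read_dense_matrix()].
#' @return An [expression_matrix()] with `norm_state = "raw"`.
#' @export
read_mtx_triplet <- function(matrix_path, features_path, barcodes_path,
                             labels = NULL) {
  for (p in c(matrix_path, features_path, barcodes_path))
    if (!file.exists(p)) err_parse(sprintf("file not found: %s", p))
  sm <- tryCatch(Matrix::readMM(matrix_path),
                 error = function(e) err_parse(sprintf("cannot parse %s: %s",
                                                       matrix_path, conditionMessage(e))))
  feats <- vapply(strsplit(readLines(features_path), "\t", fixed = TRUE),
                  `[[`, character(1), 1)
  cells <- vapply(strsplit(readLines(barcodes_path), "\t", fixed = TRUE),
                  `[[`, character(1), 1)
  if (length(feats) != nrow(sm))
    err_validate(sprintf("feature file has %d ids but MTX header declares %d rows",
                         length(feats), nrow(sm)))
  if (length(cells) != ncol(sm))
    err_validate(sprintf("barcode file has %d ids but MTX header declares %d columns",
                         length(cells), ncol(sm)))
  v <- as.matrix(sm)
  dimnames(v) <- list(feats, cells)
  samples <- if (is.null(labels)) NULL else read_labels(labels)
  expression_matrix(v, samples = samples, norm_state = "raw")
}

#' Write a matrix as MatrixMarket triplet plus feature/barcode files
#'
#' @param mat An `expr_matrix` or numeric matrix with dimnames.
#' @param matrix_path,features_path,barcodes_path Output paths.
#' @export
write_mtx_triplet <- function(mat, matrix_path, features_path, barcodes_path) {
  v <- if (inherits(mat, "expr_matrix")) mat$values else mat
  Matrix::writeMM(methods::as(Matrix::Matrix(v, sparse = TRUE), "TsparseMatrix"),
                  matrix_path)
  writeLines(rownames(v), features_path)
  writeLines(colnames(v), barcodes_path)
  invisible(matrix_path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: per line a set name, a description (ignored), then gene ids,
#' tab-separated. Duplicate genes within a line are deduplicated.
#'
#' @param path Path to the GMT file.
#' @return Named list of [gene_set()] objects, in file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) err_parse(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) err_parse(sprintf("empty GMT file: %s", path))
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      err_validate(sprintf("%s line %d: GMT lines need name, description and >=1 gene",
                           path, i))
    sets[[i]] <- gene_set(fields[1], fields[-(1:2)])
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  sets
}

#' Write gene sets to a GMT file
#' @param sets List of `gene_set` objects.
#' @param path Output path.
#' @param description Description field written for every set.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a per-cell score table as TSV
#'
#' Columns `cell_id`, `sample_id`, `score`; values are written with enough
#' digits that a read-back reproduces them to 1e-12.
#'
#' @param table data.frame with columns `cell_id`, `sample_id`, `score`.
#' @param path Output path.
#' @export
write_score_table <- function(table, path) {
  need <- c("cell_id", "sample_id", "score")
  if (!all(need %in% names(table)))
    err_validate("score table needs columns cell_id, sample_id, score")
  con <- tryCatch(file(path, "w"),
                  error = function(e) ax_stop(sprintf("cannot open %s for writing", path),
                                              "ataxic_io_error"))
  on.exit(close(con))
  writeLines("cell_id\tsample_id\tscore", con)
  if (nrow(table))
    writeLines(sprintf("%s\t%s\t%.17g", table$cell_id, table$sample_id, table$score), con)
  invisible(path)
}

#' Read a per-cell score table written by [write_score_table()]
#' @param path Path to the TSV.
#' @return data.frame with columns `cell_id`, `sample_id`, `score`.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) err_parse(sprintf("file not found: %s", path))
  dt <- data.table::fread(path, header = TRUE, sep = "\t", data.table = FALSE)
  if (!all(c("cell_id", "sample_id", "score") %in% names(dt)))
    err_parse(sprintf("%s: not a score table (need cell_id, sample_id, score)", path))
  dt$cell_id <- as.character(dt$cell_id)
  dt$sample_id <- as.character(dt$sample_id)
  dt$score <- as.numeric(dt$score)
  dt
}
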