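# End-to-end pipeline: load or simulate a cohort, run QC and normalization,
# score cells, score signatures, and correlate scores with each signature
# per sample. Every output TSV carries a provenance header (tool version,
# config hash, seed) and no timestamps, so reruns with the same config are
# byte-identical.

provenance_lines <- function(cfg) {
  c(sprintf("# ataxic_version=%s", as.character(utils::packageVersion("ataxic"))),
    sprintf("# config_md5=%s", config_hash(cfg)),
    sprintf("# seed=%s", if (is.null(cfg$seed)) "NA" else cfg$seed))
}

config_hash <- function(cfg) {
  # hash the scientific configuration only; the output location is not part
  # of the result's identity
  cfg <- cfg[setdiff(names(cfg), "outdir")]
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(cfg[order(names(cfg))]), tmp)
  unname(tools::md5sum(tmp))
}

write_tsv_with_provenance <- function(df, path, cfg, digits_cols = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_lines(cfg), con)
  for (nm in names(df))
    if (is.numeric(df[[nm]]) && !is.integer(df[[nm]]))
      df[[nm]] <- sprintf("%.17g", df[[nm]])
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df))
    writeLines(do.call(paste, c(unname(df), sep = "\t")), con)
  invisible(path)
}

default_run_config <- function() {
  list(seed = 1L, outdir = "ataxic_out",
       input = NULL, labels = NULL, gmt = NULL, simulate = NULL,
       qc = list(min_genes = 300, max_mito_frac = 0.10, mito_pattern = "^MT-",
                 min_cells = 10, normalize = TRUE),
       score = list(scope = "sample"),
       correlate = list(fdr_scope = "within_call"))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

load_run_config <- function(config) {
  cfg <- default_run_config()
  if (is.character(config)) {
    if (!file.exists(config)) err_usage(sprintf("config file not found: %s", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.null(config)) cfg <- merge_config(cfg, config)
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$input))
      err_usage("config must provide either 'input' (matrix path) or 'simulate'")
    if (!file.exists(cfg$input))
      err_usage(sprintf("input matrix not found: %s", cfg$input))
    if (!is.null(cfg$labels) && !file.exists(cfg$labels))
      err_usage(sprintf("label file not found: %s", cfg$labels))
  }
  if (!is.null(cfg$gmt) && !file.exists(cfg$gmt))
    err_usage(sprintf("GMT file not found: %s", cfg$gmt))
  cfg
}

#' Run the full workflow: QC, scoring, enrichment, correlation
#'
#' Stages, in order: load (or simulate) a raw cohort; QC + log2(TPM+1)
#' normalization; per-cell heterogeneity scoring; per-cell signature
#' enrichment for every gene set; per-sample Spearman correlation of the
#' heterogeneity score against each signature with Benjamini-Hochberg
#' adjustment within each signature. All tables are written under `outdir`
#' with a provenance header; reruns with the same config are byte-identical.
#'
#' @param config Either a path to a YAML config file or a config list.
#'   Recognized keys: `seed`, `outdir`, `input` (dense matrix TSV path),
#'   `labels` (cell-to-sample TSV), `gmt` (gene sets), `simulate` (a list of
#'   [sim_config()] arguments; used instead of `input`), `qc` (`min_genes`,
#'   `max_mito_frac`, `mito_pattern`, `min_cells`, `normalize`), `score`
#'   (`scope`), `correlate` (`fdr_scope`).
#' @return Invisibly, a list with `outdir` and the written file paths.
#' @export
run_full_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(cfg$outdir, f)
  written <- character(0)

  message("[load] reading input cohort")
  gene_sets <- NULL
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    if (!is.null(sim_args$signature_modules))
      sim_args$signature_modules <- lapply(sim_args$signature_modules, as.list)
    sim <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(sim)
    raw <- cohort$matrix
    gene_sets <- cohort$gene_sets
    write_tsv_with_provenance(cohort$truth$cells, pth("ground_truth_cells.tsv"), cfg)
    written <- c(written, pth("ground_truth_cells.tsv"))
  } else {
    raw <- read_dense_matrix(cfg$input, labels = cfg$labels)
  }
  if (!is.null(cfg$gmt)) gene_sets <- read_gmt(cfg$gmt)

  message("[qc] filtering and normalizing")
  qc <- run_qc_pipeline(raw,
                        min_genes = cfg$qc$min_genes,
                        max_mito_frac = cfg$qc$max_mito_frac,
                        mito_pattern = cfg$qc$mito_pattern,
                        min_cells = cfg$qc$min_cells,
                        normalize = isTRUE(cfg$qc$normalize))
  write_tsv_with_provenance(as.data.frame(qc$report), pth("qc_report.tsv"), cfg)
  written <- c(written, pth("qc_report.tsv"))

  message("[score] computing heterogeneity scores")
  fit <- ataxic(qc$matrix, scope = cfg$score$scope,
                allow_raw = !isTRUE(cfg$qc$normalize))
  score_df <- fit$scores
  write_tsv_with_provenance(score_df, pth("ataxic_scores.tsv"), cfg)
  write_tsv_with_provenance(summarize_scores(score_df), pth("score_summary.tsv"), cfg)
  dropped <- data.frame(
    group = rep(names(fit$dropped_genes), lengths(fit$dropped_genes)),
    gene_id = unlist(fit$dropped_genes, use.names = FALSE),
    stringsAsFactors = FALSE)
  write_tsv_with_provenance(dropped, pth("dropped_genes.tsv"), cfg)
  written <- c(written, pth("ataxic_scores.tsv"), pth("score_summary.tsv"),
               pth("dropped_genes.tsv"))

  if (!is.null(gene_sets) && length(gene_sets)) {
    message("[enrich] scoring gene sets")
    sig <- suppressWarnings(score_all_signatures(qc$matrix, gene_sets))
    write_tsv_with_provenance(sig, pth("signature_scores.tsv"), cfg)
    written <- c(written, pth("signature_scores.tsv"))

    message("[correlate] score vs signature per sample")
    cors <- lapply(setdiff(names(sig), c("cell_id", "sample_id")), function(nm) {
      cov <- data.frame(cell_id = sig$cell_id, score = sig[[nm]],
                        stringsAsFactors = FALSE)
      out <- correlate_by_group(score_df, cov, fdr_scope = cfg$correlate$fdr_scope)
      out$signature <- nm
      out
    })
    cors <- do.call(rbind, cors)
    cors <- cors[, c("signature", setdiff(names(cors), "signature"))]
    write_tsv_with_provenance(cors, pth("correlations.tsv"), cfg)
    written <- c(written, pth("correlations.tsv"))
  }

  message("[done] outputs in ", cfg$outdir)
  invisible(list(outdir = cfg$outdir, files = written))
}
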