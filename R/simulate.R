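# Synthetic multi-patient scRNA-seq cohorts with known per-cell perturbation
# asynchrony. The generator works on the log2 scale: a fixed per-gene
# baseline plus i.i.d. cell noise, then, for a cell with asynchrony a, a
# random subset of round(perturbed_gene_fraction * a * n_genes) genes
# receives heavy-tailed (Laplace) perturbations. Heavy-tailed, gene-specific
# shifts raise the dispersion of a cell's |z| population, which is exactly
# what the heterogeneity score measures; a uniform shift of all genes would
# be invisible to it (per-gene affine invariance), so the generator must
# perturb asynchronously. Values are exponentiated and rescaled to TPM-like
# columns (fixed column sum) so the log2(TPM+1) path is exercised
# realistically.

rlaplace <- function(n, scale, cap = Inf) {
  u <- stats::runif(n) - 0.5
  x <- -scale * sign(u) * log(1 - 2 * abs(u))
  pmin(pmax(x, -cap), cap)
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_genes Total genes (including mitochondrial ones).
#' @param n_cells_per_sample Integer vector, one entry per sample (patient).
#' @param n_mito_genes Genes given the `MT-` prefix; default 13, the human
#'   mitochondrial protein-coding gene count.
#' @param asynchrony_range Per-cell true asynchrony is drawn uniformly from
#'   this range (in \[0, 1\]); overridden by `asynchrony_values`.
#' @param asynchrony_values Optional explicit per-cell asynchrony vector
#'   (length = total cells).
#' @param perturbed_gene_fraction At asynchrony 1, this fraction of genes is
#'   perturbed; a cell with asynchrony a perturbs
#'   `round(perturbed_gene_fraction * a * n_genes)` genes. Default 0.2.
#' @param perturbation_scale Laplace scale (log2 units) of the per-gene
#'   perturbations; default 2.
#' @param perturbation_cap Truncation bound (log2 units) on individual
#'   perturbations; default 8, i.e. at most a 256-fold change. Untruncated
#'   Laplace tails at scale 2 have infinite linear-scale mean, letting single
#'   draws dominate a cell's TPM column sum, which no real transcriptome
#'   does.
#' @param baseline_log_mean,baseline_log_sd Per-gene baseline log2 expression
#'   is drawn once from N(mean, sd); defaults 3 and 1.5.
#' @param cell_noise_sd SD (log2 units) of the i.i.d. gene x cell noise;
#'   default 0.4.
#' @param signature_modules List of module specs, each a list with `name`,
#'   `size`, and `coupling` in `"positive"`, `"negative"`, `"none"`: the
#'   module's genes are shifted by `+/- module_effect * a` in cells with
#'   asynchrony a. Default: none.
#' @param module_effect Shift (log2 units) at asynchrony 1; default 2.
#' @param low_quality_cell_fraction Fraction of cells rendered low-quality
#'   (all but 30-250 genes zeroed, so they fail the 300-expressed-genes
#'   filter); default 0.
#' @param high_mito_cell_fraction Fraction of cells given an elevated
#'   mitochondrial share (drawn uniformly in 0.15-0.40, above the 10 percent
#'   filter); default 0.
#' @param target_colsum TPM-like column sum; default 1e6.
#' @param seed Mandatory integer seed; generation is fully reproducible.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_cells_per_sample = c(120, 100, 80),
                       n_mito_genes = 13,
                       asynchrony_range = c(0, 1),
                       asynchrony_values = NULL,
                       perturbed_gene_fraction = 0.2,
                       perturbation_scale = 2,
                       perturbation_cap = 8,
                       baseline_log_mean = 3,
                       baseline_log_sd = 1.5,
                       cell_noise_sd = 0.4,
                       signature_modules = list(),
                       module_effect = 2,
                       low_quality_cell_fraction = 0,
                       high_mito_cell_fraction = 0,
                       target_colsum = 1e6,
                       seed) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    err_validate("a single integer 'seed' is mandatory")
  cfg <- list(n_genes = as.integer(n_genes),
              n_cells_per_sample = as.integer(n_cells_per_sample),
              n_mito_genes = as.integer(n_mito_genes),
              asynchrony_range = asynchrony_range,
              asynchrony_values = asynchrony_values,
              perturbed_gene_fraction = perturbed_gene_fraction,
              perturbation_scale = perturbation_scale,
              perturbation_cap = perturbation_cap,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              cell_noise_sd = cell_noise_sd,
              signature_modules = signature_modules,
              module_effect = module_effect,
              low_quality_cell_fraction = low_quality_cell_fraction,
              high_mito_cell_fraction = high_mito_cell_fraction,
              target_colsum = target_colsum,
              seed = as.integer(seed))
  t_cells <- sum(cfg$n_cells_per_sample)
  if (cfg$n_genes < 2 || t_cells < 2)
    err_validate("need at least 2 genes and 2 cells")
  if (any(cfg$n_cells_per_sample < 1))
    err_validate("every sample needs at least one cell")
  if (cfg$n_mito_genes < 0 || cfg$n_mito_genes >= cfg$n_genes)
    err_validate("n_mito_genes must be in [0, n_genes)")
  for (f in c("perturbed_gene_fraction", "low_quality_cell_fraction",
              "high_mito_cell_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      err_validate(sprintf("%s must lie in [0, 1]", f))
  if (cfg$perturbation_scale < 0)
    err_validate("perturbation_scale must be >= 0")
  if (cfg$perturbation_cap <= 0)
    err_validate("perturbation_cap must be positive")
  if (!is.null(cfg$asynchrony_values)) {
    if (length(cfg$asynchrony_values) != t_cells)
      err_validate("asynchrony_values must have one entry per cell")
    if (any(cfg$asynchrony_values < 0 | cfg$asynchrony_values > 1))
      err_validate("asynchrony values must lie in [0, 1]")
  } else if (length(cfg$asynchrony_range) != 2 ||
             any(cfg$asynchrony_range < 0 | cfg$asynchrony_range > 1) ||
             diff(cfg$asynchrony_range) < 0) {
    err_validate("asynchrony_range must be an increasing pair in [0, 1]")
  }
  msize <- sum(vapply(cfg$signature_modules,
                      function(m) as.integer(m$size), integer(1)))
  if (msize > cfg$n_genes - cfg$n_mito_genes)
    err_validate("signature module sizes exceed the number of non-mito genes")
  for (m in cfg$signature_modules)
    if (!all(c("name", "size", "coupling") %in% names(m)) ||
        !m$coupling %in% c("positive", "negative", "none"))
      err_validate("each module needs name, size, and coupling in {positive, negative, none}")
  structure(cfg, class = "sim_config")
}

#' Simulate a multi-patient scRNA-seq cohort with known asynchrony
#'
#' Generates a raw TPM-like expression matrix together with the per-cell and
#' per-gene ground truth and fixture gene sets (one per signature module,
#' plus the mitochondrial set). Identical seeds give bit-identical output.
#'
#' @param cfg A [sim_config()].
#' @return List with `matrix` (raw [expression_matrix()]), `truth` (list of
#'   data.frames `cells`: cell_id, sample_id, asynchrony, low_quality,
#'   high_mito; and `genes`: gene_id, mito, module), and `gene_sets` (named
#'   list of [gene_set()] fixtures).
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_genes
  t_cells <- sum(cfg$n_cells_per_sample)
  n_mito <- cfg$n_mito_genes
  gene_ids <- c(if (n_mito) sprintf("MT-G%02d", seq_len(n_mito)),
                sprintf("G%05d", seq_len(m - n_mito)))
  sample_ids <- sprintf("P%02d", seq_along(cfg$n_cells_per_sample))
  samples <- rep(sample_ids, cfg$n_cells_per_sample)
  cell_ids <- paste0(samples, "_C", sprintf("%04d", unlist(
    lapply(cfg$n_cells_per_sample, seq_len))))
  names(samples) <- cell_ids

  # module membership over non-mito genes, disjoint blocks
  module <- rep(NA_character_, m)
  pool <- which(!grepl("^MT-", gene_ids))
  taken <- 0
  for (ms in cfg$signature_modules) {
    idx <- pool[(taken + 1):(taken + ms$size)]
    module[idx] <- ms$name
    taken <- taken + ms$size
  }

  asyn <- if (!is.null(cfg$asynchrony_values)) cfg$asynchrony_values
          else stats::runif(t_cells, cfg$asynchrony_range[1], cfg$asynchrony_range[2])

  baseline <- stats::rnorm(m, cfg$baseline_log_mean, cfg$baseline_log_sd)
  logx <- baseline + matrix(stats::rnorm(m * t_cells, 0, cfg$cell_noise_sd), m, t_cells)

  for (j in seq_len(t_cells)) {
    k <- round(cfg$perturbed_gene_fraction * asyn[j] * m)
    if (k > 0) {
      idx <- sample.int(m, k)
      logx[idx, j] <- logx[idx, j] + rlaplace(k, cfg$perturbation_scale, cfg$perturbation_cap)
    }
    for (ms in cfg$signature_modules) {
      if (ms$coupling == "none") next
      sgn <- if (ms$coupling == "positive") 1 else -1
      midx <- which(!is.na(module) & module == ms$name)
      logx[midx, j] <- logx[midx, j] + sgn * cfg$module_effect * asyn[j]
    }
  }

  lin <- 2^logx
  dimnames(lin) <- list(gene_ids, cell_ids)

  high_mito <- rep(FALSE, t_cells)
  if (cfg$high_mito_cell_fraction > 0 && n_mito > 0) {
    n_hm <- round(cfg$high_mito_cell_fraction * t_cells)
    pick <- sample.int(t_cells, n_hm)
    high_mito[pick] <- TRUE
    target <- stats::runif(n_hm, 0.15, 0.40)
    mito_idx <- seq_len(n_mito)
    for (k in seq_along(pick)) {
      j <- pick[k]
      sm <- sum(lin[mito_idx, j])
      so <- sum(lin[-mito_idx, j])
      lin[mito_idx, j] <- lin[mito_idx, j] * (so * target[k] / (1 - target[k])) / sm
    }
  }

  low_quality <- rep(FALSE, t_cells)
  if (cfg$low_quality_cell_fraction > 0) {
    n_lq <- round(cfg$low_quality_cell_fraction * t_cells)
    pick <- sample.int(t_cells, n_lq)
    low_quality[pick] <- TRUE
    for (j in pick) {
      keep <- sample.int(m, sample(30:250, 1))
      zeroed <- setdiff(seq_len(m), keep)
      lin[zeroed, j] <- 0
    }
  }

  lin <- sweep(lin, 2, colSums(lin) / cfg$target_colsum, "/")

  gene_sets <- list()
  for (ms in cfg$signature_modules)
    gene_sets[[ms$name]] <- gene_set(ms$name, gene_ids[!is.na(module) & module == ms$name])
  if (n_mito) gene_sets[["mito"]] <- gene_set("mito", gene_ids[seq_len(n_mito)])

  list(matrix = expression_matrix(lin, samples, norm_state = "raw"),
       truth = list(
         cells = data.frame(cell_id = cell_ids, sample_id = unname(samples),
                            asynchrony = asyn, low_quality = low_quality,
                            high_mito = high_mito, stringsAsFactors = FALSE),
         genes = data.frame(gene_id = gene_ids, mito = grepl("^MT-", gene_ids),
                            module = module, stringsAsFactors = FALSE)),
       gene_sets = gene_sets)
}

#' Recovery experiment: does the score track true asynchrony?
#'
#' Repeatedly simulates a cohort, normalizes it, scores it, and reports the
#' Spearman correlation between each cell's true asynchrony and its ATAXIC
#' score. Replicate r uses seed `cfg$seed + r - 1`.
#'
#' @param cfg A [sim_config()] whose asynchrony spans at least 3 distinct
#'   values.
#' @param n_reps Number of replicates.
#' @param scope Scoring scope passed to [ataxic()]; default `"cohort"` since
#'   asynchrony is defined on a common scale across all cells.
#' @return List with `rho` (per-replicate vector), `mean_rho`, `sd_rho`,
#'   `n_cells`, `n_genes`, `n_reps`.
#' @export
recovery_experiment <- function(cfg, n_reps = 10, scope = "cohort") {
  stopifnot(inherits(cfg, "sim_config"))
  probe <- if (!is.null(cfg$asynchrony_values)) cfg$asynchrony_values
           else cfg$asynchrony_range
  if (is.null(cfg$asynchrony_values) && diff(cfg$asynchrony_range) == 0)
    err_validate("recovery needs a non-degenerate asynchrony range")
  if (!is.null(cfg$asynchrony_values) && length(unique(probe)) < 3)
    err_validate("recovery needs at least 3 distinct asynchrony levels")
  rho <- vapply(seq_len(n_reps), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + r - 1L
    sim <- simulate_cohort(cfg_r)
    norm <- normalize_log2(sim$matrix)
    sc <- ataxic_scores(norm, scope = scope)
    truth <- stats::setNames(sim$truth$cells$asynchrony, sim$truth$cells$cell_id)
    spearman_cor(truth[sc$cell_id], sc$score)$rho
  }, numeric(1))
  list(rho = rho, mean_rho = mean(rho), sd_rho = stats::sd(rho),
       n_cells = sum(cfg$n_cells_per_sample), n_genes = cfg$n_genes,
       n_reps = n_reps)
}
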