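---
title: "Methods: scoring transcriptomic perturbation heterogeneity in single cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring transcriptomic perturbation heterogeneity in single cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ataxic)
```

## The model

Intratumor heterogeneity shows up in scRNA-seq as cells whose expression
deviates from the population in *unequal* ways: some genes far from their
means, others not at all. The ATAXIC score captures this asynchrony. Given a
normalized genes × cells matrix, each gene is z-scored across cells
(subtract the gene's mean, divide by its sample SD, both over the cells in
scope), and a cell's score is the sample standard deviation, across genes,
of its absolute z-scores. Two properties follow directly and are enforced
as tests:

* **Per-gene affine invariance.** Replacing a gene row $x_i$ by
  $a_i x_i + b_i$ ($a_i \neq 0$) flips at most the sign of $z_i$, so
  $|z_i|$ and every score are unchanged. The score measures the *shape* of
  a cell's deviation profile, not its location or per-gene scale.
* **The two-cell degeneracy.** With $t = 2$ untied cells every gene gives
  $|z| = 1/\sqrt 2$ for both cells, so every score is exactly 0. The score
  is only informative from $t \ge 3$, and stabilizes as genes accumulate
  (its precision grows with the number of retained genes, which is why
  whole-transcriptome matrices are the intended input).

Both SDs use the $n-1$ (sample) denominator. Genes with zero variance in
scope have no defined z-score; they are dropped before scoring and reported,
rather than imputed as $z = 0$, which would dilute the $|z|$ population with
artificial zeros.

### Scoring scope

Per-gene means and SDs can be taken within each patient's cells
(`scope = "sample"`, the default — appropriate when correlating scores with
signatures patient by patient) or across the whole matrix
(`scope = "cohort"` — appropriate when cells of one cancer type are compared
on a common footing). Published per-patient analyses of this kind do not
state which population was standardized over; both are supported and the
choice is always explicit in the API, never guessed.

## Preprocessing

Filters run in a fixed order, on the raw (linear TPM) scale, with strict
thresholds:

1. cells expressing fewer than 300 genes are removed ("expressed" means
   value strictly > 0: TPM is non-negative and 0 means undetected);
2. cells whose mitochondrial share of total expression exceeds 10% are
   removed (share computed on linear values, where a percentage is
   meaningful; cells with zero total expression are removed under a
   distinct reason code; mitochondrial genes default to the
   case-insensitive `MT-` symbol prefix, overridable since annotations
   differ);
3. patients with fewer than 10 remaining cells are removed — after the
   cell-level filters, so a patient is judged on its post-QC cells;
4. log2(TPM+1) normalization, tracked by a state flag so it cannot be
   applied twice and so the scorer can refuse raw input unless explicitly
   allowed.

Boundary cells (exactly 300 genes, exactly 10% mitochondrial, exactly 10
cells) are retained: each wording is a strict inequality and the tests pin
the boundaries.

## Association statistics

Spearman correlation uses average ranks for ties. Its two-sided p-value is
exact (full permutation enumeration) for $n \le 9$ when neither vector is
tied — the $\sum d^2$ shortcut used for the enumeration assumes untied
ranks, so tied small samples fall back to the $t$ approximation with $n-2$
degrees of freedom, which is also the large-sample route. The one-tailed
Mann–Whitney U enumerates all rank assignments when $n_a n_b \le 100$
without ties (a determinism/cost threshold: at most $\binom{20}{10}$
assignments) and otherwise uses the tie-corrected normal approximation with
continuity correction. Both are cross-checked in the test suite against
`stats::cor.test` and `stats::wilcox.test`, which serve as independent
oracles, not as the implementation. Benjamini–Hochberg adjustment and the
Shapiro–Wilk check are delegated to `stats::p.adjust` and
`stats::shapiro.test`; the Shapiro check only annotates reports (scores are
typically non-Gaussian, which motivates the rank-based tests) and never
switches methods silently.

FDR pooling is deliberately explicit: `correlate_by_group()` adjusts across
the groups of one call (one covariate, all patients — the per-figure
framing of published correlation tables), and `fdr_scope = "none"` lets a
caller pool several calls before adjusting. Records with constant input or
fewer than 3 shared cells are flagged and excluded from adjustment rather
than contributing meaningless p-values. The compound screen adjusts across
all tested compounds and deletes missing viability pairwise per compound.

## The synthetic cohort generator

The generator emulates the features of a multi-patient cancer scRNA-seq
cohort that this toolkit touches, with known ground truth:

* per-gene baseline log2 expression drawn once from
  N(`baseline_log_mean` = 3, `baseline_log_sd` = 1.5) — a broad, realistic
  dynamic range of roughly 0–200 TPM for most genes;
* i.i.d. gene × cell noise (`cell_noise_sd` = 0.4 log2 units);
* for a cell with asynchrony $a \in [0,1]$, a random subset of
  `perturbed_gene_fraction` · $a$ · `n_genes` genes (fraction default 0.2)
  shifted by Laplace-distributed amounts (`perturbation_scale` = 2 log2
  units), truncated at `perturbation_cap` = 8 log2 units. The heavy tail
  matters: asynchrony must raise the *dispersion* of $|z|$, not shift all
  genes uniformly — a uniform shift is exactly what the score is blind to.
  The truncation is a biological-plausibility bound (at most a 256-fold
  change); untruncated Laplace tails at scale 2 have infinite linear-scale
  mean, letting single draws dominate a cell's TPM column sum, which no
  real transcriptome does;
* optional signature modules whose mean expression rises (or falls) by
  `module_effect` · $a$ (default 2 log2 units at $a = 1$);
* planted QC failures: low-quality cells keep only 30–250 expressed genes;
  high-mito cells have their 13 `MT-` genes rescaled to a 15–40% share;
* TPM-like closure: columns rescaled to sum to 1e6.

One consequence of closure is worth knowing: cells with many perturbed
genes carry extra linear mass, so *all other* genes in those cells are
scaled down. An uncoupled ("none") module therefore correlates mildly
negatively with asynchrony — real compositional behavior of TPM, and the
generator's contract tests assert the ordering (positive > none > negative)
rather than pretending the neutral module is exactly flat.

What the generator does **not** emulate: UMI counting noise, dropout beyond
the low-quality zeroing, batch effects, doublets, or cell-type mixtures.
Passing the recovery tests therefore shows the score identifies asynchrony
under this generative model, not that it is robust to every artifact of
real data.

The recovery experiment (truth-vs-score Spearman ρ at 2000 genes × 300
cells, 10 replicates, with a zero-signal control at `perturbation_scale = 0`
over 20 replicates) uses no signature modules and no planted QC failures,
so the control isolates the perturbation mechanism: with modules present the
coupling itself would correlate scores with asynchrony and mask a broken
perturbation path.

## Numerical choices

* Column SDs in the scorer use the two-pass formula (subtract the column
  mean, then sum squares), matching the naive per-cell `sd()` reference to
  well below 1e-10 instead of risking one-pass cancellation.
* Zero variance is detected by exact equality (`sd == 0`): constant rows
  subtract to exactly 0 in floating point, and near-constant rows are
  legitimately scored.
* Score tables are written with `%.17g`, so write→read round trips are
  exact to 1e-12 and pipeline reruns are byte-identical (provenance headers
  carry the package version, a hash of the scientific config — output paths
  excluded — and the seed; no timestamps).
* All generator randomness derives from the mandatory config seed;
  replicate $r$ of an experiment uses seed + $r$ − 1.

## Problem sizes

The default test suite and the acceptance script run at desk scale: random
matrices up to 100 × 30 for invariance batches, 50 × 20 for oracle
equivalence, simulated cohorts of 400–1000 genes and 80–200 cells for
generator contracts, and 2000 × 300 for the recovery experiment — sizes
chosen so the full suite completes in well under a minute while each check
still exercises the asymptotic regime it targets (e.g. enough genes that a
cell's score SD estimate is stable).

## Limitations

The score conflates any source of unequal per-gene deviation — subclonal
programs, but also cell-cycle phase or stress responses — and the package
makes no attempt to decompose them. Enrichment scoring is the plain mean
over matched genes (rank-based alternatives such as ssGSEA are explicitly
out of scope). Real-cohort headline values (per-cancer mean scores,
compound-screen counts) depend on the original GEO and DepMap inputs and
are not reproduced here; the package reproduces the *method* and validates
it on ground-truth simulations instead.
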