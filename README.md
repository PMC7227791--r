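# mcfsel

Monte Carlo feature selection and incremental feature selection for
two-class expression data.

## What this is for

Given a genes × samples expression matrix and a two-class sample
assignment — the motivating application is discriminating
tumor-infiltrating CD8+ T cells (TIL) from CD8+ T cells of adjacent
uninvolved lung tissue (NTIL) in non-small-cell lung cancer — `mcfsel`
finds a small panel of genes that *classifies* the samples, rather than
a long list of one-gene-at-a-time significant differences. It is aimed
at analysts doing biomarker discovery on bulk or single-cell expression
matrices with modest sample counts.

The pipeline is:

1. **Monte Carlo feature selection (MCFS).** Draw `s` random subsets of
   `m` genes; grow `t` information-gain decision trees per subset, each
   on its own stratified train/test split. Gene *g*'s relative
   importance aggregates over all *s·t* trees:

   *RI(g) = Σ_τ (wAcc_τ)^u · Σ_{nodes on g} IG(node) · (n_node / n_τ)^v*

   where *IG* is the node's information gain (bits), *n_node / n_τ* is
   the fraction of the tree's training samples reaching the node, and
   *wAcc* is the tree's balanced accuracy on held-out samples
   (`u = v = 1` by default).
2. **Ranking and truncation.** Genes sort by decreasing RI (ties
   lexicographic); the top 500 go forward.
3. **Incremental feature selection (IFS).** Evaluate every nested
   top-*i* prefix with leave-one-out cross-validation under a
   radial-kernel SVM (`e1071` defaults) or a CART tree (`rpart`), and
   select the panel at the accuracy peak.
4. **Over-representation analysis.** One-sided hypergeometric test of
   the panel against GMT gene sets, with odds ratio, enrichment ratio
   and Benjamini–Hochberg adjustment.
5. **Cluster report.** Per-gene z-scores, hierarchical clustering of
   genes and samples, and the count of samples falling outside their
   class's cluster.

A planted-signal simulator (`synthetic_spec()` /
`generate_expression()`) provides study-shaped data with known ground
truth, so the whole pipeline is testable offline.

## Worked example

```r
library(mcfsel)

sim <- generate_expression(synthetic_spec(
  n_genes = 300, n_pos = 18, n_neg = 16, n_informative = 10,
  effect_size = 2, seed = 1))

fit <- mcfs(sim$expr, sim$labels, s = 100, t = 5, m = 15, seed = 2)
head(fit$ri, 3)
#>   rank   gene   ri_raw ri_normalized
#> 1    1 g00237 17.97269     1.0000000
#> 2    2 g00297 15.15398     0.8431670
#> 3    3 g00284 13.21826     0.7354639

ranked <- truncate_top(rank_genes(fit), 20)
length(intersect(ranked, sim$ground_truth))
#> [1] 8         # 8 of the 10 planted genes sit in the top 20

curve <- ifs(sim$expr, sim$labels, ranked, k_max = 15, tie_policy = "max")
curve
#> Incremental feature selection (svm_rbf, LOOCV)
#>   evaluated prefixes: 1..15
#>   peak accuracy 1 at k = {7, 8, 9, 10, 11, 12, 13, 14, 15}
#>   selected panel (tie policy 'max'): k = 15

report <- cluster_for_heatmap(sim$expr[curve$selected_genes, ], sim$labels)
report
#> Cluster report: 15 genes x 34 samples
#>   2-cut sample partition sizes: 18 / 16
#>   samples not matching their cluster's majority class: 0
```

The importance column is the raw ensemble sum (it scales with `s·t`;
use ranks for comparisons), the IFS printout shows the LOOCV accuracy
peak and the chosen panel size, and a misplaced-sample count of 0 means
the two-way sample clustering reproduces the class labels exactly.

For a full run — ranking, IFS, enrichment against a GMT file, cluster
report, and a YAML manifest with per-file checksums — use
`run_pipeline(pipeline_config(...))` or a YAML config via
`read_pipeline_config()`.

## Using real data

The package reads plain TSV (genes × samples, header of sample ids), a
two-column labels file and standard GMT. To analyse the motivating
study's data, download the processed expression matrix of GEO accession
GSE90728 (23,366 genes; 36 TIL and 32 NTIL samples), save it as TSV
with a label file mapping each sample to `TIL`/`NTIL`, and point
`pipeline_config()` at the two files. Expect an `mcfs()` run at
`s = 1000` on the full matrix to take a while; rank on the top of a
variance-filtered matrix if iteration speed matters.

See `vignettes/mcfsel-methods.Rmd` for the model, the design decisions
and the honest limitations (notably: LOOCV accuracies of panels chosen
on the same samples are optimistic; nest the pipeline in an outer loop
for unbiased estimates).
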