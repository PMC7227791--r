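---
title: "Monte Carlo feature selection for two-class expression data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monte Carlo feature selection for two-class expression data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcfsel)
```

## The problem

Given a genes × samples expression matrix and a two-class assignment of
the samples — the motivating case is CD8+ T cells isolated from
non-small-cell lung tumors (TIL, the positive class) versus adjacent
uninvolved lung tissue (NTIL) — we want a small panel of genes that
*discriminates* the classes, not merely a list of statistically
significant differences. Differential-expression tests score genes one
at a time; a significant gene can still be useless in a classifier, and
a thousand significant genes are not a biomarker. `mcfsel` implements
the alternative route: rank all genes by their contribution to an
ensemble of classifiers, then let cross-validated prediction accuracy
decide how many of the top genes to keep.

## The relative-importance score

The ranking engine is Monte Carlo feature selection. Draw `s` random
subsets of `m` genes (`m` much smaller than the gene count `d`); for
each subset grow `t` binary decision trees, each on its own stratified
train/test split of the samples. Gene `g`'s raw relative importance is

$$
RI_g \;=\; \sum_{\tau = 1}^{s\,t} (wAcc_\tau)^u
  \sum_{n_g(\tau)} IG\!\left(n_g(\tau)\right)
  \left( \frac{\mathrm{no.in}\; n_g(\tau)}{\mathrm{no.in}\;\tau} \right)^{\!v}
$$

where the inner sum runs over the nodes of tree $\tau$ that split on
$g$, $IG$ is the node's information gain in bits, the coverage ratio is
the fraction of the tree's training samples reaching that node, and
$wAcc_\tau$ is the tree's accuracy on its held-out samples. A gene
scores highly when it is *repeatedly* chosen for informative,
well-covered splits inside trees that actually generalise. The
exponents `u` and `v` tune the influence of the accuracy and coverage
weights; both default to 1.

Two interpretation choices in this formula were genuinely open and are
fixed as follows:

* **"Weighted" accuracy** is the unweighted mean of per-class recalls
  (balanced accuracy). With 36 versus 32 samples the imbalance is mild,
  but balanced accuracy keeps a tree that always predicts the majority
  class at exactly 0.5, which is the behaviour the score needs.
* **Raw versus normalised score.** Raw importance sums scale with
  `s * t`, so the table reports both `ri_raw` and `ri_normalized`
  (divided by the maximum). Comparisons across runs or with published
  tables should use ranks, not magnitudes.

### The tree primitive

The trees are grown in the package rather than borrowed, because the
score needs quantities a generic CART fit does not expose: per-node
information gain *in bits*, per-node training-sample counts, and a
fully deterministic split rule. Each internal node takes the
gain-maximising (feature, threshold) pair, with thresholds at midpoints
between consecutive distinct sorted values; ties break toward the
earlier feature in subset order, then the smaller threshold. Growth
stops at purity, at `min_leaf` (default 1 — the ensemble, not the
individual tree, does the regularising), or when no split gains
information. Majority ties at leaves resolve to the first class level,
i.e. the positive class.

### Defaults and their rationale

* `s = 1000`, `t = 5`: enough subsets that an average gene is sampled
  about `s * m / d` times; desk-scale analyses and the package's own
  calibration runs use `s` of 100–200, which this package treats as its
  standard experiment size (1000–1500 trees).
* `m = max(2, ceil(0.05 d))`: 5% of genes per subset keeps single
  trees cheap and forces the ensemble, not any one tree, to carry the
  ranking.
* `train_fraction = 0.66`, stratified per class and redrawn per tree:
  a conventional two-thirds/one-third split so every tree has an
  honest held-out accuracy.
* One master seed is fanned out to subset sampling and per-tree splits
  through a counter-based derivation, so results are bit-reproducible
  and independent of execution order.

## Incremental feature selection

Ranking does not say how many genes to keep. The incremental stage
evaluates the nested prefixes $F_i = [f_1, \dots, f_i]$ of the ranking
for $i = 1 \dots k_{max}$, scoring each with leave-one-out
cross-validation: n folds, one held-out sample each, accuracy = correct
held-out predictions / n. Any preprocessing (SVM standardisation) is
fitted inside each fold on the n − 1 training samples only. The default
classifier is a radial-kernel SVM with cost 1 and kernel width
1/(number of features) — the stock defaults of `e1071::svm()` — and a
CART tree (`rpart`) is available as the standard robustness check that
the selected panel is not an artefact of the SVM.

The panel is chosen at the curve's accuracy peak. When several prefix
sizes tie at the maximum, the package defaults to the smallest
(`tie_policy = "min"`, biomarker parsimony); `"max"` takes the largest
tied size, which is how the motivating study resolved its own 18–20
tie. Truncation of the ranking to the top 500 genes before this stage
reflects the field convention that a practical biomarker search never
needs more.

## Over-representation and the cluster report

The selected panel is tested against gene-set collections (GMT format)
with the one-sided hypergeometric test: with `N` background genes, `K`
set members in the background, `n` query genes and overlap `a`, the
p-value is $P(X \ge a)$, $X \sim \mathrm{Hypergeom}(N, K, n)$.
Both the 2×2-table odds ratio and the enrichment ratio
$(a/n)/(K/N)$ are reported, since published analyses quote either
convention. P-values are Benjamini–Hochberg adjusted across sets. The
background defaults to all genes of the expression matrix — the query
arose from that universe, not from the genome.

The reporting stage z-scores each panel gene across samples, clusters
genes and samples (Euclidean distance, complete linkage — the common
default of heatmap tooling; both are configurable), cuts the sample
dendrogram in two, and counts samples whose cluster majority class
differs from their own label. On a discriminative panel this count
should be near zero.

## The synthetic-data generator

Every stage is testable without any download through a planted-signal
simulator. Its defaults are the study-shaped conditions used throughout
the package's tests: 1000 genes, 36 positive and 32 negative samples,
20 informative genes whose class means differ by 2 within-class
standard deviations on the log scale, half up- and half down-regulated
in the positive class. Expression is Gaussian on the log scale — the
downstream machinery is distribution-agnostic (trees are invariant to
monotone per-gene transforms), so the simplest model with a
controllable effect size is the right one. Informative rows are placed
first, then all rows are shuffled under the seed before identifiers are
assigned, so position encodes nothing. The generator is a pure function
of its spec.

What the simulator deliberately does **not** emulate: library-size and
batch effects, count noise, and gene–gene correlation. The last one
matters for interpreting the tests below.

## What the calibration runs show — and do not show

The package's acceptance-style runs, at the sizes above
(`s = 200, t = 5, m = 50`; IFS over the top 30 with `k_max = 30`),
recover ≥ 18 of 20 planted genes in the top 30 and reach a LOOCV peak
accuracy of 1.0; a 20-gene panel at 3 SD separation clusters with zero
misplaced samples. Two behaviours deserve honest flagging:

* **Null-data IFS accuracy is optimistic by construction.** With zero
  effect size, the peak LOOCV accuracy over prefixes of the ranking is
  about 0.85, not 0.5. The ranking is fitted on the same samples the
  LOOCV then evaluates, so the top "null" genes are exactly those that
  happen to separate these particular samples — the classic selection
  bias of feature selection performed outside the cross-validation
  loop. This is a property of the procedure itself (shared by the
  published pipelines this package follows), not an implementation
  artefact; the package keeps the stages separate so a user who needs
  unbiased accuracy estimates can nest the ranking inside an outer
  resampling loop. The complementary null check does hold: across
  reseeds, no gene persists in the top 10 of the ranking.
* **Classifier agreement on panel size is data-dependent.** On real
  expression data, panels selected under the SVM and under a decision
  tree tend to agree, because many moderately informative, correlated
  genes shape both curves. On the simulator's independent, equal-effect
  planted genes they do not: one 2-SD gene already gives a univariate
  tree ~0.96 LOOCV accuracy, so the tree curve peaks at k = 1, while
  the SVM plateaus at 1.0 from k ≈ 6 onward. The disagreement is a
  property of the synthetic conditions, and passing or failing that
  comparison here says little about real data.

## Numerical and degenerate-input choices

* Entropies and gains are in bits; gains are clamped at 0 and splits
  require a gain above 1e-12, so floating-point dust never forces a
  split.
* Exact ranking ties (including all-zero importances) break
  lexicographically by gene identifier.
* Constant genes: never split on (no gain); in the z-scored report
  they become all-zero rows with a warning rather than an error.
* Readers reject malformed input (ragged rows, non-numeric cells,
  duplicate identifiers, >2 label tokens) with located errors instead
  of repairing it.
* LOOCV refuses classes with fewer than 2 samples (a fold would lose
  the class); the per-tree stratified split validates that each class
  keeps ≥ 2 training and ≥ 1 test samples and otherwise advises a
  larger `train_fraction`.

## A compact worked example

```{r example}
sim <- generate_expression(synthetic_spec(
  n_genes = 300, n_pos = 18, n_neg = 16, n_informative = 10,
  effect_size = 2, seed = 1))
fit <- mcfs(sim$expr, sim$labels, s = 100, t = 5, m = 15, seed = 2)
head(fit$ri)
ranked <- truncate_top(rank_genes(fit), 20)
length(intersect(ranked, sim$ground_truth))
curve <- ifs(sim$expr, sim$labels, ranked, k_max = 15,
             tie_policy = "max")
curve
report <- cluster_for_heatmap(sim$expr[curve$selected_genes, ],
                              sim$labels)
report
```

## Known limitations

* Binary classes only; the motivating design has exactly two.
* No permutation-based significance cutoff on the importance scores and
  no feature-interdependency graphs; the ranking is descriptive.
* The tree ensemble is plain R; at `s = 1000` on tens of thousands of
  genes a run is minutes, not seconds.
* Real-data accuracy claims require nesting the whole pipeline in an
  outer validation loop, for the selection-bias reason above.
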