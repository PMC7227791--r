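## Monte Carlo feature selection: rank genes by aggregating, over an
## ensemble of s * t information-gain trees grown on random feature
## subsets, each gene's weighted-accuracy-scaled, coverage-weighted
## information gain.

canonical_labels <- function(labels) {
  if (is.factor(labels)) {
    out <- droplevels(labels)
    if (nlevels(out) > 2L)
      stop("more than two classes present: ",
           paste(levels(out), collapse = ", "))
    out
  } else {
    as_class_labels(labels)
  }
}

#' Sample random feature subsets
#'
#' Draws `s` subsets of `m` distinct feature indices from `1..d`,
#' uniformly without replacement, independently across subsets and
#' deterministically under `seed`.
#'
#' @param d Total number of features.
#' @param m Subset size (`m <= d`).
#' @param s Number of subsets.
#' @param seed Non-negative integer seed.
#' @return Integer matrix, `m` rows x `s` columns; column j is subset j.
#' @export
sample_feature_subsets <- function(d, m, s, seed) {
  if (m > d)
    stop("configuration error: subset size m (", m,
         ") exceeds feature count d (", d, ")")
  with_seed(derive_seed(seed, 1L),
            vapply(seq_len(s), function(j) sample.int(d, m),
                   integer(m)))
}

## Stratified train indices at train_fraction, per class; validates that
## each class keeps >= 2 training and >= 1 test sample.
.stratified_train <- function(y, train_fraction) {
  idx <- split(seq_along(y), y)
  train <- unlist(lapply(idx, function(i) {
    n_tr <- round(train_fraction * length(i))
    if (n_tr < 2L || length(i) - n_tr < 1L)
      stop("configuration error: stratified split leaves a class with ",
           "fewer than 2 training or 1 test samples; increase ",
           "train_fraction or provide more samples")
    sample(i, n_tr)
  }), use.names = FALSE)
  sort(train)
}

#' Rank genes by Monte Carlo relative importance
#'
#' The core estimator. `s` feature subsets of size `m` are drawn at
#' random from the `d` genes; for each subset, `t` information-gain
#' decision trees are grown on independent stratified train/test splits
#' of the samples. Gene `g`'s raw relative importance is
#'
#' \deqn{RI_g = \sum_{\tau=1}^{s t} (wAcc_\tau)^u \sum_{n_g(\tau)}
#'   IG(n_g(\tau)) \left(\frac{no.in\, n_g(\tau)}{no.in\, \tau}\right)^v}
#'
#' summing over every node of every tree that splits on `g`: `IG` is the
#' node's information gain in bits, the coverage ratio is the fraction
#' of the tree's training samples reaching the node, and `wAcc` is the
#' tree's balanced accuracy on its held-out samples. Genes never
#' selected into a subset, or never used in a split, score 0. The score
#' is reported raw and max-normalised; ranks sort by decreasing raw
#' score with exact ties broken lexicographically by gene identifier.
#'
#' @param x Numeric genes x samples matrix with gene rownames and sample
#'   colnames.
#' @param labels Class labels for the columns of `x` (named vector or
#'   factor; two classes).
#' @param s Number of random feature subsets (default 1000).
#' @param t Trees per subset (default 5).
#' @param m Subset size; default `max(2, ceiling(0.05 * d))`.
#' @param u Exponent on the tree accuracy weight (default 1).
#' @param v Exponent on the node coverage weight (default 1).
#' @param train_fraction Fraction of each class used to train each tree
#'   (default 0.66), stratified and resampled independently per tree.
#' @param min_leaf Minimum samples per tree leaf (default 1).
#' @param seed Master seed; subset sampling and per-tree splits derive
#'   from it by fixed offsets, so results are reproducible and
#'   independent of execution order.
#' @return An object of class `mcfs`: list with `ri` (data frame of
#'   rank, gene, ri_raw, ri_normalized), `wacc` (per-tree balanced
#'   accuracies), `config`, and `call`.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 60, n_pos = 8,
#'   n_neg = 8, n_informative = 5, effect_size = 3, seed = 1))
#' fit <- mcfs(sim$expr, sim$labels, s = 30, t = 2, m = 10, seed = 1)
#' head(fit$ri)
#' @export
mcfs <- function(x, labels, s = 1000L, t = 5L, m = NULL, u = 1, v = 1,
                 train_fraction = 0.66, min_leaf = 1L, seed = 1L) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  y <- canonical_labels(labels)
  if (!is.null(names(y))) y <- align_labels(x, y)
  if (length(y) != ncol(x)) stop("labels do not match matrix columns")
  if (nlevels(y) != 2L) stop("exactly two classes are required")
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  d <- nrow(x)
  if (is.null(m)) m <- max(2L, as.integer(ceiling(0.05 * d)))
  subsets <- sample_feature_subsets(d, m, s, seed)
  ri <- structure(numeric(d), names = rownames(x))
  wacc_all <- numeric(s * t)
  tree_idx <- 0L
  for (j in seq_len(s)) {
    xs <- x[subsets[, j], , drop = FALSE]
    for (k in seq_len(t)) {
      tree_idx <- tree_idx + 1L
      train <- with_seed(derive_seed(seed, 2L, tree_idx),
                         .stratified_train(y, train_fraction))
      test <- setdiff(seq_along(y), train)
      tree <- grow_tree(xs[, train, drop = FALSE], y[train],
                        min_leaf = min_leaf)
      wacc <- weighted_accuracy(tree, xs[, test, drop = FALSE], y[test])
      wacc_all[tree_idx] <- wacc
      contrib <- tree_feature_contributions(tree, v = v)
      if (length(contrib))
        ri[names(contrib)] <- ri[names(contrib)] + wacc^u * contrib
    }
  }
  ord <- order(-ri, names(ri))
  max_ri <- max(ri)
  tab <- data.frame(rank = seq_len(d), gene = names(ri)[ord],
                    ri_raw = unname(ri[ord]),
                    ri_normalized = if (max_ri > 0) unname(ri[ord]) / max_ri
                                    else rep(0, d),
                    stringsAsFactors = FALSE)
  structure(list(ri = tab, wacc = wacc_all,
                 config = list(s = s, t = t, m = m, u = u, v = v,
                               train_fraction = train_fraction,
                               min_leaf = min_leaf, seed = seed),
                 classes = levels(y), call = match.call()),
            class = "mcfs")
}

#' Ordered gene list from a relative-importance table
#'
#' Sorts genes by strictly decreasing raw relative importance; exact
#' ties break lexicographically by gene identifier, so the ranking is
#' deterministic.
#'
#' @param ritable An `mcfs` object or a data frame with columns `gene`
#'   and `ri_raw`.
#' @return Character vector of gene identifiers, most important first.
#' @export
rank_genes <- function(ritable) {
  if (inherits(ritable, "mcfs")) ritable <- ritable$ri
  stopifnot(all(c("gene", "ri_raw") %in% names(ritable)))
  ritable$gene[order(-ritable$ri_raw, ritable$gene)]
}

#' Truncate a ranking to its top k genes
#'
#' Downstream panel selection only ever considers the head of the
#' ranking; by convention the top 500 genes are retained.
#'
#' @param ranked Character vector from [rank_genes()].
#' @param k Number of genes to keep (default 500).
#' @return The first `min(k, length(ranked))` genes, order preserved.
#'   `k` larger than the list emits a warning and returns the whole
#'   list.
#' @export
truncate_top <- function(ranked, k = 500L) {
  if (k < 1L) stop("k must be a positive integer")
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds ranking length ", length(ranked),
            "; returning the full ranking")
    return(ranked)
  }
  ranked[seq_len(k)]
}

#' @export
print.mcfs <- function(x, ...) {
  cfg <- x$config
  cat("Monte Carlo feature selection\n")
  cat("  ", nrow(x$ri), " genes ranked by ", cfg$s * cfg$t,
      " trees (s=", cfg$s, ", t=", cfg$t, ", m=", cfg$m, ")\n", sep = "")
  cat("  mean tree balanced accuracy: ",
      format(mean(x$wacc), digits = 3), "\n", sep = "")
  cat("Top genes:\n")
  print(utils::head(x$ri, 5L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.mcfs <- function(object, top = 20L, ...) {
  cat("Monte Carlo feature selection: top", top, "of", nrow(object$ri),
      "genes\n")
  print(utils::head(object$ri, top), row.names = FALSE)
  invisible(object$ri)
}

#' Plot a relative-importance profile
#'
#' Raw relative importance against rank, on the truncated head of the
#' ranking — the usual diagnostic for how quickly importance decays.
#'
#' @param x An `mcfs` object.
#' @param k Number of top ranks to show (default 50).
#' @param ... Passed to [plot()].
#' @export
plot.mcfs <- function(x, k = 50L, ...) {
  k <- min(k, nrow(x$ri))
  plot(x$ri$rank[seq_len(k)], x$ri$ri_raw[seq_len(k)], type = "b",
       pch = 16, cex = 0.6, xlab = "rank", ylab = "relative importance",
       main = "Monte Carlo relative importance", ...)
  invisible(x)
}
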