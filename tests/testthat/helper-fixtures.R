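## Fixtures are built in code; nothing is read from disk except what a
## test writes itself.

named_matrix <- function(values, nrow, gene_ids = NULL, sample_ids = NULL) {
  x <- matrix(values, nrow = nrow)
  if (is.null(gene_ids)) gene_ids <- sprintf("f%d", seq_len(nrow(x)))
  if (is.null(sample_ids)) sample_ids <- sprintf("s%d", seq_len(ncol(x)))
  dimnames(x) <- list(gene_ids, sample_ids)
  x
}

## Two well-separated clusters in 2 features: classes at (0,0) and
## (10,10) with small jitter; 5 + 5 samples.
separable_toy <- function(eps = 0.1) {
  offs <- seq(-2, 2) * eps
  x <- rbind(c(0 + offs, 10 + offs), c(0 - offs, 10 - offs))
  x <- named_matrix(x, nrow = 2)
  y <- structure(rep(c("A", "B"), each = 5), names = colnames(x))
  list(x = x, y = y)
}

## Label-independent Gaussian matrix with balanced labels.
null_toy <- function(n_feat, n_per_class, seed) {
  set.seed(seed)
  x <- named_matrix(stats::rnorm(n_feat * 2 * n_per_class), nrow = n_feat)
  y <- structure(rep(c("A", "B"), each = n_per_class), names = colnames(x))
  list(x = x, y = y)
}

## A tiny expression dataset whose single informative feature separates
## the classes perfectly and whose second feature is pure noise at a
## single constant value; exact relative importances are computable by
## hand for this layout (see test-mcfs).
exact_ri_toy <- function() {
  x <- matrix(c(1, 2, 3, 4, 11, 12, 13, 14,
                rep(5, 8)), nrow = 2, byrow = TRUE,
              dimnames = list(c("sig", "flat"), sprintf("s%d", 1:8)))
  y <- structure(rep(c("A", "B"), each = 4), names = colnames(x))
  list(x = x, y = y)
}

## Independent exact hypergeometric upper-tail oracle built from
## binomial coefficients only (no phyper / fisher.test on this path).
hyper_upper_tail <- function(N, K, n, a) {
  xs <- a:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

## Brute-force best root information gain over all features and all
## midpoint thresholds, using only the exported information_gain().
brute_force_root_ig <- function(x, y) {
  best <- 0
  for (f in rownames(x)) {
    v <- x[f, ]
    cuts <- sort(unique(v))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (thr in mids) {
      ig <- information_gain(y, y[v <= thr], y[v > thr])
      if (ig > best) best <- ig
    }
  }
  best
}
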