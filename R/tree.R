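## Binary CART-style trees split by information gain (bits).  This is the
## primitive the Monte Carlo relative-importance score is built on: every
## internal node exposes its information gain and the number of training
## samples it covers, and a fitted tree exposes its balanced accuracy on
## held-out samples.

#' Shannon entropy of a class-count vector, in bits
#'
#' @param class_counts Non-negative integer vector of per-class counts;
#'   at least one must be positive.
#' @return Entropy in bits, between 0 and log2(number of non-empty
#'   classes).
#' @export
entropy <- function(class_counts) {
  if (any(class_counts < 0)) stop("negative class count")
  n <- sum(class_counts)
  if (n == 0) stop("all class counts are zero")
  p <- class_counts[class_counts > 0] / n
  -sum(p * log2(p))
}

#' Information gain of a binary split, in bits
#'
#' `H(parent) - sum(|child|/|parent| * H(child))` over the two children.
#' The children must partition the parent label multiset and both be
#' non-empty.
#'
#' @param parent_labels,left_labels,right_labels Label vectors.
#' @return Non-negative information gain in bits.
#' @export
information_gain <- function(parent_labels, left_labels, right_labels) {
  if (!length(left_labels) || !length(right_labels))
    stop("degenerate split: a child is empty")
  if (length(parent_labels) != length(left_labels) + length(right_labels) ||
      !identical(sort(as.character(parent_labels)),
                 sort(as.character(c(left_labels, right_labels)))))
    stop("children do not partition the parent labels")
  n <- length(parent_labels)
  h <- function(l) entropy(table(as.character(l)))
  gain <- h(parent_labels) -
    (length(left_labels) / n) * h(left_labels) -
    (length(right_labels) / n) * h(right_labels)
  max(gain, 0)
}

## Entropy of (a, b) count pairs, vectorised over positions.
.h2 <- function(a, b) {
  n <- a + b
  pa <- ifelse(n > 0, a / n, 0)
  pb <- ifelse(n > 0, b / n, 0)
  ha <- ifelse(a > 0, -pa * log2(pa), 0)
  hb <- ifelse(b > 0, -pb * log2(pb), 0)
  ha + hb
}

## Best split of one feature vector v against binary indicator y1
## (TRUE = class level 1).  Candidates are midpoints between consecutive
## distinct sorted values; both children must have >= min_leaf samples.
## Returns list(ig, threshold) or NULL.  Among equal-IG candidates the
## smallest threshold wins (positions scan in ascending value order).
.best_split_feature <- function(v, y1, min_leaf) {
  n <- length(v)
  o <- order(v)
  vs <- v[o]
  ys <- y1[o]
  i <- seq_len(n - 1L)
  valid <- vs[i] < vs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  cum1 <- cumsum(ys)
  n1 <- cum1[n]
  l1 <- cum1[i]; l2 <- i - l1
  r1 <- n1 - l1; r2 <- (n - i) - r1
  h_parent <- .h2(n1, n - n1)
  ig <- h_parent - (i / n) * .h2(l1, l2) - ((n - i) / n) * .h2(r1, r2)
  ig[!valid] <- -Inf
  best <- which.max(ig)
  if (ig[best] <= 1e-12) return(NULL)
  list(ig = unname(ig[best]),
       threshold = unname(vs[best] + vs[best + 1L]) / 2)
}

.majority_level <- function(y) {
  counts <- tabulate(as.integer(y), nbins = nlevels(y))
  levels(y)[which.max(counts)]  # tie -> first level in the fixed ordering
}

.grow_node <- function(x, y, idx, min_leaf) {
  yi <- y[idx]
  n_here <- length(idx)
  counts <- tabulate(as.integer(yi), nbins = nlevels(y))
  if (sum(counts > 0) <= 1L || n_here < 2L * min_leaf)
    return(list(leaf = TRUE, class = .majority_level(yi), n_samples = n_here))
  y1 <- as.integer(yi) == 1L
  best <- NULL
  best_feat <- NA_character_
  for (f in rownames(x)) {
    cand <- .best_split_feature(x[f, idx], y1, min_leaf)
    if (!is.null(cand) &&
        (is.null(best) || cand$ig > best$ig + 1e-12)) {
      best <- cand
      best_feat <- f
    }
  }
  if (is.null(best))
    return(list(leaf = TRUE, class = .majority_level(yi), n_samples = n_here))
  go_left <- x[best_feat, idx] <= best$threshold
  list(leaf = FALSE, feature = best_feat, threshold = best$threshold,
       info_gain = best$ig, n_samples = n_here,
       left = .grow_node(x, y, idx[go_left], min_leaf),
       right = .grow_node(x, y, idx[!go_left], min_leaf))
}

#' Grow an information-gain decision tree
#'
#' Greedy binary CART-style growth: each internal node stores the
#' information-gain-maximising (feature, threshold) pair over candidate
#' midpoints between consecutive distinct sorted values. Growth stops at
#' pure nodes, when a child would fall below `min_leaf` samples, or when
#' no split gains information. Ties in gain are broken by earlier
#' feature (row order of `x`), then smaller threshold, so growth is
#' deterministic. Single-class training data yields a depth-0 leaf.
#'
#' @param x Numeric features x samples matrix (rownames = feature ids).
#' @param y Class labels for the columns of `x` (two levels; level 1 is
#'   the positive class and wins majority ties).
#' @param min_leaf Minimum samples per leaf (default 1; trees are
#'   unpruned, as the ensemble aggregation does the regularising).
#' @return An object of class `mcfs_tree` with components `root`
#'   (nested node list), `n_train`, and `classes`.
#' @export
grow_tree <- function(x, y, min_leaf = 1L) {
  stopifnot(is.matrix(x), !is.null(rownames(x)))
  y <- if (is.factor(y)) droplevels(y) else factor(y)
  if (ncol(x) != length(y)) stop("x and y disagree on sample count")
  if (length(y) < 1L) stop("no training samples")
  root <- .grow_node(x, y, seq_along(y), as.integer(min_leaf))
  structure(list(root = root, n_train = length(y), classes = levels(y)),
            class = "mcfs_tree")
}

#' Predict classes with a fitted tree
#'
#' @param object An `mcfs_tree`.
#' @param newdata Numeric features x samples matrix containing at least
#'   the features the tree splits on.
#' @param ... Unused.
#' @return Character vector of predicted class labels, one per column.
#' @export
predict.mcfs_tree <- function(object, newdata, ...) {
  one <- function(node, j) {
    while (!node$leaf) {
      node <- if (newdata[node$feature, j] <= node$threshold)
        node$left else node$right
    }
    node$class
  }
  vapply(seq_len(ncol(newdata)), function(j) one(object$root, j), "")
}

#' Balanced accuracy of a tree on held-out samples
#'
#' The mean over classes of the per-class recall (fraction of that
#' class's test samples predicted correctly). This is the
#' weighted-accuracy term that scales each tree's contribution to the
#' relative-importance score; it is robust to class imbalance. Every
#' class must be represented in the test set.
#'
#' @param tree An `mcfs_tree`.
#' @param x_test Features x samples test matrix.
#' @param y_test Test labels.
#' @return Balanced accuracy in \[0, 1\].
#' @export
weighted_accuracy <- function(tree, x_test, y_test) {
  y_test <- factor(as.character(y_test), levels = tree$classes)
  counts <- table(y_test)
  if (any(counts == 0))
    stop("class absent from test set: ",
         paste(names(counts)[counts == 0], collapse = ", "))
  pred <- predict(tree, x_test)
  recalls <- vapply(tree$classes, function(cl) {
    in_cl <- y_test == cl
    mean(pred[in_cl] == cl)
  }, 0)
  mean(recalls)
}

## Per-feature sum over nodes splitting on the feature of
## IG * (n_node / n_train)^v -- the inner sum of the relative-importance
## score for one tree (before the wAcc^u factor).
tree_feature_contributions <- function(tree, v = 1) {
  acc <- new.env(parent = emptyenv())
  walk <- function(node) {
    if (node$leaf) return(invisible())
    prev <- if (exists(node$feature, acc)) get(node$feature, acc) else 0
    assign(node$feature,
           prev + node$info_gain * (node$n_samples / tree$n_train)^v,
           acc)
    walk(node$left)
    walk(node$right)
  }
  walk(tree$root)
  out <- unlist(as.list(acc))
  if (is.null(out)) numeric(0) else out
}

#' @export
print.mcfs_tree <- function(x, ...) {
  cat("Information-gain decision tree (", x$n_train, " training samples)\n",
      sep = "")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$leaf) {
      cat(pad, "leaf: ", node$class, " (n=", node$n_samples, ")\n", sep = "")
    } else {
      cat(pad, node$feature, " <= ", format(node$threshold), "  IG=",
          format(node$info_gain, digits = 4), " (n=", node$n_samples, ")\n",
          sep = "")
      show(node$left, indent + 1L)
      show(node$right, indent + 1L)
    }
  }
  show(x$root, 1L)
  invisible(x)
}
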