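## Incremental feature selection: score nested top-i prefixes of a gene
## ranking with leave-one-out cross-validation and select the panel at
## the accuracy peak.

#' Classifier specification for incremental feature selection
#'
#' Two classifiers are supported. `svm_rbf` is a radial-basis support
#' vector machine with cost 1, kernel width 1 / (number of features) and
#' per-fold standardisation fitted on the training fold only — the
#' conventional defaults of [e1071::svm()]. `decision_tree` is a CART
#' tree via [rpart::rpart()], the standard robustness check that the
#' selected panel is not an artefact of the SVM.
#'
#' @param kind `"svm_rbf"` or `"decision_tree"`.
#' @param cost SVM soft-margin cost (default 1).
#' @param standardize Standardise features per training fold (default
#'   TRUE; `svm_rbf` only).
#' @param min_leaf Minimum samples per leaf for `decision_tree`
#'   (default 1; maps to `rpart.control(minbucket = min_leaf,
#'   minsplit = 2 * min_leaf)`).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("svm_rbf", "decision_tree"),
                            cost = 1, standardize = TRUE, min_leaf = 1L) {
  kind <- match.arg(kind)
  if (cost <= 0) stop("cost must be positive")
  structure(list(kind = kind, cost = cost, standardize = standardize,
                 min_leaf = as.integer(min_leaf)),
            class = "classifier_spec")
}

## Fit on x_train (features x samples) / predict columns of x_new.
.fit_predict <- function(spec, x_train, y_train, x_new) {
  y_train <- droplevels(y_train)
  if (nlevels(y_train) < 2L)
    stop("a training fold lost one class entirely; LOOCV is undefined")
  if (spec$kind == "svm_rbf") {
    fit <- e1071::svm(x = t(x_train), y = y_train, kernel = "radial",
                      cost = spec$cost, scale = spec$standardize)
    as.character(predict(fit, t(x_new)))
  } else {
    df <- as.data.frame(t(x_train))
    df$.class <- y_train
    fit <- rpart::rpart(.class ~ ., data = df, method = "class",
                        control = rpart::rpart.control(
                          minbucket = spec$min_leaf,
                          minsplit = 2L * spec$min_leaf))
    as.character(predict(fit, as.data.frame(t(x_new)), type = "class"))
  }
}

#' Leave-one-out cross-validated accuracy of a feature set
#'
#' Runs exactly n train/predict rounds, each holding out one sample;
#' any preprocessing (SVM standardisation) is fitted on the n - 1
#' training samples only. Accuracy is the number of correctly predicted
#' held-out samples over n.
#'
#' @param x Numeric features x samples matrix restricted to the feature
#'   set under evaluation.
#' @param labels Class labels for the columns of `x` (two classes, at
#'   least 3 samples, at least 2 per class).
#' @param classifier A [classifier_spec()] (default `svm_rbf`).
#' @return Accuracy in \[0, 1\].
#' @export
loocv_accuracy <- function(x, labels, classifier = classifier_spec()) {
  stopifnot(is.matrix(x))
  y <- canonical_labels(labels)
  if (!is.null(names(y)) && !is.null(colnames(x))) y <- align_labels(x, y)
  n <- ncol(x)
  if (n < 3L) stop("LOOCV needs at least 3 samples")
  if (nlevels(y) != 2L) stop("exactly two classes are required")
  if (any(table(y) < 2L))
    stop("a training fold would lose one class entirely; ",
         "each class needs at least 2 samples")
  correct <- 0L
  for (i in seq_len(n)) {
    pred <- .fit_predict(classifier, x[, -i, drop = FALSE], y[-i],
                         x[, i, drop = FALSE])
    if (pred == as.character(y[i])) correct <- correct + 1L
  }
  correct / n
}

#' Incremental feature selection over a gene ranking
#'
#' For each i in `1..k_max`, evaluates the top-i prefix of the ranking
#' with [loocv_accuracy()] and records the (i, accuracy) curve. The
#' optimal panel size is the accuracy peak; when several i tie at the
#' maximum, `tie_policy = "min"` picks the smallest (parsimony) and
#' `"max"` the largest panel.
#'
#' @param x Numeric genes x samples matrix.
#' @param labels Class labels for the columns of `x`.
#' @param ranked_genes Character vector of gene identifiers, most
#'   important first (see [rank_genes()]).
#' @param k_max Largest prefix length to evaluate (default
#'   `min(500, length(ranked_genes))`).
#' @param classifier A [classifier_spec()].
#' @param tie_policy `"min"` or `"max"` (default `"min"`).
#' @return An object of class `ifs`: list with `points` (data frame k,
#'   accuracy), `peak_indices`, `selected_k`, `selected_genes`,
#'   `classifier`, `tie_policy`.
#' @examples
#' sim <- generate_expression(synthetic_spec(n_genes = 40, n_pos = 8,
#'   n_neg = 8, n_informative = 4, effect_size = 3, seed = 2))
#' fit <- mcfs(sim$expr, sim$labels, s = 30, t = 2, m = 8, seed = 1)
#' curve <- ifs(sim$expr, sim$labels, rank_genes(fit), k_max = 6)
#' curve$selected_k
#' @export
ifs <- function(x, labels, ranked_genes,
                k_max = min(500L, length(ranked_genes)),
                classifier = classifier_spec(),
                tie_policy = c("min", "max")) {
  tie_policy <- match.arg(tie_policy)
  if (k_max > length(ranked_genes))
    stop("k_max (", k_max, ") exceeds ranking length (",
         length(ranked_genes), ")")
  missing <- setdiff(ranked_genes[seq_len(k_max)], rownames(x))
  if (length(missing))
    stop("ranked genes absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  acc <- vapply(seq_len(k_max), function(i) {
    tryCatch(
      loocv_accuracy(x[ranked_genes[seq_len(i)], , drop = FALSE], labels,
                     classifier),
      error = function(e)
        stop("IFS failed at prefix i = ", i, ": ", conditionMessage(e)))
  }, 0)
  out <- structure(list(points = data.frame(k = seq_len(k_max),
                                            accuracy = acc),
                        ranked_genes = ranked_genes[seq_len(k_max)],
                        classifier = classifier, tie_policy = tie_policy),
                   class = "ifs")
  select_peak(out, tie_policy)
}

#' Select the panel at the peak of an IFS curve
#'
#' @param curve An `ifs` object (or a data frame with columns `k` and
#'   `accuracy` plus an attached ranking).
#' @param tie_policy `"min"` (smallest peak index, parsimony) or
#'   `"max"` (largest peak index).
#' @return The `ifs` object with `peak_indices`, `selected_k` and
#'   `selected_genes` set.
#' @export
select_peak <- function(curve, tie_policy = c("min", "max")) {
  tie_policy <- match.arg(tie_policy)
  stopifnot(inherits(curve, "ifs"), nrow(curve$points) >= 1L)
  acc <- curve$points$accuracy
  peak <- curve$points$k[acc >= max(acc) - 1e-12]
  curve$peak_indices <- peak
  curve$selected_k <- if (tie_policy == "min") min(peak) else max(peak)
  curve$selected_genes <- curve$ranked_genes[seq_len(curve$selected_k)]
  curve$tie_policy <- tie_policy
  curve
}

#' @export
print.ifs <- function(x, ...) {
  cat("Incremental feature selection (", x$classifier$kind, ", LOOCV)\n",
      sep = "")
  cat("  evaluated prefixes: 1..", nrow(x$points), "\n", sep = "")
  cat("  peak accuracy ", format(max(x$points$accuracy), digits = 4),
      " at k = {", paste(x$peak_indices, collapse = ", "), "}\n", sep = "")
  cat("  selected panel (tie policy '", x$tie_policy, "'): k = ",
      x$selected_k, "\n", sep = "")
  invisible(x)
}

#' @export
summary.ifs <- function(object, ...) {
  print(object)
  cat("Selected genes:\n")
  cat(" ", paste(object$selected_genes, collapse = ", "), "\n")
  invisible(object$points)
}

#' Plot an IFS curve
#'
#' LOOCV accuracy against the number of top-ranked genes, with the
#' selected panel size marked.
#'
#' @param x An `ifs` object.
#' @param ... Passed to [plot()].
#' @export
plot.ifs <- function(x, ...) {
  plot(x$points$k, x$points$accuracy, type = "l",
       xlab = "number of top-ranked genes",
       ylab = "LOOCV accuracy", main = "IFS curve", ...)
  graphics::points(x$selected_k,
                   x$points$accuracy[x$points$k == x$selected_k],
                   pch = 19, col = 2)
  invisible(x)
}
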