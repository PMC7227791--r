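#' Specification for a planted-signal synthetic expression matrix
#'
#' Describes a two-class genes-by-samples expression matrix on the log
#' scale: a Gaussian noise background plus a small set of informative
#' genes whose class means differ by `effect_size` within-class standard
#' deviations. The defaults emulate the shape of a bulk RNA-seq
#' comparison of 36 tumor-infiltrating (TIL-like, positive) versus 32
#' adjacent-tissue (NTIL-like, negative) CD8+ T cell samples with a
#' 20-gene planted panel.
#'
#' @param n_genes Number of genes (rows).
#' @param n_pos,n_neg Samples in the positive (TIL-like) and negative
#'   (NTIL-like) class; each must be at least 2 so that leave-one-out
#'   folds and per-class accuracies are defined.
#' @param n_informative Number of planted discriminative genes
#'   (0 <= n_informative <= n_genes).
#' @param effect_size Class-mean shift of informative genes, in units of
#'   `base_log_sd` on the log scale. 0 means no gene is informative in
#'   distribution.
#' @param base_log_mean,base_log_sd Mean and standard deviation of the
#'   log-scale background expression.
#' @param direction_mix Fraction of informative genes up-regulated in the
#'   positive class (the rest are down-regulated there).
#' @param seed Non-negative integer master seed; the generator is a pure
#'   function of the spec.
#' @return An object of class `synthetic_spec`.
#' @seealso [generate_expression()]
#' @export
synthetic_spec <- function(n_genes = 1000, n_pos = 36, n_neg = 32,
                           n_informative = 20, effect_size = 2,
                           base_log_mean = 6, base_log_sd = 1,
                           direction_mix = 0.5, seed = 1) {
  chk <- function(ok, field, msg) {
    if (!ok) stop("invalid synthetic_spec field '", field, "': ", msg)
  }
  chk(is.numeric(n_genes) && n_genes >= 1, "n_genes", "must be a positive integer")
  chk(is.numeric(n_pos) && n_pos >= 2, "n_pos", "must be >= 2")
  chk(is.numeric(n_neg) && n_neg >= 2, "n_neg", "must be >= 2")
  chk(is.numeric(n_informative) && n_informative >= 0, "n_informative",
      "must be non-negative")
  chk(n_informative <= n_genes, "n_informative", "must not exceed n_genes")
  chk(is.numeric(effect_size) && effect_size >= 0, "effect_size",
      "must be non-negative")
  chk(is.numeric(base_log_sd) && base_log_sd > 0, "base_log_sd",
      "must be positive")
  chk(is.numeric(direction_mix) && direction_mix >= 0 && direction_mix <= 1,
      "direction_mix", "must lie in [0, 1]")
  chk(is.numeric(seed) && seed >= 0, "seed", "must be a non-negative integer")
  structure(list(n_genes = as.integer(n_genes), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, base_log_mean = base_log_mean,
                 base_log_sd = base_log_sd, direction_mix = direction_mix,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a planted-signal expression matrix with known ground truth
#'
#' Draws log-scale expression values as Gaussian noise around
#' `base_log_mean`; for the planted informative genes the positive-class
#' mean is shifted by `effect_size * base_log_sd` (up for a
#' `direction_mix` fraction of them, down for the rest). Rows are then
#' shuffled before gene identifiers are assigned, so row position
#' carries no information about ground truth. Output is bit-identical
#' for identical specs.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with components `expr` (numeric genes x samples matrix
#'   with gene/sample dimnames), `labels` (named factor, level 1 =
#'   "TIL"), and `ground_truth` (character vector of the planted gene
#'   identifiers, empty when `n_informative = 0`).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_pos + spec$n_neg
  sample_ids <- c(sprintf("TIL_%02d", seq_len(spec$n_pos)),
                  sprintf("NTIL_%02d", seq_len(spec$n_neg)))
  labels <- as_class_labels(
    structure(rep(c("TIL", "NTIL"), c(spec$n_pos, spec$n_neg)),
              names = sample_ids),
    positive = "TIL")
  with_seed(spec$seed, {
    x <- matrix(stats::rnorm(spec$n_genes * n, mean = spec$base_log_mean,
                             sd = spec$base_log_sd),
                nrow = spec$n_genes, ncol = n)
    if (spec$n_informative > 0L) {
      n_up <- round(spec$direction_mix * spec$n_informative)
      dirs <- rep(c(1, -1), c(n_up, spec$n_informative - n_up))
      shift <- spec$effect_size * spec$base_log_sd
      pos_cols <- seq_len(spec$n_pos)
      for (i in seq_len(spec$n_informative))
        x[i, pos_cols] <- x[i, pos_cols] + dirs[i] * shift
    }
    perm <- sample.int(spec$n_genes)
    x <- x[perm, , drop = FALSE]
    gene_ids <- sprintf("g%05d", seq_len(spec$n_genes))
    dimnames(x) <- list(gene_ids, sample_ids)
    truth <- gene_ids[perm <= spec$n_informative]
    list(expr = x, labels = labels, ground_truth = truth)
  })
}

#' Randomly permute class labels across samples
#'
#' Shuffles which sample carries which label while preserving the class
#' sizes and the set of sample identifiers — the standard null for
#' calibrating importance scores against label-independent structure.
#'
#' @param labels Named factor or character vector of class labels.
#' @param seed Non-negative integer seed; identical seeds give identical
#'   permutations.
#' @return Labels of the same class/levels, names unchanged, values
#'   permuted.
#' @export
permute_labels <- function(labels, seed) {
  if (length(labels) == 0L) stop("labels are empty")
  with_seed(derive_seed(seed, 9L), {
    perm <- sample.int(length(labels))
    out <- labels[perm]
    names(out) <- names(labels)
    out
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the expression TSV, labels TSV and ground-truth gene list for a
#' generated dataset, in the same dialects the package readers consume.
#'
#' @param bundle Result of [generate_expression()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named character vector of file paths written.
#' @export
write_synthetic_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             labels = file.path(dir, "labels.tsv"),
             ground_truth = file.path(dir, "ground_truth.txt"))
  write_expression_tsv(bundle$expr, paths[["expression"]])
  write_labels(bundle$labels, paths[["labels"]])
  writeLines(bundle$ground_truth, paths[["ground_truth"]])
  invisible(paths)
}
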