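## Heatmap-style cluster report for a selected gene panel: per-gene
## z-scoring, hierarchical clustering of genes and samples, and a
## cluster-versus-class agreement count.

#' Cluster a selected gene panel for a heatmap report
#'
#' Standardises each gene across samples (z-score; constant genes are
#' zeroed with a warning), clusters genes and samples by agglomerative
#' hierarchical clustering, cuts the sample dendrogram into two groups,
#' and counts the samples whose cluster's majority class differs from
#' their own class — the number of "misplaced" samples, mirroring the
#' usual visual check that a discriminative panel separates the two
#' classes.
#'
#' @param x Numeric genes x samples matrix restricted to the selected
#'   panel (>= 2 genes, >= 2 samples).
#' @param labels Class labels for the columns of `x`.
#' @param distance Distance measure for [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"complete"`).
#' @return An object of class `cluster_report`: `z_matrix`
#'   (standardised values), `row_order` and `col_order` (dendrogram
#'   permutations), `sample_partition` (named 2-group assignment),
#'   `misplaced_count`, and the two `hclust` objects.
#' @export
cluster_for_heatmap <- function(x, labels, distance = "euclidean",
                                linkage = "complete") {
  stopifnot(is.matrix(x))
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need at least 2 genes and 2 samples")
  y <- canonical_labels(labels)
  if (!is.null(names(y)) && !is.null(colnames(x))) y <- align_labels(x, y)
  sds <- apply(x, 1L, stats::sd)
  const <- sds == 0 | is.na(sds)
  if (any(const))
    warning("constant gene rows zeroed in z-matrix: ",
            paste(rownames(x)[const], collapse = ", "))
  z <- t(scale(t(x)))
  z[const, ] <- 0
  row_hc <- stats::hclust(stats::dist(z, method = distance),
                          method = linkage)
  col_hc <- stats::hclust(stats::dist(t(z), method = distance),
                          method = linkage)
  partition <- stats::cutree(col_hc, k = 2L)
  misplaced <- sum(vapply(split(as.character(y), partition), function(cls) {
    length(cls) - max(table(cls))
  }, 0))
  structure(list(z_matrix = z, row_order = row_hc$order,
                 col_order = col_hc$order, sample_partition = partition,
                 misplaced_count = as.integer(misplaced),
                 labels = y, row_hclust = row_hc, col_hclust = col_hc),
            class = "cluster_report")
}

#' Write the ordered z-matrix of a cluster report to TSV
#'
#' Rows and columns appear in dendrogram order, so the file reproduces
#' the heatmap layout.
#'
#' @param report A `cluster_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cluster_report <- function(report, path) {
  z <- report$z_matrix[report$row_order, report$col_order, drop = FALSE]
  write_expression_tsv(z, path)
  invisible(path)
}

#' @export
print.cluster_report <- function(x, ...) {
  cat("Cluster report: ", nrow(x$z_matrix), " genes x ",
      ncol(x$z_matrix), " samples\n", sep = "")
  cat("  2-cut sample partition sizes: ",
      paste(table(x$sample_partition), collapse = " / "), "\n", sep = "")
  cat("  samples not matching their cluster's majority class: ",
      x$misplaced_count, "\n", sep = "")
  invisible(x)
}

#' Heatmap of a cluster report
#'
#' Base-graphics heatmap of the z-matrix in dendrogram order with a
#' class colour bar. Decorative: the tested surface is the z-matrix
#' itself.
#'
#' @param x A `cluster_report`.
#' @param ... Passed to [stats::heatmap()].
#' @export
plot.cluster_report <- function(x, ...) {
  side <- ifelse(x$labels == levels(x$labels)[1L], "firebrick", "steelblue")
  stats::heatmap(x$z_matrix,
                 Rowv = stats::as.dendrogram(x$row_hclust),
                 Colv = stats::as.dendrogram(x$col_hclust),
                 scale = "none", ColSideColors = side, ...)
  invisible(x)
}
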