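## Over-representation analysis of a selected gene panel against gene-set
## collections: one-sided hypergeometric p-values, odds ratio, enrichment
## ratio, Benjamini-Hochberg adjustment.

#' Hypergeometric over-representation test for one gene set
#'
#' Tests whether the query list overlaps a gene set more than expected
#' when `query_n` genes are drawn at random from the background. With
#' `N` background genes, `K` of which belong to the set (after
#' intersecting the set with the background), `n` query genes and an
#' observed overlap `a`, the p-value is the one-sided upper tail
#' `P(X >= a)` for `X ~ Hypergeometric(N, K, n)`. The odds ratio comes
#' from the 2x2 table (a, n - a; K - a, N - K - (n - a)), with `Inf`
#' when the denominator product is zero and the numerator is not; the
#' enrichment ratio is `(a / n) / (K / N)`.
#'
#' @param query Character vector of query gene identifiers (must all be
#'   in `background`).
#' @param gene_set Character vector of the set's member genes.
#' @param background Character vector of background gene identifiers
#'   (conventionally all genes of the expression matrix the query arose
#'   from).
#' @return One-row data frame: overlap_k, set_size_K, query_n,
#'   background_N, p_value, odds_ratio, enrichment_ratio — or NULL
#'   (with a warning) when the set has no member in the background.
#' @export
overrepresentation_test <- function(query, gene_set, background) {
  query <- unique(query)
  background <- unique(background)
  off <- setdiff(query, background)
  if (length(off))
    stop("query genes absent from background: ",
         paste(utils::head(off, 10L), collapse = ", "))
  if (length(query) < 1L) stop("empty query list")
  eff <- intersect(unique(gene_set), background)
  if (!length(eff)) {
    warning("gene set has no members in the background; skipped")
    return(NULL)
  }
  N <- length(background)
  K <- length(eff)
  n <- length(query)
  a <- length(intersect(query, eff))
  p <- stats::phyper(a - 1L, K, N - K, n, lower.tail = FALSE)
  b <- n - a
  cc <- K - a
  d <- N - K - b
  odds <- if (b * cc == 0) {
    if (a * d > 0) Inf else NaN
  } else {
    (a * d) / (b * cc)
  }
  data.frame(overlap_k = a, set_size_K = K, query_n = n, background_N = N,
             p_value = min(p, 1), odds_ratio = odds,
             enrichment_ratio = (a / n) / (K / N))
}

#' Over-representation analysis across a gene-set collection
#'
#' Applies [overrepresentation_test()] to every set in the collection,
#' adjusts p-values across the tested sets by the Benjamini-Hochberg
#' step-up procedure, and sorts by ascending p-value (ties by set
#' identifier).
#'
#' @param query Character vector of query genes.
#' @param collection Named list of gene sets as from [read_gmt()], or a
#'   named list of character vectors.
#' @param background Character vector of background genes.
#' @param method Multiple-testing adjustment (default `"BH"`; any
#'   [stats::p.adjust()] method).
#' @return Data frame with one row per tested set: set_id, description,
#'   the columns of [overrepresentation_test()], and adjusted_p.
#' @export
enrich_all <- function(query, collection, background, method = "BH") {
  if (!length(collection))
    return(data.frame(set_id = character(), description = character(),
                      overlap_k = integer(), set_size_K = integer(),
                      query_n = integer(), background_N = integer(),
                      p_value = numeric(), adjusted_p = numeric(),
                      odds_ratio = numeric(), enrichment_ratio = numeric()))
  rows <- lapply(names(collection), function(id) {
    set <- collection[[id]]
    members <- if (is.list(set)) set$members else set
    descr <- if (is.list(set) && !is.null(set$description))
      set$description else ""
    row <- overrepresentation_test(query, members, background)
    if (is.null(row)) return(NULL)
    cbind(data.frame(set_id = id, description = descr,
                     stringsAsFactors = FALSE), row)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(enrich_all(query, list(), background, method))
  out <- do.call(rbind, rows)
  out$adjusted_p <- stats::p.adjust(out$p_value, method = method)
  out <- out[order(out$p_value, out$set_id), ]
  rownames(out) <- NULL
  out[c("set_id", "description", "overlap_k", "set_size_K", "query_n",
        "background_N", "p_value", "adjusted_p", "odds_ratio",
        "enrichment_ratio")]
}
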