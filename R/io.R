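## Readers and writers for the package's plain-text formats.
## All readers reject malformed input with a located error instead of
## silently repairing it; every writer/reader pair is an exact round trip.

#' Read a genes x samples expression matrix from TSV
#'
#' Expects a tab-separated file whose first line is a header of sample
#' identifiers (the leading cell may be empty or "gene_id") and whose
#' subsequent lines are a gene identifier followed by one numeric value
#' per sample. Row and column order are preserved.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames.
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty expression file: ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) >= 1L && header[1L] %in% c("", "gene_id"))
    header <- header[-1L]
  n_samp <- length(header)
  if (n_samp < 1L) stop("header contains no sample identifiers")
  if (anyDuplicated(header))
    stop("duplicate sample identifiers: ",
         paste(unique(header[duplicated(header)]), collapse = ", "))
  body <- lines[-1L]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  widths <- lengths(fields)
  bad <- which(widths != n_samp + 1L)
  if (length(bad))
    stop("ragged row at line ", bad[1L] + 1L, ": expected ", n_samp + 1L,
         " fields, found ", widths[bad[1L]])
  gene_ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(gene_ids)) {
    d <- which(duplicated(gene_ids))[1L]
    stop("duplicate gene identifier '", gene_ids[d], "' at line ", d + 1L)
  }
  vals <- suppressWarnings(
    vapply(fields, function(f) as.numeric(f[-1L]), numeric(n_samp)))
  if (n_samp == 1L) vals <- matrix(vals, nrow = 1L)
  if (anyNA(vals)) {
    idx <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric value at line ", idx[2L] + 1L, ", sample column '",
         header[idx[1L]], "'")
  }
  x <- t(vals)
  dimnames(x) <- list(gene_ids, header)
  x
}

#' Write an expression matrix to TSV
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_tsv <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
  body <- apply(x, 1L, function(r)
    paste(format(r, digits = 15, trim = TRUE, scientific = FALSE),
          collapse = "\t"))
  writeLines(paste(rownames(x), body, sep = "\t"), con)
  invisible(path)
}

#' Read per-sample class labels from a two-column TSV
#'
#' Each line carries a sample identifier and a class token, tab
#' separated. Exactly one or two distinct tokens may appear; tokens are
#' matched case-sensitively.
#'
#' @param path Path to the labels file.
#' @param positive Token treated as the positive class (default "TIL"
#'   when present; see [as_class_labels()]).
#' @return Named factor of class labels, level 1 = positive class.
#' @export
read_labels <- function(path, positive = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty labels file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  if (length(bad))
    stop("labels line ", bad[1L], " does not have 2 tab-separated fields")
  ids <- vapply(fields, `[[`, "", 1L)
  tokens <- vapply(fields, `[[`, "", 2L)
  if (anyDuplicated(ids))
    stop("duplicate sample identifier in labels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  as_class_labels(structure(tokens, names = ids), positive = positive)
}

#' Write class labels to a two-column TSV
#'
#' @param labels Named factor or character vector of labels.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labels <- function(labels, path) {
  stopifnot(!is.null(names(labels)))
  writeLines(paste(names(labels), as.character(labels), sep = "\t"), path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `set_id`, `description`, then one field per member gene. Duplicate
#' members within a set are dropped with a warning; lines with fewer
#' than three fields are a format error.
#'
#' @param path Path to the GMT file.
#' @return Named list of gene sets; each element is a list with
#'   `description` and `members` (unique character vector). An empty
#'   file yields an empty list.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(structure(list(), names = character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("GMT line ", bad[1L], " has fewer than 3 fields")
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate gene-set identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  sets <- lapply(fields, function(f) {
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("duplicate members in gene set '", f[1L], "' deduplicated")
      members <- unique(members)
    }
    if (!length(members))
      stop("gene set '", f[1L], "' has no members")
    list(description = f[2L], members = members)
  })
  names(sets) <- ids
  sets
}

#' Write a relative-importance table to TSV
#'
#' Columns: rank, gene, RI_raw, RI_normalized.
#'
#' @param ri Data frame as produced by [mcfs()] (component `ri`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ri_table <- function(ri, path) {
  stopifnot(all(c("rank", "gene", "ri_raw", "ri_normalized") %in% names(ri)))
  out <- data.frame(rank = ri$rank, gene = ri$gene, RI_raw = ri$ri_raw,
                    RI_normalized = ri$ri_normalized)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a relative-importance table written by [write_ri_table()]
#'
#' @param path Path to the RI TSV.
#' @return Data frame with columns rank, gene, ri_raw, ri_normalized.
#' @export
read_ri_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(rank = d$rank, gene = d$gene, ri_raw = d$RI_raw,
             ri_normalized = d$RI_normalized)
}

#' Write an incremental-feature-selection curve to TSV
#'
#' Columns: k (number of top-ranked genes used) and accuracy (LOOCV).
#'
#' @param curve Data frame with columns `k` and `accuracy`, or an
#'   [ifs()] object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ifs_curve <- function(curve, path) {
  if (inherits(curve, "ifs")) curve <- curve$points
  stopifnot(all(c("k", "accuracy") %in% names(curve)))
  utils::write.table(curve[c("k", "accuracy")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an enrichment table to TSV
#'
#' @param rows Data frame from [enrich_all()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_enrichment <- function(rows, path) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
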