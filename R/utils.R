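#' @keywords internal
"_PACKAGE"

## Counter-based seed derivation: every stochastic stage draws its own seed
## from (master, stage, counter) so results do not depend on execution order.
## All intermediates stay < 2^53, so the arithmetic is exact in doubles.
derive_seed <- function(master, stage, counter = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, master >= 0)
  as.integer(((master %% 100000) * 69069 + stage * 7919 + counter * 104729) %%
               2147483629)
}

## Evaluate `code` under a temporary RNG state seeded with `seed`,
## restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

#' Canonicalise two-class sample labels
#'
#' Converts a character or factor vector of per-sample class tokens into a
#' factor whose first level is the positive class (the class of interest,
#' e.g. tumor-infiltrating "TIL" samples). All modelling code in the package
#' treats level 1 as positive.
#'
#' @param labels Named character vector or factor; names are sample
#'   identifiers.
#' @param positive Token to treat as the positive class. Defaults to
#'   `"TIL"` when present among the tokens, otherwise the lexicographically
#'   smallest token.
#' @return A named factor with at most two levels, level 1 = positive class.
#' @export
as_class_labels <- function(labels, positive = NULL) {
  if (length(labels) == 0L) stop("labels are empty")
  nms <- names(labels)
  tokens <- as.character(labels)
  uniq <- sort(unique(tokens))
  if (length(uniq) > 2L)
    stop("more than two class tokens present: ", paste(uniq, collapse = ", "))
  if (is.null(positive))
    positive <- if ("TIL" %in% uniq) "TIL" else uniq[1L]
  if (!positive %in% uniq)
    stop("positive class '", positive, "' not among tokens: ",
         paste(uniq, collapse = ", "))
  lev <- c(positive, setdiff(uniq, positive))
  structure(factor(tokens, levels = lev), names = nms)
}

## Check a labels vector against an expression matrix; returns labels
## reordered to the matrix column order.
align_labels <- function(x, labels) {
  if (is.null(names(labels)))
    stop("labels must be named by sample identifier")
  missing <- setdiff(colnames(x), names(labels))
  if (length(missing))
    stop("samples missing a class label: ", paste(missing, collapse = ", "))
  labels[colnames(x)]
}
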