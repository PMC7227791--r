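## End-to-end orchestration: rank -> truncate -> IFS -> peak selection ->
## enrichment (optional) -> cluster report, with a YAML-serialisable run
## manifest carrying checksums of every output.

#' Build a validated pipeline configuration
#'
#' Either pass a named list (e.g. parsed from YAML) or individual
#' arguments. Paths are checked at validation time; the single `seed`
#' is fanned out to every stochastic stage by fixed offsets.
#'
#' @param expression Path to the expression TSV.
#' @param labels Path to the labels TSV.
#' @param out_dir Output directory for result tables and the manifest.
#' @param gmt Optional path to a GMT gene-set collection.
#' @param positive Label token of the positive class (default "TIL"
#'   when present).
#' @param mcfs Named list of [mcfs()] parameters (s, t, m, u, v,
#'   train_fraction, min_leaf).
#' @param classifier Named list of [classifier_spec()] arguments.
#' @param k_max Largest IFS prefix (default `min(top_truncation,`
#'   number of genes`)`).
#' @param tie_policy Peak tie policy, `"min"` or `"max"`.
#' @param top_truncation Ranking truncation before IFS (default 500).
#' @param seed Master seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, labels, out_dir, gmt = NULL,
                            positive = NULL, mcfs = list(),
                            classifier = list(), k_max = NULL,
                            tie_policy = "min", top_truncation = 500L,
                            seed = 1L) {
  if (!file.exists(expression))
    stop("expression file not found: ", expression)
  if (!file.exists(labels)) stop("labels file not found: ", labels)
  if (!is.null(gmt) && !file.exists(gmt))
    stop("GMT file not found: ", gmt)
  if (!tie_policy %in% c("min", "max"))
    stop("tie_policy must be 'min' or 'max'")
  structure(list(expression = expression, labels = labels,
                 out_dir = out_dir, gmt = gmt, positive = positive,
                 mcfs = mcfs, classifier = classifier,
                 k_max = if (is.null(k_max)) NULL else as.integer(k_max),
                 tie_policy = tie_policy,
                 top_truncation = as.integer(top_truncation),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML fields mirror [pipeline_config()] argument-for-argument.
#'
#' @param path Path to the YAML file.
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes Monte Carlo ranking, top-500 truncation, incremental feature
#' selection with LOOCV, peak selection, optional over-representation
#' analysis, and the cluster report, writing each stage's table under
#' `out_dir` and a `manifest.yaml` with the configuration embedded
#' verbatim and an MD5 checksum per output file. Reruns with an
#' identical configuration reproduce identical checksums.
#'
#' @param config A `pipeline_config` (or a path to a YAML config).
#' @return Invisibly, the manifest as a named list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) message("[mcfsel] ", ...)

  x <- .stage("read_expression", read_expression_tsv(config$expression))
  y <- .stage("read_labels", {
    l <- read_labels(config$labels, positive = config$positive)
    align_labels(x, l)
  })
  log_stage("input: ", nrow(x), " genes x ", ncol(x), " samples (",
            paste(table(y), collapse = "/"), ")")

  fit <- .stage("mcfs_rank",
                do.call(mcfs, c(list(x = x, labels = y,
                                     seed = derive_seed(config$seed, 10L)),
                                config$mcfs)))
  ranked <- truncate_top(rank_genes(fit),
                         min(config$top_truncation, nrow(x)))
  log_stage("ranked ", nrow(x), " genes; kept top ", length(ranked))

  cls <- do.call(classifier_spec, config$classifier)
  k_max <- if (is.null(config$k_max)) length(ranked)
           else min(config$k_max, length(ranked))
  curve <- .stage("ifs",
                  ifs(x, y, ranked, k_max = k_max, classifier = cls,
                      tie_policy = config$tie_policy))
  log_stage("IFS peak accuracy ", format(max(curve$points$accuracy),
                                         digits = 4),
            "; selected k = ", curve$selected_k)

  enr <- NULL
  if (!is.null(config$gmt)) {
    enr <- .stage("enrichment", {
      sets <- read_gmt(config$gmt)
      enrich_all(curve$selected_genes, sets, rownames(x))
    })
    log_stage("enrichment over ", nrow(enr), " gene sets")
  }

  report <- .stage("reporting",
                   cluster_for_heatmap(
                     x[curve$selected_genes, , drop = FALSE], y))
  log_stage("cluster report: ", report$misplaced_count,
            " samples off their cluster majority class")

  out <- function(f) file.path(config$out_dir, f)
  files <- c(ri = out("ri.tsv"), ifs_curve = out("ifs_curve.tsv"),
             selected_genes = out("selected_genes.txt"),
             cluster_report = out("cluster_report.tsv"))
  write_ri_table(fit$ri, files[["ri"]])
  write_ifs_curve(curve, files[["ifs_curve"]])
  writeLines(curve$selected_genes, files[["selected_genes"]])
  write_cluster_report(report, files[["cluster_report"]])
  if (!is.null(enr)) {
    files <- c(files, enrichment = out("enrichment.tsv"))
    write_enrichment(enr, files[["enrichment"]])
  }

  manifest <- list(
    package = as.character(utils::packageVersion("mcfsel")),
    config = unclass(config),
    stages = list(
      input = list(genes = nrow(x), samples = ncol(x)),
      mcfs_rank = list(trees = fit$config$s * fit$config$t,
                       m = fit$config$m),
      ifs = list(k_max = k_max,
                 peak_accuracy = max(curve$points$accuracy),
                 selected_k = curve$selected_k),
      reporting = list(misplaced_count = report$misplaced_count)),
    outputs = lapply(stats::setNames(as.list(files), names(files)),
                     function(f) list(path = f,
                                      md5 = unname(tools::md5sum(f)))))
  yaml::write_yaml(manifest, file.path(config$out_dir, "manifest.yaml"))
  invisible(manifest)
}
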