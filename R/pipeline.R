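# End-to-end orchestration: skew -> split -> diff -> categorize -> enrich on
# two expression cohorts, and/or tails -> methylation link on one cohort with
# matched methylation. Identical config + seed gives identical artifacts.

#' Assemble a pipeline configuration
#'
#' Inputs may be in-memory objects (matrices, annotation data.frame, gene-set
#' list) or file paths (TSV / GMT), mixed freely. The skew-difference branch
#' needs `first` and `second`; the methylation branch needs `first`,
#' `methylation` and `annotation`.
#'
#' @param first,second gene x sample expression matrices or TSV paths.
#' @param methylation probe x sample methylation matrix or TSV path.
#' @param methylation_is_beta logical; convert beta-values to M-values first.
#' @param annotation probe annotation data.frame or TSV path.
#' @param gene_sets named list of gene sets or GMT path.
#' @param unbiased apply the third-moment bias correction.
#' @param tail_method "quantile" or "gaussian"; `q`, `z_threshold` its
#'   parameters.
#' @param alpha_probe per-probe adjusted-p level (default 0.01).
#' @param alpha_enrich enrichment adjusted-p level (default 0.05).
#' @param top_n genes selected by methylation significance (default 500).
#' @param force_k3 use the K = 3 mixture fit for categories (default TRUE).
#' @param seed integer seed for the mixture restarts.
#' @param outdir optional directory; artifacts are written there as TSV/JSON.
#' @return list of class "pipeline_config".
#' @export
pipeline_config <- function(first, second = NULL, methylation = NULL,
                            methylation_is_beta = FALSE, annotation = NULL,
                            gene_sets = NULL, unbiased = FALSE,
                            tail_method = "quantile", q = 0.1,
                            z_threshold = 2.5, alpha_probe = 0.01,
                            alpha_enrich = 0.05, top_n = 500,
                            force_k3 = TRUE, seed = 1L, outdir = NULL) {
  if (alpha_probe <= 0 || alpha_probe >= 1 || alpha_enrich <= 0 || alpha_enrich >= 1) {
    stop("significance thresholds must lie in (0, 1)")
  }
  cfg <- list(first = first, second = second, methylation = methylation,
              methylation_is_beta = methylation_is_beta,
              annotation = annotation, gene_sets = gene_sets,
              unbiased = unbiased, tail_method = tail_method, q = q,
              z_threshold = z_threshold, alpha_probe = alpha_probe,
              alpha_enrich = alpha_enrich, top_n = top_n,
              force_k3 = force_k3, seed = as.integer(seed), outdir = outdir)
  # resolve every referenced path up front so failures precede any compute
  for (nm in c("first", "second", "methylation")) {
    if (is.character(cfg[[nm]]) && !file.exists(cfg[[nm]])) {
      stop(nm, " file not found: ", cfg[[nm]])
    }
  }
  if (is.character(cfg$annotation) && !file.exists(cfg$annotation)) {
    stop("annotation file not found: ", cfg$annotation)
  }
  if (is.character(cfg$gene_sets) && !file.exists(cfg$gene_sets)) {
    stop("gene_sets file not found: ", cfg$gene_sets)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

resolve_input <- function(x, reader) {
  if (is.character(x)) reader(x) else x
}

#' Run the skewness analysis pipeline
#'
#' Executes the configured stages and returns all intermediate and final
#' results plus a run report of per-stage record counts. When `outdir` is
#' set, artifacts are additionally written as TSV (tables) and JSON (report).
#'
#' @param config a [pipeline_config()].
#' @return list with (depending on configured stages) skew_first,
#'   skew_second, split_first, split_second, diff, mixture, categories,
#'   enrichment, pathway_summary, tails, probe_results, gene_summaries,
#'   top_genes, quadrants, correlations, and `report`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  report <- list(seed = config$seed)

  first <- resolve_input(config$first, function(p) read_matrix(p, "expression"))
  res$skew_first <- compute_skewness(first, config$unbiased)
  res$split_first <- gene_split(res$skew_first)
  report$n_genes_first <- nrow(res$skew_first)

  if (!is.null(config$second)) {
    second <- resolve_input(config$second, function(p) read_matrix(p, "expression"))
    res$skew_second <- compute_skewness(second, config$unbiased)
    res$split_second <- gene_split(res$skew_second)
    res$diff <- skew_difference(res$skew_first, res$skew_second)
    report$n_genes_shared <- nrow(res$diff)
    res$mixture <- fit_skew_mixture(res$diff, seed = config$seed)
    report$selected_k <- res$mixture$selected_k
    res$categories <- assign_categories(res$mixture, force_k3 = config$force_k3)
    report$category_counts <- as.list(table(res$categories$category))
    if (!is.null(config$gene_sets)) {
      sets <- resolve_input(config$gene_sets, read_gmt)
      res$enrichment <- overrepresentation_test(res$categories, sets,
                                                alpha = config$alpha_enrich)
      res$pathway_summary <- summarize_top_pathways(res$enrichment)
      report$n_enrichment_tests <- nrow(res$enrichment)
    }
  }

  if (!is.null(config$methylation)) {
    if (is.null(config$annotation)) {
      stop("methylation analysis requires a probe annotation")
    }
    meth <- resolve_input(config$methylation,
                          function(p) read_matrix(p, "methylation"))
    if (config$methylation_is_beta) meth <- beta_to_mvalue(meth)
    ann <- resolve_input(config$annotation, read_annotation)
    res$tails <- tail_split_cohort(first, res$skew_first,
                                   method = config$tail_method,
                                   q = config$q,
                                   z_threshold = config$z_threshold)
    report$n_genes_with_tails <- length(res$tails)
    res$probe_results <- probe_dm_test(meth, res$tails, ann)
    report$n_probes_tested <- nrow(res$probe_results)
    res$gene_summaries <- summarize_genes(res$probe_results, res$skew_first,
                                          alpha = config$alpha_probe)
    res$top_genes <- select_top_genes(res$gene_summaries, config$top_n)
    report$n_top_genes <- nrow(res$top_genes)
    res$quadrants <- quadrant_analysis(res$top_genes)
    res$correlations <- do.call(rbind, lapply(
      c("All", "Promoter", "UTR", "Body"),
      function(reg) tryCatch(correlation_with_ci(res$top_genes, reg),
                             error = function(e) NULL)
    ))
  }

  res$report <- report
  if (!is.null(config$outdir)) write_pipeline_artifacts(res, config$outdir)
  res
}

write_pipeline_artifacts <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(outdir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$skew_first)) wt(res$skew_first, "skew_first.tsv")
  if (!is.null(res$skew_second)) wt(res$skew_second, "skew_second.tsv")
  if (!is.null(res$diff)) wt(res$diff, "skew_difference.tsv")
  if (!is.null(res$categories)) wt(res$categories, "categories.tsv")
  if (!is.null(res$enrichment)) wt(res$enrichment, "enrichment.tsv")
  if (!is.null(res$pathway_summary)) wt(res$pathway_summary, "pathway_summary.tsv")
  if (!is.null(res$probe_results)) wt(res$probe_results, "probe_results.tsv")
  if (!is.null(res$gene_summaries)) wt(res$gene_summaries, "gene_summaries.tsv")
  if (!is.null(res$correlations)) wt(res$correlations, "correlations.tsv")
  jsonlite::write_json(res$report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
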