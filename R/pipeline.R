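#' Pipeline configuration
#'
#' One configuration object drives the full analysis: either paths to real
#' inputs (`allele_counts`, `gene_counts`, `models`, `samples`, optionally
#' `term_map` and `external_list`) or a [sim_config()] for synthetic mode.
#' Analysis parameters default to the published settings: `alpha` 0.05,
#' `bcv` 0.1, twofold ASE criterion, `min_module_size` 80, eigengene merge
#' cut 0.3, GS/MM hub thresholds 0.2/0.8, edge weight 0.3, low-expression
#' filter at FPKM 5 and class boundaries 5/20/100.
#'
#' @param sim A [sim_config()] for synthetic mode, or `NULL`.
#' @param paths Named list of input file paths for real-data mode.
#' @param alpha,bcv,fold,floor,min_module_size,merge_cut_height,gs_min,mm_min,edge_weight_min,fpkm_filter,class_breaks,power
#'   Stage parameters (see the stage functions).
#' @param seed Integer seed controlling all randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = NULL, paths = NULL, alpha = 0.05, bcv = 0.1,
                            fold = 2, floor = 0.5, min_module_size = 80,
                            merge_cut_height = 0.3, gs_min = 0.2, mm_min = 0.8,
                            edge_weight_min = 0.3, fpkm_filter = 5,
                            class_breaks = c(5, 20, 100), power = NULL,
                            seed = 1) {
  if (is.null(sim) && is.null(paths)) {
    stop_hd("either a sim_config or input paths must be given",
            class = "haplodyn_config_error")
  }
  structure(list(sim = sim, paths = paths, alpha = alpha, bcv = bcv,
                 fold = fold, floor = floor,
                 min_module_size = min_module_size,
                 merge_cut_height = merge_cut_height, gs_min = gs_min,
                 mm_min = mm_min, edge_weight_min = edge_weight_min,
                 fpkm_filter = fpkm_filter, class_breaks = class_breaks,
                 power = power, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input loading or simulation,
#' quantification (FPKM, expression classes, sample correlation),
#' differential expression, ASE trajectory classification, co-expression
#' network with hub screening, ASE-connectivity intersection, and (when a
#' term map / external list is supplied) enrichment and external-list
#' overlap. Reruns with an identical config reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, stage outputs are written
#'   as TSV plus a JSON run summary.
#' @param verbose Log stage progress to stderr.
#' @return List of class `hd_pipeline` with elements `inputs`, `fpkm`,
#'   `classes`, `sample_cor`, `de`, `ase`, `network`, `hubs`,
#'   `ase_connectivity`, `enrichment`, `external_overlap`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hd(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  inputs <- stage("inputs", {
    if (!is.null(config$sim)) {
      say("simulating synthetic experiment (seed %d)", config$sim$seed)
      sim <- simulate_experiment(config$sim)
      list(allele_counts = sim$allele_counts, gene_counts = sim$gene_counts,
           models = sim$models, samples = sim$samples, truth = sim$truth,
           term_map = NULL, external = NULL)
    } else {
      p <- config$paths
      list(
        allele_counts = if (!is.null(p$allele_counts))
          read_count_matrix(p$allele_counts, "allele") else NULL,
        gene_counts = read_count_matrix(p$gene_counts, "gene"),
        models = read_gene_models(p$models),
        samples = read_sample_sheet(p$samples),
        truth = NULL,
        term_map = if (!is.null(p$term_map)) read_term_map(p$term_map) else NULL,
        external = if (!is.null(p$external_list)) read_gene_list(p$external_list) else NULL
      )
    }
  })

  say("quantifying (FPKM)")
  expr <- stage("fpkm", fpkm(inputs$gene_counts, models = inputs$models))
  classes <- stage("expression_classes",
                   expression_classes(expr, breaks = config$class_breaks))
  sample_cor <- stage("sample_correlation", sample_correlation(expr))

  say("differential expression")
  de <- stage("diffexpr", run_de(inputs$gene_counts, inputs$samples,
                                 alpha = config$alpha, bcv = config$bcv))

  ase <- NULL
  if (!is.null(inputs$allele_counts)) {
    say("allele-specific expression")
    ase <- stage("ase", run_ase(inputs$allele_counts, inputs$models,
                                inputs$samples, fold = config$fold,
                                floor = config$floor))
  }

  say("co-expression network")
  keep <- low_expression_filter(expr, threshold = config$fpkm_filter)
  network <- stage("network", build_coexpression_network(
    expr[keep, , drop = FALSE], inputs$samples, power = config$power,
    min_module_size = config$min_module_size,
    merge_cut_height = config$merge_cut_height))
  hubs <- NULL
  if (!is.null(network$eigengenes)) {
    hubs <- stage("hub_screen", hub_screen(
      network, gs_min = config$gs_min, mm_min = config$mm_min,
      edge_weight_min = config$edge_weight_min))
  }

  ase_conn <- NULL
  if (!is.null(ase) && !is.null(hubs)) {
    sets <- list(
      salt_specific = setdiff(ase$sets$salt_union, ase$sets$drought_union),
      drought_specific = setdiff(ase$sets$drought_union, ase$sets$salt_union),
      both = intersect(ase$sets$salt_union, ase$sets$drought_union))
    ase_conn <- stage("ase_connectivity",
                      ase_network_overlap(sets, hubs$edge_counts))
  }

  enrichment <- NULL
  if (!is.null(inputs$term_map)) {
    universe <- keep
    interest <- intersect(unique(c(de$summary$union_up, de$summary$union_down)),
                          universe)
    enrichment <- stage("enrichment",
                        fisher_enrich(interest, universe, inputs$term_map,
                                      alpha = config$alpha))
  }
  external_overlap <- NULL
  if (!is.null(inputs$external) && !is.null(ase)) {
    external_overlap <- stage("external_overlap", external_list_overlap(
      ase$sets$salt_union, ase$sets$drought_union, inputs$external))
  }

  out <- structure(list(inputs = inputs, fpkm = expr, classes = classes,
                        sample_cor = sample_cor, de = de, ase = ase,
                        network = network, hubs = hubs,
                        ase_connectivity = ase_conn, enrichment = enrichment,
                        external_overlap = external_overlap, config = config),
                   class = "hd_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

write_pipeline_outputs <- function(x, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  w <- function(df, f) readr::write_tsv(df, file.path(out_dir, f))
  fp <- x$fpkm
  w(tibble::as_tibble(as.data.frame(fp), rownames = "gene_id"), "fpkm.tsv")
  w(x$classes, "expression_classes.tsv")
  dendrogram_newick(x$sample_cor, file.path(out_dir, "sample_dendrogram.nwk"))
  w(x$de$results, "de_results.tsv")
  w(x$de$summary$counts, "de_counts.tsv")
  if (!is.null(x$ase)) {
    traj <- dplyr::mutate(x$ase$trajectories,
                          dplyr::across(dplyr::where(is.factor), as.character))
    w(traj, "ase_trajectories.tsv")
    w(x$ase$summary$categories, "ase_categories.tsv")
    w(x$ase$summary$responsiveness, "ase_responsiveness.tsv")
  }
  w(x$network$modules, "modules.tsv")
  if (!is.null(x$network$module_trait)) w(x$network$module_trait, "module_trait.tsv")
  if (!is.null(x$hubs)) {
    w(x$hubs$edges, "edges.tsv")
    w(x$hubs$hubs, "hubs.tsv")
    w(x$hubs$edge_counts, "edge_counts.tsv")
  }
  if (!is.null(x$ase_connectivity)) w(x$ase_connectivity, "ase_connectivity.tsv")
  if (!is.null(x$enrichment)) w(x$enrichment, "enrichment.tsv")
  summary <- list(
    seed = x$config$seed,
    config_hash = rlang::hash(unclass(x$config)),
    n_genes = nrow(x$inputs$gene_counts),
    n_samples = ncol(x$inputs$gene_counts),
    de_counts = x$de$summary$counts,
    ase_responsiveness = if (!is.null(x$ase)) x$ase$summary$responsiveness,
    n_modules = if (!is.null(x$network$eigengenes)) ncol(x$network$eigengenes) else 0L
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}
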