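#' Run the module-network pipeline for one disease condition
#'
#' Restricts the dataset to the normal condition plus `condition`, selects
#' the top `n_feature_genes` by pairwise moderated differential expression
#' (BH-adjusted p ascending; all genes with a warning when fewer are
#' available), infers co-expression modules by pooling `gibbs_runs`
#' independent Gibbs chains (run `r` seeded with `seed + r`) and tightening
#' the consensus spectrally, builds each module's sample partition tree,
#' scores every candidate TF per module by the regulatory-program and
#' impact-factor routes, intersects and integrates them, computes module
#' significance scores with knee-point selection, and assembles the
#' condition network over the selected modules. All randomness derives from
#' `config$seed`, so a fixed seed reproduces the bundle exactly.
#'
#' @param dataset an [expression_dataset()].
#' @param tfs candidate regulator ids (present in the dataset).
#' @param config a [pipeline_config()].
#' @param condition a non-normal condition label.
#' @param verbose log stage-by-stage counts via `message()`.
#' @return a `condition_result` list: `condition`, `dataset` (the pair
#'   subset), `feature_genes`, `de`, `fuzzy`, `modules` (with per-module
#'   `sample_tree`), `regulators` (long table over modules x TFs),
#'   `module_scores`, `selected_modules`, `network` (condition edge list),
#'   `de_direction`.
#' @export
run_condition_pipeline <- function(dataset, tfs, config = pipeline_config(),
                                   condition, verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  sub <- subset_condition_pair(dataset, condition)
  normal <- samples_of(sub, sub$normal_label)
  disease <- samples_of(sub, condition)
  say("[%s] %d samples (%d normal, %d %s), %d genes", condition,
      ncol(sub$matrix), length(normal), length(disease), condition,
      nrow(sub$matrix))

  de <- moderated_de(sub, disease, normal)
  o <- order(de$adj_p_value, rownames(de))
  n_feat <- config$n_feature_genes
  if (nrow(de) < n_feat) {
    warning(sprintf("only %d genes available (< n_feature_genes = %d); using all",
                    nrow(de), n_feat))
    n_feat <- nrow(de)
  }
  feature_genes <- rownames(de)[o][seq_len(n_feat)]
  say("[%s] feature selection: top %d genes by pairwise DE", condition, n_feat)

  # row-center: the block score's prior mean is 0, and clustering should see
  # shape, not absolute abundance (abundance re-enters via RIF)
  centered <- sub$matrix - rowMeans(sub$matrix)
  expr <- centered[feature_genes, , drop = FALSE]
  states <- lapply(seq_len(config$gibbs_runs) - 1L, function(r)
    gibbs_cluster(expr, config$block_params, config$burn_in,
                  config$gibbs_steps, seed = config$seed + r))
  fuzzy <- build_fuzzy(states)
  modules <- tight_clusters(fuzzy, config$prob_cutoff,
                            config$min_module_size, seed = config$seed)
  say("[%s] module inference: %d Gibbs runs -> %d tight modules (%d genes)",
      condition, config$gibbs_runs, length(modules$modules),
      sum(lengths(modules$modules)))

  modules$sample_tree <- lapply(modules$modules, partition_samples,
                                data = centered,
                                params = config$block_params)
  tf_matrix <- centered[tfs, , drop = FALSE]
  reg_rows <- lapply(names(modules$modules), function(mid) {
    lrp <- lrp_scores(modules$sample_tree[[mid]], tf_matrix,
                      config$block_params)
    rif <- rif_scores(sub, tfs, modules$modules[[mid]], normal, disease)
    tab <- suppressWarnings(combine_regulators(lrp, rif, config$top_q))
    cbind(condition = condition, module = mid, tab)
  })
  regulators <- if (length(reg_rows) > 0) do.call(rbind, reg_rows) else
    data.frame(condition = character(), module = character(),
               TF = character(), lrp_score = numeric(), RIF1 = numeric(),
               RIF2 = numeric(), z1 = numeric(), z2 = numeric(),
               stdScore = numeric(), in_intersection = logical(),
               rank = integer())
  say("[%s] regulators: %d TFs scored, %d intersected (TF, module) pairs",
      condition, length(tfs), sum(regulators$in_intersection))

  module_scores <- score_modules(modules, de, sub$matrix)
  selected <- module_scores$module[module_scores$selected]
  say("[%s] ranking: %d best modules of %d", condition, length(selected),
      nrow(module_scores))

  network <- build_condition_network(modules$modules[selected], regulators,
                                     condition)
  de_direction <- stats::setNames(
    ifelse(de$adj_p_value < config$fdr_alpha,
           ifelse(de$effect > 0, "up", "down"), "no-change"),
    rownames(de))
  say("[%s] network: %d edges", condition, nrow(network))

  structure(list(condition = condition, dataset = sub,
                 feature_genes = feature_genes, de = de, fuzzy = fuzzy,
                 modules = modules, regulators = regulators,
                 module_scores = module_scores,
                 selected_modules = selected, network = network,
                 de_direction = de_direction),
            class = "condition_result")
}

#' Run every condition and aggregate
#'
#' Calls [run_condition_pipeline()] for each non-normal condition and
#' aggregates the condition networks, overlap analysis and best-module
#' summary.
#'
#' @inheritParams run_condition_pipeline
#' @return a `pipeline_result` list: `conditions` (named list of
#'   `condition_result`), `network` (an `aggregated_network`), `overlap`,
#'   `summary` (best-module summary table).
#' @export
run_full_pipeline <- function(dataset, tfs, config = pipeline_config(),
                              verbose = TRUE) {
  dz <- setdiff(conditions(dataset), dataset$normal_label)
  results <- lapply(stats::setNames(dz, dz), function(cn)
    run_condition_pipeline(dataset, tfs, config, cn, verbose))
  de_dir <- unlist(lapply(rev(results), function(r) r$de_direction))
  names(de_dir) <- sub("^[^.]*\\.", "", names(de_dir))
  de_dir <- de_dir[!duplicated(names(de_dir))]
  net <- aggregate_networks(lapply(results, function(r) r$network),
                            tf_universe = tfs, de_direction = de_dir)
  selections <- lapply(results, function(r) {
    reg <- r$regulators
    list(total_modules = nrow(r$module_scores),
         modules = r$modules$modules[r$selected_modules],
         tfs = unique(reg$TF[reg$in_intersection &
                               reg$module %in% r$selected_modules]))
  })
  structure(list(conditions = results, network = net,
                 overlap = overlap_analysis(net),
                 summary = best_module_summary(selections)),
            class = "pipeline_result")
}
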