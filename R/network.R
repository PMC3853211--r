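#' Build the TF-to-target edge list for one condition
#'
#' For each selected module, every intersected regulator of that module is
#' connected to every member gene (a regulator that is itself a member is
#' not emitted as its own target).
#'
#' @param modules named list of module gene sets (the selected modules).
#' @param regulator_table data.frame with columns `module`, `TF`,
#'   `stdScore`, `in_intersection` (rows for this condition).
#' @param condition condition label stamped on every edge.
#' @return data.frame (TF, TG, condition, module, stdScore); zero rows is
#'   valid.
#' @export
build_condition_network <- function(modules, regulator_table, condition) {
  need <- c("module", "TF", "stdScore", "in_intersection")
  stopifnot(all(need %in% names(regulator_table)))
  reg <- regulator_table[regulator_table$in_intersection, , drop = FALSE]
  rows <- list()
  for (mid in names(modules)) {
    tfs <- reg[reg$module == mid, , drop = FALSE]
    if (nrow(tfs) == 0) next
    members <- modules[[mid]]
    for (i in seq_len(nrow(tfs))) {
      tg <- setdiff(members, tfs$TF[i])
      if (length(tg) == 0) next
      rows[[length(rows) + 1L]] <-
        data.frame(TF = tfs$TF[i], TG = tg, condition = condition,
                   module = mid, stdScore = tfs$stdScore[i],
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(TF = character(), TG = character(),
                      condition = character(), module = character(),
                      stdScore = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Aggregate condition-specific networks
#'
#' Concatenates condition-tagged edge lists. Edges are condition-scoped
#' records: an interaction present in two conditions contributes two edges,
#' so the aggregated edge count is exactly the sum of the per-condition
#' counts. Node attributes (type, condition membership, modules, DE
#' direction) are derived for export.
#'
#' @param condition_edges list of edge data.frames from
#'   [build_condition_network()].
#' @param tf_universe optional candidate-regulator id set; defaults to the
#'   ids observed in the TF column. Nodes in this set are typed `TF` even
#'   where they appear as targets.
#' @param de_direction optional named character vector (`up` / `down` /
#'   `no-change`) per gene.
#' @return an `aggregated_network`: `edges` (TF, TG, condition, module,
#'   stdScore) and `nodes` (id, type, conditions, modules,
#'   n_modules_regulated, de_direction).
#' @export
aggregate_networks <- function(condition_edges, tf_universe = NULL,
                               de_direction = NULL) {
  stopifnot(length(condition_edges) >= 1)
  edges <- do.call(rbind, condition_edges)
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(TF = character(), TG = character(),
                        condition = character(), module = character(),
                        stdScore = numeric(), stringsAsFactors = FALSE)
  }
  key <- paste(edges$TF, edges$TG, edges$condition, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (TF, TG, condition) edge - upstream bug")
  if (is.null(tf_universe)) tf_universe <- unique(edges$TF)

  ids <- sort(unique(c(edges$TF, edges$TG)))
  cond_of <- function(id) {
    sort(unique(edges$condition[edges$TF == id | edges$TG == id]))
  }
  nodes <- do.call(rbind, lapply(ids, function(id) {
    is_tf <- id %in% tf_universe
    mods_reg <- unique(paste(edges$condition, edges$module, sep = "/")[edges$TF == id])
    mods_mem <- unique(paste(edges$condition, edges$module, sep = "/")[edges$TG == id])
    data.frame(id = id, type = if (is_tf) "TF" else "TG",
               conditions = paste(cond_of(id), collapse = ","),
               modules = paste(sort(if (is_tf) mods_reg else mods_mem),
                               collapse = ","),
               n_modules_regulated = length(mods_reg),
               de_direction = if (!is.null(de_direction) && id %in% names(de_direction))
                 de_direction[[id]] else "no-change",
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes))
    nodes <- data.frame(id = character(), type = character(),
                        conditions = character(), modules = character(),
                        n_modules_regulated = integer(),
                        de_direction = character(), stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes), class = "aggregated_network")
}

#' @export
print.aggregated_network <- function(x, ...) {
  cat(sprintf("aggregated_network: %d edges, %d nodes (%d TF, %d TG), %d condition(s)\n",
              nrow(x$edges), nrow(x$nodes), sum(x$nodes$type == "TF"),
              sum(x$nodes$type == "TG"),
              length(unique(x$edges$condition))))
  invisible(x)
}

#' Condition-overlap analysis of an aggregated network
#'
#' For TFs, target genes, and interactions (keyed by the TF-target pair),
#' reports the set of conditions each element appears in and the counts of
#' elements shared by exactly 1, 2, ..., C conditions.
#'
#' @param network an `aggregated_network`.
#' @return list with elements `tf`, `tg`, `edge`, each a list of
#'   `membership` (named list of condition sets) and `shared_by` (named
#'   integer vector over sharing classes `1..C`).
#' @export
overlap_analysis <- function(network) {
  edges <- network$edges
  n_cond <- length(unique(edges$condition))
  summarize <- function(keys) {
    membership <- lapply(split(edges$condition, keys), function(x) sort(unique(x)))
    sizes <- lengths(membership)
    shared <- vapply(seq_len(max(1L, n_cond)), function(k) sum(sizes == k), 0L)
    names(shared) <- as.character(seq_along(shared))
    list(membership = membership, shared_by = shared)
  }
  list(tf = summarize(edges$TF),
       tg = summarize(edges$TG),
       edge = summarize(paste(edges$TF, edges$TG, sep = "->")))
}

#' Jaccard similarity of two gene sets
#'
#' `|A intersect B| / |A union B|`; symmetric, 1 iff the sets are equal.
#'
#' @param moduleA,moduleB id vectors; at least one must be nonempty.
#' @return a number in \[0, 1\].
#' @export
module_similarity <- function(moduleA, moduleB) {
  a <- unique(moduleA); b <- unique(moduleB)
  if (length(a) == 0 && length(b) == 0) stop("both sets are empty")
  length(intersect(a, b)) / length(union(a, b))
}

#' Jaccard similarity of two enriched-term sets
#'
#' Same formula as [module_similarity()], applied to the significantly
#' enriched terms of two modules.
#'
#' @param termsA,termsB term id vectors.
#' @return a number in \[0, 1\].
#' @export
term_similarity <- function(termsA, termsB) module_similarity(termsA, termsB)

#' Per-condition best-module summary with totals
#'
#' @param selections named list (one entry per condition), each a list with
#'   `total_modules` (count), `modules` (named list of best-module gene
#'   sets) and `tfs` (regulator ids of those modules).
#' @return data.frame with one row per condition, a `Total` row summing the
#'   per-condition counts, and a `Unique` row counting distinct elements
#'   across conditions. Columns: condition, total_modules, best_modules,
#'   genes, tfs, tgs.
#' @export
best_module_summary <- function(selections) {
  per_cond <- lapply(names(selections), function(cn) {
    s <- selections[[cn]]
    genes <- unique(unlist(s$modules, use.names = FALSE))
    tfs <- unique(s$tfs)
    data.frame(condition = cn, total_modules = s$total_modules,
               best_modules = length(s$modules), genes = length(genes),
               tfs = length(tfs), tgs = length(setdiff(genes, tfs)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_cond)
  total <- data.frame(condition = "Total",
                      total_modules = sum(out$total_modules),
                      best_modules = sum(out$best_modules),
                      genes = sum(out$genes), tfs = sum(out$tfs),
                      tgs = sum(out$tgs), stringsAsFactors = FALSE)
  all_genes <- unique(unlist(lapply(selections, function(s)
    unlist(s$modules, use.names = FALSE))))
  all_tfs <- unique(unlist(lapply(selections, function(s) s$tfs)))
  uniq <- data.frame(condition = "Unique",
                     total_modules = sum(out$total_modules),
                     best_modules = sum(out$best_modules),
                     genes = length(all_genes), tfs = length(all_tfs),
                     tgs = length(setdiff(all_genes, all_tfs)),
                     stringsAsFactors = FALSE)
  rbind(out, total, uniq)
}

#' Export an aggregated network in Cytoscape-compatible form
#'
#' Writes `network.sif` (`TF<TAB>regulates<TAB>TG`), `node_attributes.tsv`
#' and `edge_attributes.tsv` with deterministic (lexicographic) row order,
#' so re-exporting a re-imported network is byte-identical.
#'
#' @param network an `aggregated_network`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the three file paths.
#' @export
export_network <- function(network, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  e <- network$edges[order(network$edges$TF, network$edges$TG,
                           network$edges$condition), , drop = FALSE]
  sif_path <- file.path(out_dir, "network.sif")
  sif <- unique(data.frame(TF = e$TF, edge = "regulates", TG = e$TG,
                           stringsAsFactors = FALSE))
  utils::write.table(sif, sif_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  node_path <- file.path(out_dir, "node_attributes.tsv")
  n <- network$nodes[order(network$nodes$id), , drop = FALSE]
  utils::write.table(n, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  edge_path <- file.path(out_dir, "edge_attributes.tsv")
  ea <- data.frame(TF = e$TF, TG = e$TG, condition = e$condition,
                   stdScore = sprintf("%.17g", e$stdScore),
                   stringsAsFactors = FALSE)
  utils::write.table(ea, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(sif_path, node_path, edge_path))
}
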