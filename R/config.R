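#' Pipeline configuration
#'
#' Collects the tunable parameters of the per-condition pipeline. Defaults
#' follow the workflow's stated settings: top 4000 differentially expressed
#' genes per normal/condition pair, 10 Gibbs clustering runs of 50 burn-in
#' plus 100 recorded sweeps each, minimum module size 4, assignment
#' probability cutoff 0.2, and FDR level 0.05.
#'
#' @param n_feature_genes genes kept by per-pair differential expression.
#' @param gibbs_runs number of independent Gibbs chains pooled.
#' @param burn_in discarded sweeps per chain.
#' @param gibbs_steps recorded sweeps per chain.
#' @param min_module_size smallest tight module retained.
#' @param prob_cutoff minimum mean co-clustering of a gene with its module.
#' @param fdr_alpha Benjamini-Hochberg FDR level.
#' @param seed integer seed; every stochastic stage derives from it.
#' @param block_params Normal-Gamma prior, see [block_score_params()].
#' @param top_q fraction of a module's positively scored regulators counted
#'   as identified by the regulatory-program route.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_feature_genes = 4000, gibbs_runs = 10,
                            burn_in = 50, gibbs_steps = 100,
                            min_module_size = 4, prob_cutoff = 0.2,
                            fdr_alpha = 0.05, seed = 1L,
                            block_params = block_score_params(),
                            top_q = 0.25) {
  counts <- c(n_feature_genes = n_feature_genes, gibbs_runs = gibbs_runs,
              burn_in = burn_in, gibbs_steps = gibbs_steps,
              min_module_size = min_module_size)
  if (any(counts < 1)) stop("all counts must be >= 1")
  if (prob_cutoff < 0 || prob_cutoff > 1) stop("prob_cutoff must be in [0,1]")
  if (fdr_alpha <= 0 || fdr_alpha >= 1) stop("fdr_alpha must be in (0,1)")
  structure(list(n_feature_genes = as.integer(n_feature_genes),
                 gibbs_runs = as.integer(gibbs_runs),
                 burn_in = as.integer(burn_in),
                 gibbs_steps = as.integer(gibbs_steps),
                 min_module_size = as.integer(min_module_size),
                 prob_cutoff = prob_cutoff, fdr_alpha = fdr_alpha,
                 seed = as.integer(seed), block_params = block_params,
                 top_q = top_q),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a file
#'
#' Accepts JSON (`.json`) or flat `key = value` text; keys mirror the
#' arguments of [pipeline_config()]. Unknown keys are an error.
#'
#' @param path path to the configuration file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    lines <- sub("#.*$", "", readLines(path, warn = FALSE))
    lines <- lines[grepl("=", lines, fixed = TRUE)]
    kv <- strsplit(lines, "=", fixed = TRUE)
    vals <- lapply(kv, function(p) as.numeric(trimws(p[2L])))
    names(vals) <- vapply(kv, function(p) trimws(p[1L]), "")
  }
  allowed <- setdiff(names(formals(pipeline_config)), "block_params")
  bad <- setdiff(names(vals), allowed)
  if (length(bad) > 0) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}
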