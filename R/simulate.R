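#' Simulation specification
#'
#' Describes a synthetic expression study mirroring the shape of a multi-
#' condition disease microarray cohort at desk scale: one normal condition
#' plus several disease conditions, planted co-expressed gene modules whose
#' means shift in a condition-specific way, one planted regulator (TF) per
#' module tracking that module's latent profile, decoy TFs, and independent
#' background genes.
#'
#' Defaults give 1 normal + 3 disease conditions with 15 samples each,
#' 6 modules of 20 genes, 400 background genes and 24 TFs (6 planted + 18
#' decoys); shift 2 log2 units over residual sd 0.5 (signal-to-noise 4).
#'
#' @param n_conditions total conditions including normal.
#' @param samples_per_condition samples per condition.
#' @param n_modules planted co-expression modules.
#' @param genes_per_module member genes per module.
#' @param n_background_genes i.i.d. noise genes.
#' @param n_decoy_tfs TFs with no planted regulatory role.
#' @param shift per-module per-condition mean offset (log2 units). Either a
#'   single number (each module is shifted in a module-specific subset of
#'   disease conditions) or an `n_modules` x `n_conditions` matrix.
#' @param sigma residual (gene-level) noise sd, log2 units.
#' @param sigma_latent sd of the module latent profile around its mean.
#' @param regulator_noise_sd sd of planted-TF noise around the latent profile.
#' @param baseline global mean log2 expression.
#' @param seed integer seed.
#' @return a `simulation_spec` list; `shift` is stored in matrix form.
#' @export
simulation_spec <- function(n_conditions = 4, samples_per_condition = 15,
                            n_modules = 6, genes_per_module = 20,
                            n_background_genes = 400, n_decoy_tfs = 18,
                            shift = 2, sigma = 0.5, sigma_latent = 0.5,
                            regulator_noise_sd = 0.25, baseline = 8,
                            seed = 1L) {
  stopifnot(n_conditions >= 2, samples_per_condition >= 2, n_modules >= 1,
            genes_per_module >= 1, sigma > 0)
  if (!is.matrix(shift)) {
    s <- matrix(0, n_modules, n_conditions)
    # module m is shifted in disease conditions {m mod D, (m+1) mod D} so
    # conditions have both shared and specific signal
    ndz <- n_conditions - 1L
    for (m in seq_len(n_modules)) {
      c1 <- 1L + (m - 1L) %% ndz
      c2 <- 1L + m %% ndz
      sgn <- if (m %% 2 == 0) -1 else 1
      s[m, 1L + c1] <- sgn * shift
      s[m, 1L + c2] <- sgn * shift / 2
    }
    shift <- s
  }
  stopifnot(nrow(shift) == n_modules, ncol(shift) == n_conditions)
  structure(list(n_conditions = n_conditions,
                 samples_per_condition = samples_per_condition,
                 n_modules = n_modules, genes_per_module = genes_per_module,
                 n_background_genes = n_background_genes,
                 n_decoy_tfs = n_decoy_tfs, shift = shift, sigma = sigma,
                 sigma_latent = sigma_latent,
                 regulator_noise_sd = regulator_noise_sd,
                 baseline = baseline, seed = as.integer(seed),
                 snr = max(abs(shift)) / sigma),
            class = "simulation_spec")
}

#' Generate a synthetic expression dataset with ground truth
#'
#' Module m's latent profile is `baseline + shift[m, condition] +
#' N(0, sigma_latent)` per sample; each member gene adds `N(0, sigma)`
#' residual noise, the module's planted TF adds `N(0, regulator_noise_sd)`,
#' and background genes and decoy TFs are i.i.d. `N(baseline, sigma)`.
#'
#' @param spec a `simulation_spec`.
#' @return list with `dataset` (an [expression_dataset()]), `tfs` (all TF
#'   ids), and `truth`: `module_of` (named, planted module index per module
#'   gene), `tf_of_module` (planted TF id per module), `de_conditions`
#'   (per module, disease conditions where the module mean is shifted).
#' @export
simulate_dataset <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  conds <- c("normal", paste0("dz", LETTERS[seq_len(spec$n_conditions - 1L)]))
  n_s <- spec$n_conditions * spec$samples_per_condition
  condition_of <- stats::setNames(rep(conds, each = spec$samples_per_condition),
                                  sprintf("s%03d", seq_len(n_s)))
  cond_idx <- match(condition_of, conds)

  mod_genes <- outer(seq_len(spec$genes_per_module), seq_len(spec$n_modules),
                     function(i, m) sprintf("M%02dg%02d", m, i))
  bg_genes <- sprintf("BG%04d", seq_len(spec$n_background_genes))
  tf_planted <- sprintf("TFmod%02d", seq_len(spec$n_modules))
  tf_decoy <- if (spec$n_decoy_tfs > 0) sprintf("TFdecoy%02d", seq_len(spec$n_decoy_tfs)) else character()
  genes <- c(as.vector(mod_genes), bg_genes, tf_planted, tf_decoy)

  m <- matrix(NA_real_, length(genes), n_s,
              dimnames = list(genes, names(condition_of)))
  for (mod in seq_len(spec$n_modules)) {
    latent <- spec$baseline + spec$shift[mod, cond_idx] +
      stats::rnorm(n_s, 0, spec$sigma_latent)
    for (g in mod_genes[, mod])
      m[g, ] <- latent + stats::rnorm(n_s, 0, spec$sigma)
    m[tf_planted[mod], ] <- latent + stats::rnorm(n_s, 0, spec$regulator_noise_sd)
  }
  for (g in c(bg_genes, tf_decoy))
    m[g, ] <- stats::rnorm(n_s, spec$baseline, spec$sigma)

  module_of <- stats::setNames(rep(seq_len(spec$n_modules),
                                   each = spec$genes_per_module),
                               as.vector(mod_genes))
  de_conditions <- lapply(seq_len(spec$n_modules), function(mod)
    conds[-1L][abs(spec$shift[mod, -1L]) > 0])
  names(de_conditions) <- tf_planted
  # condition where each module carries its largest planted shift
  primary_condition <- vapply(seq_len(spec$n_modules), function(mod)
    conds[which.max(abs(spec$shift[mod, ]))], "")

  list(dataset = expression_dataset(m, condition_of, "normal"),
       tfs = c(tf_planted, tf_decoy),
       truth = list(module_of = module_of,
                    tf_of_module = stats::setNames(tf_planted,
                                                   seq_len(spec$n_modules)),
                    de_conditions = de_conditions,
                    primary_condition = stats::setNames(
                      primary_condition, seq_len(spec$n_modules))))
}

#' Write a simulated study to disk
#'
#' Emits the matrix and annotation TSVs, the TF list, and a `truth.json`
#' describing the planted structure.
#'
#' @param sim result of [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression_dataset(sim$dataset, file.path(dir, "matrix.tsv"),
                           file.path(dir, "annotation.tsv"))
  writeLines(sim$tfs, file.path(dir, "tf_list.txt"))
  truth <- sim$truth
  truth$module_of <- as.list(truth$module_of)      # keep gene names in JSON
  truth$tf_of_module <- as.list(truth$tf_of_module)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
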