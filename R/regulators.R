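#' Regulatory-program scores for candidate TFs
#'
#' Scores how well each regulator's expression explains a module's sample
#' partition tree. For every internal node splitting samples `L | R` and
#' every TF `r`, the split gain is
#' `delta_r = blm(r on L) + blm(r on R) - blm(r on L+R)` with `blm` the
#' Normal-Gamma block score; the node contributes `max(delta_r, 0)` weighted
#' by the fraction of all samples under the node. A TF whose expression is
#' homogeneous across the split gains nothing (the conjugate marginal of
#' pooled identical data always beats the split product), so constant TFs
#' score 0, as do modules with trivial trees.
#'
#' @param sample_tree a tree from [partition_samples()].
#' @param tf_matrix TF x sample numeric matrix (all tree samples present).
#' @param params a [block_score_params()].
#' @return named numeric vector, one score >= 0 per TF.
#' @export
lrp_scores <- function(sample_tree, tf_matrix,
                       params = block_score_params()) {
  stopifnot(nrow(tf_matrix) >= 1)
  tfs <- rownames(tf_matrix)
  n_all <- length(sample_tree$samples)
  nodes <- tree_internal_nodes(sample_tree)
  scores <- stats::setNames(numeric(length(tfs)), tfs)
  for (nd in nodes) {
    l <- nd$left_samples; r <- nd$right_samples
    w <- (length(l) + length(r)) / n_all
    for (tf in tfs) {
      delta <- block_log_marginal(tf_matrix[tf, l], params) +
        block_log_marginal(tf_matrix[tf, r], params) -
        block_log_marginal(tf_matrix[tf, c(l, r)], params)
      if (delta > 0) scores[tf] <- scores[tf] + w * delta
    }
  }
  scores
}

#' Regulatory impact factors
#'
#' Scores each TF against a set of differentially expressed (DE) genes by
#' combining differential wiring (the change in TF-gene correlation between
#' the two conditions), the magnitude of differential expression, and the
#' expression abundance of the DE genes. With `e1_j`, `e2_j` the mean
#' expression of DE gene `j` in the normal and disease condition,
#' `r1_ij`, `r2_ij` the within-condition Pearson correlations of TF `i`
#' with gene `j`, `PIF_j = ((e1_j + e2_j)/2) * (e1_j - e2_j)` and
#' `DW_ij = r1_ij - r2_ij`:
#'
#' * `RIF1_i = mean_j( PIF_j * DW_ij^2 )`
#' * `RIF2_i = mean_j( (e1_j * r1_ij)^2 - (e2_j * r2_ij)^2 )`
#'
#' `z1`, `z2` are z-scores of RIF1 and RIF2 across the scored TFs. TFs (or
#' genes) with zero variance within a condition contribute correlation 0
#' there.
#'
#' @param dataset an [expression_dataset()] restricted to the two
#'   conditions of interest (or any superset; only the listed samples are
#'   used).
#' @param tfs TF ids (rows of the dataset matrix).
#' @param de_genes DE gene ids (rows of the dataset matrix).
#' @param normal_samples,condition_samples the two sample groups
#'   (condition 1 = normal, condition 2 = disease).
#' @return a `rif_result` data.frame with rownames = TF ids and columns
#'   `RIF1`, `RIF2`, `z1`, `z2`; attribute `pif` holds the per-gene PIF.
#' @export
rif_scores <- function(dataset, tfs, de_genes, normal_samples,
                       condition_samples) {
  stopifnot(length(de_genes) >= 1, length(normal_samples) >= 2,
            length(condition_samples) >= 2)
  m <- dataset$matrix
  e1 <- rowMeans(m[de_genes, normal_samples, drop = FALSE])
  e2 <- rowMeans(m[de_genes, condition_samples, drop = FALSE])
  pif <- ((e1 + e2) / 2) * (e1 - e2)

  safe_cor <- function(samples) {
    r <- suppressWarnings(stats::cor(t(m[tfs, samples, drop = FALSE]),
                                     t(m[de_genes, samples, drop = FALSE])))
    r[!is.finite(r)] <- 0
    r
  }
  r1 <- safe_cor(normal_samples)
  r2 <- safe_cor(condition_samples)
  dw2 <- (r1 - r2)^2
  rif1 <- as.vector(dw2 %*% pif) / length(de_genes)
  rif2 <- rowMeans(sweep(r1^2, 2L, e1^2, "*") - sweep(r2^2, 2L, e2^2, "*"))
  zscore <- function(x) {
    s <- stats::sd(x)
    if (length(x) < 2 || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  out <- data.frame(RIF1 = rif1, RIF2 = rif2, z1 = zscore(rif1),
                    z2 = zscore(rif2), row.names = tfs)
  attr(out, "pif") <- pif
  class(out) <- c("rif_result", class(out))
  out
}

minmax01 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0, length(x)))
  (x - rng[1L]) / diff(rng)
}

#' Intersect and integrate the two regulator scores
#'
#' A TF is identified by the regulatory-program route for a module if its
#' `lrp_score` is positive and within the top `top_q` fraction of that
#' module's ranked scores; it is identified by the impact-factor route if
#' `max(|z1|, |z2|) >= 1`. The confident regulators are the intersection,
#' and the integrated `stdScore` is the mean of the two scores after
#' min-max mapping to \[0, 1\] (`lrp_score` within the module,
#' `max(|z1|, |z2|)` across TFs; a constant range maps to 0). Rank is dense
#' over intersected rows by `stdScore` descending, ties by TF id.
#'
#' @param lrp named per-TF scores from [lrp_scores()] for one module.
#' @param rif a `rif_result` over the same TF universe.
#' @param top_q fraction of the module's ranked positive scores counted as
#'   identified by the program route.
#' @return data.frame (TF, lrp_score, RIF1, RIF2, z1, z2, stdScore,
#'   in_intersection, rank); rank is NA outside the intersection.
#' @export
combine_regulators <- function(lrp, rif, top_q = 0.25) {
  tfs <- names(lrp)
  if (!setequal(tfs, rownames(rif)))
    stop("LRP and RIF must cover the same TF universe")
  rif <- rif[tfs, , drop = FALSE]
  zmax <- pmax(abs(rif$z1), abs(rif$z2))
  n_top <- ceiling(top_q * length(tfs))
  lrp_rank <- rank(-lrp, ties.method = "min")
  by_lrp <- lrp > 0 & lrp_rank <= n_top
  by_rif <- zmax >= 1
  std <- (minmax01(lrp) + minmax01(zmax)) / 2
  out <- data.frame(TF = tfs, lrp_score = unname(lrp), RIF1 = rif$RIF1,
                    RIF2 = rif$RIF2, z1 = rif$z1, z2 = rif$z2,
                    stdScore = std, in_intersection = by_lrp & by_rif,
                    rank = NA_integer_, stringsAsFactors = FALSE)
  sel <- which(out$in_intersection)
  if (length(sel) == 0) {
    warning("empty regulator intersection for this module")
  } else {
    o <- sel[order(-out$stdScore[sel], out$TF[sel])]
    out$rank[o] <- seq_along(o)
  }
  rownames(out) <- NULL
  out
}
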