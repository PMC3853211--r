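#' Average gene significance of a module
#'
#' Mean of `-log10(p)` over the module's member genes, using the raw
#' differential-expression p-values by default (set `adjusted = TRUE` for
#' BH-adjusted ones). P-values are clamped to `1e-300` before the log.
#'
#' @param module_genes gene ids.
#' @param de a [moderated_de()] result covering those genes.
#' @param adjusted use BH-adjusted instead of raw p-values.
#' @return mean `-log10(p)`, a number >= 0.
#' @export
average_gs <- function(module_genes, de, adjusted = FALSE) {
  missing <- setdiff(module_genes, rownames(de))
  if (length(missing) > 0)
    stop("module gene(s) missing from DE table: ",
         paste(missing, collapse = ", "))
  p <- de[module_genes, if (adjusted) "adj_p_value" else "p_value"]
  mean(-log10(pmax(p, 1e-300)))
}

#' Module coherence score
#'
#' Mean absolute pairwise Pearson correlation over the module's genes:
#' the sum of `|r|` over unordered gene pairs divided by
#' `choose(ngenes, 2)`. Genes with zero variance contribute correlation 0.
#'
#' @param module_genes gene ids (>= 2).
#' @param data genes x samples matrix over the relevant samples.
#' @return a number in \[0, 1\].
#' @export
mod_score <- function(module_genes, data) {
  n <- length(module_genes)
  if (n < 2) stop("mod_score needs at least 2 genes")
  r <- suppressWarnings(stats::cor(t(data[module_genes, , drop = FALSE])))
  r[!is.finite(r)] <- 0
  sum(abs(r[upper.tri(r)])) / choose(n, 2)
}

#' Combined module significance
#'
#' `1 - (1 - averageGS) * (1 - modScore)`, exactly as printed. Note the
#' value can exceed 1 when `averageGS > 1` (the usual case for a module
#' with genuinely differential genes); the ordering, not the absolute
#' value, is what the knee-point selection consumes.
#'
#' @param averageGS from [average_gs()].
#' @param modScore from [mod_score()].
#' @return the combined score.
#' @export
standard_score <- function(averageGS, modScore) {
  1 - (1 - averageGS) * (1 - modScore)
}

#' Knee-point selection of best modules
#'
#' Sorts the scores descending as points `(index, score)` and finds the
#' interior index with the maximum vertical distance above the chord
#' joining the first and last points; all modules at or before that index
#' are selected. With fewer than 3 modules, or when no interior point lies
#' above the chord (e.g. an exactly linear profile), all are selected.
#'
#' @param scores named numeric vector of per-module standard scores.
#' @return character vector of selected module names (or indices as
#'   character if unnamed).
#' @export
knee_select <- function(scores) {
  m <- length(scores)
  if (m == 0) stop("need at least one module")
  nm <- if (is.null(names(scores))) as.character(seq_len(m)) else names(scores)
  o <- order(-scores, nm)
  if (m < 3) return(nm[o])
  s <- scores[o]
  x <- seq_len(m) - 1
  chord <- s[1L] + (s[m] - s[1L]) * x / (m - 1)
  above <- s - chord
  interior <- 2:(m - 1)
  if (all(above[interior] <= 0)) return(nm[o])
  knee <- interior[which.max(above[interior])]
  nm[o][seq_len(knee)]
}

#' Score and select modules
#'
#' Computes averageGS, modScore and the combined standard score for every
#' module, then flags the knee-selected best modules.
#'
#' @param modules a `module_set` from [tight_clusters()].
#' @param de a [moderated_de()] result for the condition pair.
#' @param data genes x samples matrix over the condition-pair samples.
#' @param adjusted passed to [average_gs()].
#' @return data.frame (module, ngenes, averageGS, modScore, standardScore,
#'   selected), ordered by standardScore descending.
#' @export
score_modules <- function(modules, de, data, adjusted = FALSE) {
  stopifnot(inherits(modules, "module_set"))
  if (length(modules$modules) == 0)
    return(data.frame(module = character(), ngenes = integer(),
                      averageGS = numeric(), modScore = numeric(),
                      standardScore = numeric(), selected = logical()))
  rows <- lapply(names(modules$modules), function(mid) {
    g <- modules$modules[[mid]]
    ags <- average_gs(g, de, adjusted)
    ms <- mod_score(g, data)
    data.frame(module = mid, ngenes = length(g), averageGS = ags,
               modScore = ms, standardScore = standard_score(ags, ms))
  })
  out <- do.call(rbind, rows)
  sel <- knee_select(stats::setNames(out$standardScore, out$module))
  out$selected <- out$module %in% sel
  out[order(-out$standardScore, out$module), , drop = FALSE]
}
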