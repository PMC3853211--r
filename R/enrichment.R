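#' Upper-tail hypergeometric p-value
#'
#' Probability of drawing at least `k` annotated genes when sampling `n`
#' genes without replacement from a background of `N` genes of which `K`
#' carry the annotation: `P[X >= k]`.
#'
#' @param k observed annotated genes in the module.
#' @param n module size.
#' @param K annotated genes in the background.
#' @param N background size.
#' @return p-value in (0, 1\].
#' @export
hypergeom_p <- function(k, n, K, N) {
  if (k < 0 || k > n || n > N || K > N || K < 0)
    stop("require 0 <= k <= n <= N and 0 <= K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation in modules
#'
#' Tests every (module, term) pair — for terms with at least one carrier in
#' the background — with the upper-tail hypergeometric test, and applies
#' Benjamini-Hochberg adjustment within each module (or globally across
#' modules with `scope = "global"`). Unannotated genes count toward the
#' background size `N` and the module size `n` but match no term. By
#' default the background is the full network gene set; the
#' `"network_minus_module"` mode reads "all other genes" literally and
#' excludes the tested module's genes from its own null pool (`K`, `N`) —
#' approximate by construction, since the drawn set keeps size `n`.
#'
#' @param modules a `module_set` or a named list of gene id vectors.
#' @param annotations data.frame with columns `gene`, `term` (one row per
#'   gene-term link), or a named list term -> gene ids.
#' @param background gene id vector containing all module genes.
#' @param fdr_alpha BH significance level.
#' @param scope `"per_module"` (default) or `"global"` BH adjustment.
#' @param background_mode `"network"` (default) or
#'   `"network_minus_module"`.
#' @return list with `table` (module, term, k, n, K, N, p, fdr,
#'   significant) and `module_flag` (named logical: module has >= 1
#'   significant term).
#' @export
enrich_modules <- function(modules, annotations, background,
                           fdr_alpha = 0.05,
                           scope = c("per_module", "global"),
                           background_mode = c("network",
                                               "network_minus_module")) {
  scope <- match.arg(scope)
  background_mode <- match.arg(background_mode)
  if (inherits(modules, "module_set")) modules <- modules$modules
  background <- unique(background)
  if (length(background) == 0) stop("empty background")
  all_members <- unique(unlist(modules, use.names = FALSE))
  if (!all(all_members %in% background))
    stop("background must contain every module gene")
  if (is.data.frame(annotations)) {
    stopifnot(all(c("gene", "term") %in% names(annotations)))
    term_genes <- split(as.character(annotations$gene),
                        as.character(annotations$term))
  } else term_genes <- annotations
  if (length(term_genes) == 0) stop("empty annotation map")
  term_genes <- lapply(term_genes, function(g)
    unique(intersect(g, background)))
  term_genes <- term_genes[lengths(term_genes) >= 1]

  rows <- list()
  for (mid in names(modules)) {
    mg <- modules[[mid]]
    for (tid in names(term_genes)) {
      carriers <- term_genes[[tid]]
      k <- length(intersect(carriers, mg))
      n <- length(mg)
      if (background_mode == "network_minus_module") {
        # literal "all other genes" null pool; approximate by construction
        # (the draw itself still has size n), p floored to stay in (0, 1]
        Kt <- length(setdiff(carriers, mg))
        Nt <- length(setdiff(background, mg))
        if (n > Nt) next
      } else {
        Kt <- length(carriers)
        Nt <- length(background)
      }
      if (Kt < 1) next
      rows[[length(rows) + 1L]] <-
        data.frame(module = mid, term = tid, k = k, n = n, K = Kt, N = Nt,
                   p = max(hypergeom_p(min(k, Kt), n, Kt, Nt), 1e-300),
                   stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    tab <- data.frame(module = character(), term = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), p = numeric())
  if (nrow(tab) > 0) {
    if (scope == "per_module") {
      tab$fdr <- stats::ave(tab$p, tab$module, FUN = bh_adjust)
    } else {
      tab$fdr <- bh_adjust(tab$p)
    }
    tab$significant <- tab$fdr <= fdr_alpha
  } else {
    tab$fdr <- numeric(0); tab$significant <- logical(0)
  }
  flag <- vapply(names(modules), function(mid)
    any(tab$significant[tab$module == mid]), TRUE)
  list(table = tab, module_flag = flag)
}
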