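#' Normal-Gamma block score parameters
#'
#' Conjugate prior for the per-block Gaussian model used by the Gibbs
#' clustering score: mean `mu0` with precision scale `lambda0`, and a
#' Gamma(`alpha0`, `beta0`) prior on the precision. `crp_alpha` is the
#' concentration weight given to opening a new cluster, which lets the
#' sampler estimate the number of modules automatically.
#'
#' @param mu0 prior mean (log2 expression units).
#' @param lambda0 prior precision scale (pseudo-observations on the mean).
#' @param alpha0,beta0 Gamma shape and rate on the precision.
#' @param crp_alpha new-cluster concentration.
#' @return a `block_score_params` list.
#' @export
block_score_params <- function(mu0 = 0, lambda0 = 0.1, alpha0 = 0.1,
                               beta0 = 0.1, crp_alpha = 1.0) {
  if (lambda0 <= 0 || alpha0 <= 0 || beta0 <= 0 || crp_alpha <= 0)
    stop("lambda0, alpha0, beta0 and crp_alpha must be positive")
  structure(list(mu0 = mu0, lambda0 = lambda0, alpha0 = alpha0,
                 beta0 = beta0, crp_alpha = crp_alpha),
            class = "block_score_params")
}

#' Log marginal likelihood of a value block
#'
#' Closed-form marginal of an i.i.d. Gaussian block under the Normal-Gamma
#' conjugate prior. With `n` values of mean `xbar` and centered sum of
#' squares `SS`:
#' `lambda_n = lambda0 + n`, `alpha_n = alpha0 + n/2`,
#' `beta_n = beta0 + SS/2 + lambda0*n*(xbar - mu0)^2 / (2*lambda_n)`, and
#' the score is `lgamma(alpha_n) - lgamma(alpha0) + alpha0*log(beta0) -
#' alpha_n*log(beta_n) + log(lambda0/lambda_n)/2 - (n/2)*log(2*pi)`.
#' The empty block scores 0 (empty product). Depends on the data only
#' through `(n, xbar, SS)`, hence is permutation invariant.
#'
#' @param values numeric vector (may be empty).
#' @param params a [block_score_params()].
#' @return log marginal likelihood (scalar).
#' @export
block_log_marginal <- function(values, params = block_score_params()) {
  stopifnot(all(is.finite(values)))
  n <- length(values)
  if (n == 0) return(0)
  .blm_stats_cpp(n, sum(values), sum(values^2), params$mu0, params$lambda0,
                 params$alpha0, params$beta0)
}

#' Gibbs-sample gene cluster assignments
#'
#' Collapsed Gibbs sampler for a Dirichlet-process-style mixture over genes,
#' scoring each cluster as a product of independent per-sample Gaussian
#' blocks under the Normal-Gamma prior. One sweep visits every gene in a
#' freshly shuffled order, removes it from its cluster, and reassigns it to
#' cluster `k` with probability proportional to `n_k * exp(delta_k)` (or
#' `crp_alpha * exp(delta_new)` for a new singleton cluster), where
#' `delta` is the change in total block score. The chain starts from
#' all-singletons; assignments are recorded after each post-burn-in sweep.
#'
#' @param data genes x samples numeric matrix.
#' @param params a [block_score_params()].
#' @param burn_in discarded initial sweeps.
#' @param steps recorded sweeps.
#' @param seed integer seed (R RNG).
#' @return integer matrix `steps` x genes of 1-based cluster labels, with
#'   gene ids as column names.
#' @export
gibbs_cluster <- function(data, params = block_score_params(), burn_in = 50,
                          steps = 100, seed = 1L) {
  stopifnot(nrow(data) >= 2, ncol(data) >= 2)
  set.seed(seed)
  states <- .gibbs_cluster_cpp(data, as.integer(burn_in), as.integer(steps),
                               params$mu0, params$lambda0, params$alpha0,
                               params$beta0, params$crp_alpha)
  colnames(states) <- rownames(data)
  states
}

#' Total model score of a hard assignment
#'
#' Sum over clusters and samples of [block_log_marginal()]; used to check
#' that the sampler improves on its random initialization.
#'
#' @param data genes x samples matrix.
#' @param assignment integer cluster labels (1-based), one per gene.
#' @param params a [block_score_params()].
#' @return scalar log score.
#' @export
assignment_score <- function(data, assignment, params = block_score_params()) {
  .assignment_score_cpp(data, as.integer(assignment), params$mu0,
                        params$lambda0, params$alpha0, params$beta0)
}

#' Pool recorded states into a fuzzy (co-clustering) structure
#'
#' @param states a state matrix from [gibbs_cluster()], or a list of them
#'   from independent runs over the same genes. Rows are pooled, so run
#'   order does not matter.
#' @return a `fuzzy_clustering` list: `cocluster` (symmetric gene x gene
#'   co-assignment frequency matrix, unit diagonal) and `n_states`.
#' @export
build_fuzzy <- function(states) {
  if (is.list(states)) {
    gene_sets <- lapply(states, colnames)
    if (length(unique(vapply(gene_sets, paste, "", collapse = "\r"))) != 1)
      stop("states come from different gene sets")
    states <- do.call(rbind, states)
  }
  if (nrow(states) < 1) stop("need at least one recorded state")
  co <- .cocluster_cpp(states)
  dimnames(co) <- list(colnames(states), colnames(states))
  structure(list(cocluster = co, n_states = nrow(states)),
            class = "fuzzy_clustering")
}

#' Convert a fuzzy clustering into tight modules
#'
#' Spectral consensus: the number of modules `K*` is the count of
#' eigenvalues of the co-clustering matrix exceeding 1; genes are embedded
#' on the top `K*` eigenvectors and partitioned by seeded k-means into
#' provisional clusters. Each gene's `membership_prob` is its mean
#' co-clustering frequency with the other members of its provisional
#' cluster; genes below `prob_cutoff` are dropped, then clusters below
#' `min_size`, and surviving modules are renumbered by decreasing size.
#' A connected-components backend (edges at `cocluster >= prob_cutoff`)
#' is available for cross-checking.
#'
#' @param fuzzy a `fuzzy_clustering`.
#' @param prob_cutoff minimum mean co-clustering with the assigned module.
#' @param min_size minimum module size.
#' @param seed integer seed for the k-means step.
#' @param backend `"spectral"` (default) or `"components"`.
#' @return a `module_set`: `modules` (named list `M1`, `M2`, ... of gene id
#'   vectors, decreasing size), `membership_prob` (named, retained genes),
#'   `sample_tree` (NULL here; filled by [partition_samples()] callers).
#' @export
tight_clusters <- function(fuzzy, prob_cutoff = 0.2, min_size = 4,
                           seed = 1L, backend = c("spectral", "components")) {
  backend <- match.arg(backend)
  co <- fuzzy$cocluster
  genes <- rownames(co)
  G <- nrow(co)
  if (backend == "spectral") {
    eig <- eigen(co, symmetric = TRUE)
    k_star <- max(1L, sum(eig$values > 1))
    if (k_star == 1L || G <= k_star) {
      provisional <- rep(1L, G)
    } else {
      emb <- eig$vectors[, seq_len(k_star), drop = FALSE]
      set.seed(seed)
      # farthest-first centers: random starts essentially never seed every
      # small block against one dominant background blob
      centers <- matrix(emb[which.max(rowSums(emb^2)), ], 1)
      d2 <- colSums((t(emb) - centers[1, ])^2)
      for (j in seq_len(k_star - 1L)) {
        centers <- rbind(centers, emb[which.max(d2), ])
        d2 <- pmin(d2, colSums((t(emb) - centers[j + 1L, ])^2))
      }
      km_ff <- suppressWarnings(
        stats::kmeans(emb, centers = centers, algorithm = "Lloyd",
                      iter.max = 200))
      km_rs <- suppressWarnings(
        stats::kmeans(emb, centers = k_star, nstart = 20,
                      algorithm = "Lloyd", iter.max = 200))
      provisional <- if (km_ff$tot.withinss <= km_rs$tot.withinss)
        km_ff$cluster else km_rs$cluster
    }
  } else {
    adj <- co >= prob_cutoff
    provisional <- integer(G)
    cur <- 0L
    for (i in seq_len(G)) {
      if (provisional[i] > 0L) next
      cur <- cur + 1L
      queue <- i
      while (length(queue) > 0) {
        v <- queue[1L]; queue <- queue[-1L]
        if (provisional[v] > 0L) next
        provisional[v] <- cur
        queue <- c(queue, which(adj[v, ] & provisional == 0L))
      }
    }
  }
  memb <- vapply(seq_len(G), function(i) {
    others <- which(provisional == provisional[i])
    others <- setdiff(others, i)
    if (length(others) == 0) 1 else mean(co[i, others])
  }, 0)
  keep <- memb >= prob_cutoff
  modules <- split(genes[keep], provisional[keep])
  modules <- modules[lengths(modules) >= min_size]
  if (length(modules) == 0) {
    warning("no module survived the size/probability filters")
    return(structure(list(modules = list(),
                          membership_prob = stats::setNames(numeric(0), character(0)),
                          sample_tree = NULL),
                     class = "module_set"))
  }
  first_gene <- vapply(modules, function(g) min(g), "")
  modules <- modules[order(-lengths(modules), first_gene)]
  modules <- lapply(modules, sort)
  names(modules) <- paste0("M", seq_along(modules))
  kept_genes <- unlist(modules, use.names = FALSE)
  structure(list(modules = modules,
                 membership_prob = stats::setNames(memb, genes)[kept_genes],
                 sample_tree = NULL),
            class = "module_set")
}

#' @export
print.module_set <- function(x, ...) {
  cat(sprintf("module_set: %d modules, %d genes\n",
              length(x$modules), sum(lengths(x$modules))))
  if (length(x$modules) > 0)
    cat("sizes:", paste(lengths(x$modules), collapse = ", "), "\n")
  invisible(x)
}

# exact 1-D two-means: scan all cut points of the sorted profile
split_1d_2means <- function(profile) {
  o <- order(profile, names(profile))
  v <- profile[o]
  n <- length(v)
  csum <- cumsum(v); csq <- cumsum(v^2)
  tot <- csum[n]; totsq <- csq[n]
  wss <- vapply(seq_len(n - 1L), function(i) {
    (csq[i] - csum[i]^2 / i) +
      ((totsq - csq[i]) - (tot - csum[i])^2 / (n - i))
  }, 0)
  cut <- which.min(wss)
  list(left = names(v)[seq_len(cut)], right = names(v)[(cut + 1L):n])
}

#' Recursive Bayesian sample partition of a module
#'
#' Builds a binary tree of sample-set splits. At each node the samples are
#' split by exact two-means on the module-mean expression profile; the
#' split is kept iff the summed block score of the two children (over the
#' module's genes) exceeds the parent's score. Recursion stops when a
#' split is rejected or a child would have fewer than 2 samples.
#'
#' @param module_genes gene ids of the module.
#' @param data genes x samples matrix containing those genes.
#' @param params a [block_score_params()].
#' @return nested list tree; each node has `samples`, and internal nodes
#'   have `left` and `right` child nodes.
#' @export
partition_samples <- function(module_genes, data,
                              params = block_score_params()) {
  stopifnot(length(module_genes) >= 1)
  sub <- data[module_genes, , drop = FALSE]
  node_score <- function(samples) {
    sum(vapply(module_genes, function(g)
      block_log_marginal(sub[g, samples], params), 0))
  }
  grow <- function(samples) {
    node <- list(samples = samples)
    if (length(samples) < 4) return(node)  # children need >= 2 samples
    profile <- colMeans(sub[, samples, drop = FALSE])
    sp <- split_1d_2means(profile)
    if (length(sp$left) < 2 || length(sp$right) < 2) return(node)
    if (node_score(sp$left) + node_score(sp$right) > node_score(samples)) {
      node$left <- grow(sp$left)
      node$right <- grow(sp$right)
    }
    node
  }
  grow(colnames(sub))
}

#' Internal nodes of a sample tree
#'
#' @param tree a tree from [partition_samples()].
#' @return list of nodes, each with `left_samples`, `right_samples`.
#' @export
tree_internal_nodes <- function(tree) {
  nodes <- list()
  walk <- function(node) {
    if (!is.null(node$left)) {
      nodes[[length(nodes) + 1L]] <<-
        list(left_samples = node$left$samples,
             right_samples = node$right$samples)
      walk(node$left); walk(node$right)
    }
  }
  walk(tree)
  nodes
}
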