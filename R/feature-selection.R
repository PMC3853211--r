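#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, takes `p_(j) * m / j`, applies the monotone
#' (min-from-the-right) envelope, caps at 1 and maps back to input order.
#' Idempotent on its own output.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  stopifnot(all(pvals >= 0 & pvals <= 1, na.rm = TRUE))
  m <- length(pvals)
  if (m == 0) return(numeric(0))
  o <- order(pvals)
  adj <- pmin(1, rev(cummin(rev(pvals[o] * m / seq_len(m)))))
  out <- numeric(m)
  out[o] <- adj
  out
}

trigamma_inverse <- function(x) {
  # Newton iterations on y -> trigamma(y); x assumed > 0
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif) / y < 1e-8) break
  }
  y
}

#' Moderated two-group differential expression
#'
#' Empirical-Bayes moderated t-test. Per gene, the pooled two-group variance
#' `s_g^2` on `d_g = nA + nB - 2` degrees of freedom is shrunk toward a
#' common prior variance `s0^2` with prior degrees of freedom `d0`:
#' posterior variance `(d0*s0^2 + d_g*s_g^2) / (d0 + d_g)`. The prior is
#' estimated by method-of-moments on the log sample variances: `s0^2` is the
#' geometric mean of the positive `s_g^2`, and `d0` solves
#' `trigamma(d0/2) = var(log s_g^2) - trigamma(d_g/2)` (infinite — complete
#' shrinkage — when the observed spread does not exceed the sampling
#' component). The t statistic is assessed on `d0 + d_g` degrees of freedom;
#' p-values are two-sided and BH adjustment is computed over all genes.
#' When all gene variances are equal the moderated t coincides with the
#' ordinary pooled t.
#'
#' @param dataset an [expression_dataset()].
#' @param groupA,groupB disjoint sample id sets, each of size >= 2.
#'   `effect` is `mean(groupA) - mean(groupB)`.
#' @return data.frame with rownames = gene ids and columns `effect`,
#'   `t_statistic`, `p_value`, `adj_p_value`, plus attributes `d0`, `s0_sq`.
#' @export
moderated_de <- function(dataset, groupA, groupB) {
  stopifnot(inherits(dataset, "expression_dataset"))
  if (length(intersect(groupA, groupB)) > 0) stop("groups must be disjoint")
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("each group needs at least 2 samples")
  m <- dataset$matrix
  a <- m[, groupA, drop = FALSE]
  b <- m[, groupB, drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  ssa <- rowSums((a - ma)^2); ssb <- rowSums((b - mb)^2)
  dg <- na + nb - 2
  s2 <- (ssa + ssb) / dg
  if (all(s2 == 0)) stop("zero within-group variance for every gene")

  pos <- s2 > 0
  z <- log(s2[pos])
  if (sum(pos) > 2) {
    s0_sq <- exp(mean(z))
    excess <- stats::var(z) - trigamma(dg / 2)
    d0 <- if (is.na(excess) || excess <= 0) Inf else 2 * trigamma_inverse(excess)
  } else {
    s0_sq <- 0; d0 <- 0   # too few informative genes: ordinary t
  }
  post_var <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + dg * s2) / (d0 + dg)
  se <- sqrt(post_var * (1 / na + 1 / nb))
  eff <- ma - mb
  t_stat <- ifelse(se > 0, eff / se, ifelse(eff == 0, 0, sign(eff) * Inf))
  p <- 2 * stats::pt(abs(t_stat), df = d0 + dg, lower.tail = FALSE)
  out <- data.frame(effect = eff, t_statistic = t_stat, p_value = p,
                    adj_p_value = bh_adjust(p),
                    row.names = rownames(m))
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Rank genes by a feature-selection method
#'
#' * `DE_all`: moderated t of normal vs all non-normal samples pooled,
#'   ranked by BH-adjusted p ascending.
#' * `DE_pair`: one moderated t per normal/condition pair; genes ranked by
#'   their minimum adjusted p across pairs.
#' * `Var`: coefficient of variation `sd / |mean|` of each gene's row on the
#'   matrix as provided (log2 scale), ranked descending; rows with mean 0
#'   get CV 0.
#'
#' Ties are broken by gene id lexicographic order.
#'
#' @param dataset an [expression_dataset()].
#' @param method one of `"DE_all"`, `"DE_pair"`, `"Var"`.
#' @return character vector of gene ids, best first.
#' @export
rank_genes <- function(dataset, method = c("DE_all", "DE_pair", "Var")) {
  method <- match.arg(method)
  m <- dataset$matrix
  gid <- rownames(m)
  normal <- samples_of(dataset, dataset$normal_label)
  if (method == "Var") {
    mu <- rowMeans(m)
    sdv <- apply(m, 1L, stats::sd)
    cv <- ifelse(mu == 0, 0, sdv / abs(mu))
    return(gid[order(-cv, gid)])
  }
  others <- setdiff(conditions(dataset), dataset$normal_label)
  if (length(others) == 0) stop("DE ranking needs at least 2 conditions")
  if (method == "DE_all") {
    de <- moderated_de(dataset, samples_of(dataset, others), normal)
    key <- de$adj_p_value
  } else {
    ps <- sapply(others, function(cn)
      moderated_de(dataset, samples_of(dataset, cn), normal)$adj_p_value)
    key <- if (is.matrix(ps)) apply(ps, 1L, min) else ps
  }
  gid[order(key, gid)]
}

#' Cluster samples with one of five algorithms
#'
#' Methods: `kmeans` (Lloyd, 10 seeded random starts, best within-cluster
#' SS), `pam` (BUILD + SWAP on Euclidean distances), `agnes`
#' (average-linkage agglomerative tree cut at k), `fanny` (fuzzy c-means,
#' membership exponent 2, hardened by maximum membership), `gmm` (EM
#' Gaussian mixture — spherical then full covariance on a principal-
#' component projection, best BIC over restarts, hardened by maximum
#' posterior). An empty cluster after hardening triggers up to 5 reseeded
#' re-runs, then an error.
#'
#' @param data samples x features numeric matrix.
#' @param method clustering algorithm name.
#' @param k number of clusters, `1 <= k <= nrow(data)`.
#' @param seed integer seed for the stochastic methods.
#' @return integer vector of cluster labels, one per sample (row).
#' @export
cluster_samples <- function(data, method = c("kmeans", "pam", "agnes",
                                             "fanny", "gmm"),
                            k, seed = 1L) {
  method <- match.arg(method)
  data <- as.matrix(data)
  n <- nrow(data)
  if (k < 1 || k > n) stop("k must be between 1 and the sample count")
  if (k == 1) return(rep(1L, n))
  for (attempt in 0:4) {
    set.seed(seed + attempt)
    labels <- switch(method,
      kmeans = tryCatch(
        stats::kmeans(data, centers = k, algorithm = "Lloyd",
                      nstart = 10, iter.max = 100)$cluster,
        error = function(e) NULL, warning = function(w) NULL),
      pam = cluster::pam(stats::dist(data), k = k, cluster.only = TRUE),
      agnes = stats::cutree(stats::as.hclust(
        cluster::agnes(data, method = "average")), k = k),
      fanny = tryCatch({
        f <- cluster::fanny(data, k = k, memb.exp = 2, maxit = 1000)
        apply(f$membership, 1L, which.max)
      }, error = function(e) NULL),
      gmm = gmm_cluster(data, k)
    )
    if (!is.null(labels) && length(unique(labels)) == k)
      return(as.integer(as.integer(factor(labels))))
    if (method %in% c("pam", "agnes")) break  # deterministic: no point retrying
  }
  if (!is.null(labels)) return(as.integer(as.integer(factor(labels))))
  stop("clustering produced an empty cluster after 5 reseeded attempts")
}

# EM Gaussian mixture on a principal-component projection (<= 5 dims keeps
# the full covariance estimable when features outnumber samples).
gmm_cluster <- function(data, k, n_restarts = 3, max_iter = 200) {
  d_keep <- max(1L, min(ncol(data), nrow(data) - 1L, 5L))
  x <- if (ncol(data) > d_keep)
    stats::prcomp(data, center = TRUE, scale. = FALSE)$x[, seq_len(d_keep), drop = FALSE]
  else data
  n <- nrow(x); d <- ncol(x)
  best <- NULL; best_bic <- -Inf
  for (r in seq_len(n_restarts)) {
    init <- stats::kmeans(x, centers = k, nstart = 5, iter.max = 50)$cluster
    for (covtype in c("spherical", "full")) {
      fit <- tryCatch(gmm_em(x, k, init, covtype, max_iter),
                      error = function(e) NULL)
      if (is.null(fit)) next
      npar <- (k - 1) + k * d +
        if (covtype == "spherical") k else k * d * (d + 1) / 2
      bic <- 2 * fit$loglik - npar * log(n)
      if (bic > best_bic) { best_bic <- bic; best <- fit }
      if (covtype == "spherical") init <- fit$labels
    }
  }
  if (is.null(best)) return(NULL)
  best$labels
}

gmm_em <- function(x, k, init, covtype, max_iter) {
  n <- nrow(x); d <- ncol(x)
  resp <- matrix(1e-6, n, k)
  resp[cbind(seq_len(n), init)] <- 1
  resp <- resp / rowSums(resp)
  loglik <- -Inf
  ridge <- 1e-6 * mean(apply(x, 2L, stats::var))
  for (it in seq_len(max_iter)) {
    nk <- colSums(resp)
    w <- nk / n
    mu <- crossprod(resp, x) / nk
    logdens <- matrix(0, n, k)
    for (j in seq_len(k)) {
      xc <- sweep(x, 2L, mu[j, ])
      if (covtype == "spherical") {
        s2 <- sum(resp[, j] * rowSums(xc^2)) / (nk[j] * d) + ridge
        logdens[, j] <- -0.5 * (d * log(2 * pi * s2) + rowSums(xc^2) / s2)
      } else {
        sig <- crossprod(xc * resp[, j], xc) / nk[j] + diag(ridge, d)
        ch <- chol(sig)
        z <- backsolve(ch, t(xc), transpose = TRUE)
        logdens[, j] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                                  colSums(z^2))
      }
    }
    lw <- sweep(logdens, 2L, log(w), "+")
    mx <- apply(lw, 1L, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    resp <- exp(lw - mx)
    resp <- resp / rowSums(resp)
    if (is.finite(loglik) && abs(ll - loglik) < 1e-8 * abs(ll)) { loglik <- ll; break }
    loglik <- ll
  }
  list(labels = apply(resp, 1L, which.max), loglik = loglik)
}

#' Rand index between two partitions
#'
#' Fraction of item pairs on which the partitions agree: co-clustered in
#' both or separated in both, over all `choose(n, 2)` pairs.
#'
#' @param partitionA,partitionB label vectors of equal length >= 2.
#' @return a number in \[0, 1\]; 1 means identical partitions.
#' @export
rand_index <- function(partitionA, partitionB) {
  n <- length(partitionA)
  if (length(partitionB) != n) stop("partitions must have equal length")
  if (n < 2) stop("need at least 2 items")
  tab <- table(partitionA, partitionB)
  comb2 <- function(x) x * (x - 1) / 2
  total <- comb2(n)
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  (total + 2 * sij - si - sj) / total
}

#' Adjusted Rand index (chance-corrected)
#'
#' @inheritParams rand_index
#' @return a number <= 1; 0 expected under random labeling.
#' @export
adjusted_rand_index <- function(partitionA, partitionB) {
  n <- length(partitionA)
  if (length(partitionB) != n) stop("partitions must have equal length")
  tab <- table(partitionA, partitionB)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  expected <- si * sj / comb2(n)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' Feature-selection evaluation grid
#'
#' For each ranking method and gene-set size, subsets the dataset to the
#' top genes, clusters the samples with each configured algorithm at
#' `k = number of known conditions`, and scores the partition against the
#' true condition labels with the Rand index. The best combination
#' maximizes the mean Rand index across clusterers; ties prefer the smaller
#' size, then the method order `DE_all < DE_pair < Var`.
#'
#' @param dataset an [expression_dataset()].
#' @param sizes gene-set ladder (default the eight standard sizes
#'   10, 50, 100, 200, 500, 1000, 2000, 4000; sizes above the gene count
#'   are truncated to it and deduplicated).
#' @param clusterers clustering algorithms to run (see [cluster_samples()]).
#' @param methods ranking methods to evaluate.
#' @param seed integer seed.
#' @return list with `grid` (data.frame: method, size, clusterer,
#'   rand_index) and `best` (list: method, size, mean_rand_index).
#' @export
evaluate_feature_grid <- function(dataset,
                                  sizes = c(10, 50, 100, 200, 500, 1000,
                                            2000, 4000),
                                  clusterers = c("kmeans", "pam", "agnes",
                                                 "fanny", "gmm"),
                                  methods = c("DE_all", "DE_pair", "Var"),
                                  seed = 1L) {
  truth <- dataset$condition_of
  k <- length(unique(truth))
  sizes <- sort(unique(pmin(sizes, nrow(dataset$matrix))))
  rankings <- lapply(stats::setNames(methods, methods),
                     function(mth) rank_genes(dataset, mth))
  rows <- list()
  for (mth in methods) for (sz in sizes) {
    sub <- t(dataset$matrix[rankings[[mth]][seq_len(sz)], , drop = FALSE])
    for (cl in clusterers) {
      part <- cluster_samples(sub, cl, k, seed = seed)
      rows[[length(rows) + 1L]] <-
        data.frame(method = mth, size = sz, clusterer = cl,
                   rand_index = rand_index(part, truth))
    }
  }
  grid <- do.call(rbind, rows)
  agg <- stats::aggregate(rand_index ~ method + size, grid, mean)
  agg$method_order <- match(agg$method, c("DE_all", "DE_pair", "Var"))
  agg <- agg[order(-agg$rand_index, agg$size, agg$method_order), ]
  best <- list(method = agg$method[1L], size = agg$size[1L],
               mean_rand_index = agg$rand_index[1L])
  list(grid = grid, best = best)
}
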