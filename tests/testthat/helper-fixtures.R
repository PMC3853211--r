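# Shared fixtures and independent oracles.

tiny_dataset <- function() {
  m <- matrix(c(1.0, 2.0, 3.0, 4.0,
                5.0, 6.0, 7.0, 8.0,
                2.5, 2.5, 9.0, 9.5), nrow = 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"),
                              c("s1", "s2", "s3", "s4")))
  ann <- setNames(c("normal", "normal", "dz", "dz"), colnames(m))
  expression_dataset(m, ann, "normal")
}

# two-group dataset: n genes, first n_shift genes shifted by `delta` in dz
shifted_dataset <- function(n_genes = 200, n_shift = 20, n_per_group = 10,
                            delta = 4, sigma = 1, seed = 1) {
  set.seed(seed)
  n_s <- 2 * n_per_group
  m <- matrix(rnorm(n_genes * n_s, 8, sigma), n_genes, n_s,
              dimnames = list(sprintf("g%04d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_s))))
  dz <- (n_per_group + 1):n_s
  m[seq_len(n_shift), dz] <- m[seq_len(n_shift), dz] + delta * sigma
  ann <- setNames(rep(c("normal", "dz"), each = n_per_group), colnames(m))
  expression_dataset(m, ann, "normal")
}

# pairwise brute-force Rand index (independent of the contingency formula)
rand_index_bruteforce <- function(a, b) {
  n <- length(a)
  agree <- 0; total <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    total <- total + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / total
}

# all set partitions of n items as label vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(labels, k) {
    i <- length(labels) + 1L
    if (i > n) { out[[length(out) + 1L]] <<- labels; return(invisible()) }
    for (v in seq_len(k + 1L)) grow(c(labels, v), max(k, v))
  }
  grow(integer(0), 0L)
  out
}

# upper-tail hypergeometric probability by exhaustive enumeration of draws
hypergeom_enum <- function(k, n, K, N) {
  total <- choose(N, n)
  sum(vapply(k:min(n, K), function(x)
    choose(K, x) * choose(N - K, n - x), 0)) / total
}

# Normal-Gamma marginal by integrating the precision numerically after the
# exact Gaussian mean integral (independent route from the lgamma formula)
blm_numeric <- function(values, params = block_score_params()) {
  n <- length(values)
  if (n == 0) return(0)
  xbar <- mean(values); ss <- sum((values - xbar)^2)
  mu0 <- params$mu0; l0 <- params$lambda0
  a0 <- params$alpha0; b0 <- params$beta0
  # for fixed tau, integral over mu is Gaussian:
  # (tau/2pi)^(n/2) * sqrt(l0/(l0+n)) * exp(-tau/2 * q), with
  q <- ss + l0 * n * (xbar - mu0)^2 / (l0 + n)
  u <- seq(-60, 12, by = 0.002)   # tau = exp(u)
  tau <- exp(u)
  logint <- (n / 2) * (log(tau) - log(2 * pi)) + 0.5 * log(l0 / (l0 + n)) -
    tau / 2 * q + a0 * log(b0) - lgamma(a0) + (a0 - 1) * log(tau) -
    b0 * tau + log(tau)           # + log(tau) = Jacobian of tau = exp(u)
  mx <- max(logint)
  mx + log(sum(exp(logint - mx)) * 0.002)
}

# direct R transcription of the closed-form block score
blm_formula <- function(values, params = block_score_params()) {
  n <- length(values)
  if (n == 0) return(0)
  xbar <- mean(values); ss <- sum((values - xbar)^2)
  ln <- params$lambda0 + n
  an <- params$alpha0 + n / 2
  bn <- params$beta0 + ss / 2 +
    params$lambda0 * n * (xbar - params$mu0)^2 / (2 * ln)
  lgamma(an) - lgamma(params$alpha0) + params$alpha0 * log(params$beta0) -
    an * log(bn) + 0.5 * log(params$lambda0 / ln) - (n / 2) * log(2 * pi)
}

# planted two-block gene matrix: two groups of genes with block-specific
# sample profiles, `sep` sds apart, plus residual noise
two_block_matrix <- function(genes_per_block = 10, n_samples = 20,
                             sep = 5, sigma = 1, seed = 1) {
  set.seed(seed)
  p1 <- rnorm(n_samples, 0, sep * sigma / 2)
  p2 <- -p1
  m <- rbind(
    t(replicate(genes_per_block, p1 + rnorm(n_samples, 0, sigma))),
    t(replicate(genes_per_block, p2 + rnorm(n_samples, 0, sigma))))
  dimnames(m) <- list(sprintf("g%02d", seq_len(2 * genes_per_block)),
                      sprintf("s%02d", seq_len(n_samples)))
  m
}

# map recovered modules back onto a gene subset as labels ("none" = dropped)
recovered_labels <- function(module_set, genes) {
  lab <- setNames(rep("none", length(genes)), genes)
  for (mid in names(module_set$modules))
    lab[intersect(module_set$modules[[mid]], genes)] <- mid
  lab
}

# small pipeline config used across tests (desk-scale Gibbs settings)
test_config <- function(seed = 7, ...) {
  pipeline_config(gibbs_runs = 3, burn_in = 20, gibbs_steps = 25,
                  seed = seed, ...)
}
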