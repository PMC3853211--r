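test_that("block score matches the closed form and a numeric-integration oracle", {
  p <- block_score_params()
  expect_equal(block_log_marginal(numeric(0), p), 0)
  for (v in list(0, 1.7, c(-1, 2, 0.5), rnorm(8))) {
    expect_equal(block_log_marginal(v, p), blm_formula(v, p),
                 tolerance = 1e-10)
    expect_equal(block_log_marginal(v, p), blm_numeric(v, p),
                 tolerance = 1e-4)
    expect_equal(block_log_marginal(v[sample(length(v))], p),
                 block_log_marginal(v, p))        # permutation invariance
  }
  p2 <- block_score_params(mu0 = 2, lambda0 = 0.5, alpha0 = 1.3, beta0 = 0.7)
  v <- c(1.5, 2.5, 3)
  expect_equal(block_log_marginal(v, p2), blm_numeric(v, p2),
               tolerance = 1e-4)
  expect_error(block_score_params(lambda0 = -1), "positive")
})

test_that("Gibbs sampling separates planted gene blocks", {
  m <- two_block_matrix(genes_per_block = 10, n_samples = 20, sep = 5,
                        seed = 2)
  st <- gibbs_cluster(m, burn_in = 20, steps = 40, seed = 2)
  b1 <- 1:10; b2 <- 11:20
  sep_frac <- mean(apply(st, 1, function(z) {
    length(unique(z[b1])) == 1 && length(unique(z[b2])) == 1 &&
      z[b1[1]] != z[b2[1]]
  }))
  expect_gte(sep_frac, 0.95)
})

test_that("i.i.d. noise genes yield a varying cluster count across states", {
  # few samples keep the likelihood from dominating the CRP term, so the
  # posterior over the number of clusters stays diffuse enough to move
  set.seed(5)
  m <- matrix(rnorm(20 * 3), 20, 3,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:3)))
  st <- gibbs_cluster(m, burn_in = 20, steps = 100, seed = 5)
  counts <- apply(st, 1, function(z) length(unique(z)))
  expect_gt(length(unique(counts)), 1)
})

test_that("duplicate genes are co-assigned in essentially every state", {
  m <- two_block_matrix(genes_per_block = 6, n_samples = 15, sep = 4,
                        seed = 3)
  m <- rbind(m, twin = m["g01", ])
  st <- gibbs_cluster(m, burn_in = 15, steps = 40, seed = 3)
  co <- mean(st[, "twin"] == st[, "g01"])
  expect_gte(co, 0.99)
})

test_that("the model score improves on the initial singleton state", {
  for (seed in 1:10) {
    m <- two_block_matrix(genes_per_block = 8, n_samples = 12, sep = 4,
                          seed = seed)
    st <- gibbs_cluster(m, burn_in = 0, steps = 30, seed = seed)
    last <- assignment_score(m, st[nrow(st), ])
    init <- assignment_score(m, seq_len(nrow(m)))   # all-singletons start
    expect_gte(last, init)
  }
})

test_that("build_fuzzy pools states into co-assignment frequencies", {
  s1 <- matrix(c(1L, 1L, 2L), 1, 3,
               dimnames = list(NULL, c("a", "b", "c")))
  f1 <- build_fuzzy(s1)
  expect_equal(unname(f1$cocluster["a", "b"]), 1)
  expect_equal(unname(f1$cocluster["a", "c"]), 0)
  expect_true(all(diag(f1$cocluster) == 1))
  s2 <- matrix(c(1L, 2L, 2L), 1, 3, dimnames = dimnames(s1))
  f12 <- build_fuzzy(list(s1, s2))
  expect_equal(unname(f12$cocluster["a", "b"]), 0.5)
  expect_equal(f12$n_states, 2)
  # pooling is order invariant
  f21 <- build_fuzzy(list(s2, s1))
  expect_equal(f21$cocluster, f12$cocluster)
  s_other <- matrix(1L, 1, 3, dimnames = list(NULL, c("a", "b", "z")))
  expect_error(build_fuzzy(list(s1, s_other)), "different gene sets")
})

test_that("tight_clusters resolves exact block structure", {
  genes <- sprintf("g%02d", 1:11)
  co <- matrix(0, 11, 11, dimnames = list(genes, genes))
  co[1:6, 1:6] <- 1; co[7:11, 7:11] <- 1
  fz <- structure(list(cocluster = co, n_states = 1),
                  class = "fuzzy_clustering")
  ms <- tight_clusters(fz, prob_cutoff = 0.2, min_size = 4, seed = 1)
  expect_equal(lengths(ms$modules), c(M1 = 6L, M2 = 5L))
  expect_setequal(ms$modules$M1, genes[1:6])
  expect_setequal(ms$modules$M2, genes[7:11])
  expect_true(all(ms$membership_prob == 1))
  # oracle: connected components at threshold 0.5 give the same modules
  cc <- tight_clusters(fz, prob_cutoff = 0.5, min_size = 4,
                       backend = "components")
  expect_equal(lapply(cc$modules, sort), lapply(ms$modules, sort))
})

test_that("tight_clusters drops strays and undersized blocks", {
  genes <- c(sprintf("g%02d", 1:10), "x1", "x2", "x3")
  co <- matrix(0.05, 13, 13, dimnames = list(genes, genes))
  co[1:10, 1:10] <- 1
  diag(co) <- 1
  fz <- structure(list(cocluster = co, n_states = 1),
                  class = "fuzzy_clustering")
  ms <- tight_clusters(fz, prob_cutoff = 0.2, min_size = 4, seed = 1)
  expect_equal(length(ms$modules), 1L)
  expect_setequal(ms$modules$M1, genes[1:10])
  # a perfect block of 3 is below min_size
  co3 <- matrix(0, 3, 3, dimnames = list(genes[1:3], genes[1:3]))
  co3[] <- 1
  fz3 <- structure(list(cocluster = co3, n_states = 1),
                   class = "fuzzy_clustering")
  expect_warning(ms3 <- tight_clusters(fz3, 0.2, min_size = 4),
                 "no module")
  expect_equal(length(ms3$modules), 0L)
})

test_that("tight_clusters is invariant to gene input order", {
  m <- two_block_matrix(genes_per_block = 8, n_samples = 16, sep = 5,
                        seed = 6)
  st <- gibbs_cluster(m, burn_in = 15, steps = 25, seed = 6)
  fz <- build_fuzzy(st)
  ms <- tight_clusters(fz, 0.2, 4, seed = 9)
  perm <- sample(rownames(fz$cocluster))
  fzp <- structure(list(cocluster = fz$cocluster[perm, perm],
                        n_states = fz$n_states),
                   class = "fuzzy_clustering")
  msp <- tight_clusters(fzp, 0.2, 4, seed = 9)
  expect_equal(lapply(ms$modules, sort), lapply(msp$modules, sort))
})

test_that("sample partitioning splits on real structure only", {
  set.seed(8)
  n_s <- 20
  cond <- rep(c(0, 5), each = n_s / 2)   # bimodal at 5 sigma
  m <- t(replicate(6, cond + rnorm(n_s)))
  dimnames(m) <- list(sprintf("g%d", 1:6), sprintf("s%02d", seq_len(n_s)))
  tree <- partition_samples(rownames(m), m)
  expect_false(is.null(tree$left))
  expect_setequal(tree$left$samples,
                  colnames(m)[order(colMeans(m))[1:10]])
  # two samples: root only
  tree2 <- partition_samples(rownames(m), m[, 1:2])
  expect_null(tree2$left)
  # pure noise: no split accepted in >= 18 of 20 seeds
  no_split <- sum(vapply(1:20, function(s) {
    set.seed(s)
    mn <- matrix(rnorm(6 * n_s), 6, n_s,
                 dimnames = list(sprintf("g%d", 1:6),
                                 sprintf("s%02d", seq_len(n_s))))
    is.null(partition_samples(rownames(mn), mn)$left)
  }, TRUE))
  expect_gte(no_split, 18)
})

test_that("planted modules are recovered end to end at signal/noise 4", {
  # scaled-down fixture: 2 modules + background, few runs / short chains
  set.seed(14)
  sim <- simulate_dataset(simulation_spec(
    n_conditions = 2, samples_per_condition = 12, n_modules = 2,
    genes_per_module = 12, n_background_genes = 60, n_decoy_tfs = 6,
    shift = matrix(c(0, 2, 0, -2), 2, 2, byrow = TRUE), seed = 14))
  res <- suppressWarnings(run_condition_pipeline(
    sim$dataset, sim$tfs, test_config(seed = 14), "dzA", verbose = FALSE))
  planted <- names(sim$truth$module_of)
  rec <- recovered_labels(res$modules, planted)
  expect_gte(adjusted_rand_index(sim$truth$module_of, rec), 0.9)
})
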