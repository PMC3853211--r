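test_that("bh_adjust matches hand-computed step-up values and p.adjust", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.04)), c(0.01, 0.04))
  expect_equal(bh_adjust(c(0.04, 0.005)), c(0.04, 0.01))  # order-equivariant
  # idempotent on fully tied output (the general step-up is not idempotent)
  expect_equal(bh_adjust(rep(0.04, 4)), rep(0.04, 4))
  set.seed(3)
  for (i in 1:5) {
    p <- runif(50)^2
    adj <- bh_adjust(p)
    expect_equal(adj, p.adjust(p, "BH"))
    expect_true(all(adj >= p & adj <= 1))  # monotone, bounded
  }
})

test_that("moderated t handles the null gene and degenerate input", {
  m <- rbind(g1 = c(1, 2, 3, 2, 2, 2),    # equal group means
             g2 = c(0, 0, 1, 5, 5, 6))
  colnames(m) <- paste0("s", 1:6)
  ds <- expression_dataset(m, setNames(rep(c("normal", "dz"), each = 3),
                                       colnames(m)), "normal")
  de <- moderated_de(ds, paste0("s", 1:3), paste0("s", 4:6))
  expect_equal(de["g1", "t_statistic"], 0)
  expect_equal(de["g1", "p_value"], 1)
  flat <- matrix(5, 2, 6, dimnames = dimnames(m))
  dsf <- expression_dataset(flat, ds$condition_of, "normal")
  expect_error(moderated_de(dsf, paste0("s", 1:3), paste0("s", 4:6)),
               "zero within-group variance")
  expect_error(moderated_de(ds, paste0("s", 1:3), paste0("s", 3:6)),
               "disjoint")
})

test_that("with equal gene variances the moderated t is the ordinary pooled t", {
  set.seed(11)
  devA <- rnorm(5); devA <- devA - mean(devA)
  devB <- rnorm(5); devB <- devB - mean(devB)
  mu <- cbind(rnorm(30), rnorm(30))
  m <- t(apply(mu, 1, function(x) c(devA + x[1], devB + x[2])))
  dimnames(m) <- list(sprintf("g%02d", 1:30), sprintf("s%02d", 1:10))
  ds <- expression_dataset(m, setNames(rep(c("normal", "dz"), each = 5),
                                       colnames(m)), "normal")
  de <- moderated_de(ds, colnames(m)[1:5], colnames(m)[6:10])
  # independent oracle: ordinary two-sample pooled t
  t_oracle <- apply(m, 1, function(x) {
    a <- x[1:5]; b <- x[6:10]
    sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / 8
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / 5 + 1 / 5))
  })
  expect_equal(de$t_statistic, unname(t_oracle), tolerance = 1e-12)
})

test_that("strongly shifted genes occupy the top BH-adjusted ranks", {
  ds <- shifted_dataset(n_genes = 200, n_shift = 20, delta = 4, seed = 1)
  de <- moderated_de(ds, samples_of(ds, "dz"), samples_of(ds, "normal"))
  top20 <- rownames(de)[order(de$adj_p_value)][1:20]
  expect_setequal(top20, sprintf("g%04d", 1:20))
})

test_that("moderated t tracks the limma oracle on shared data", {
  ds <- shifted_dataset(n_genes = 300, n_shift = 30, delta = 2, seed = 5)
  de <- moderated_de(ds, samples_of(ds, "dz"), samples_of(ds, "normal"))
  design <- cbind(1, ds$condition_of == "dz")
  fit <- limma::eBayes(limma::lmFit(ds$matrix, design))
  expect_gt(cor(de$t_statistic, fit$t[, 2]), 0.99)
  expect_gt(length(intersect(
    rownames(de)[order(de$p_value)][1:30],
    rownames(fit)[order(fit$p.value[, 2])][1:30])), 27)
})

test_that("rank_genes implements the three ranking methods", {
  ds <- tiny_dataset()
  # constant gene ranked last under Var
  m <- rbind(ds$matrix, gflat = rep(3, 4))
  dsf <- expression_dataset(m, ds$condition_of, "normal")
  expect_equal(tail(rank_genes(dsf, "Var"), 1), "gflat")
  # two conditions: DE_all and DE_pair coincide
  ds2 <- shifted_dataset(n_genes = 50, n_shift = 5, seed = 2)
  expect_identical(rank_genes(ds2, "DE_all"), rank_genes(ds2, "DE_pair"))
  expect_error(rank_genes(ds2, "CV"))
})

test_that("condition-specific genes rank higher under DE_pair than DE_all", {
  set.seed(21)
  n_s <- 18
  m <- matrix(rnorm(120 * n_s, 8, 1), 120, n_s,
              dimnames = list(sprintf("g%03d", 1:120),
                              sprintf("s%02d", 1:n_s)))
  ann <- setNames(rep(c("normal", "dzA", "dzB"), each = 6), colnames(m))
  dzB <- which(ann == "dzB")
  m[1:10, dzB] <- m[1:10, dzB] + 3   # dzB-only signal
  ds <- expression_dataset(m, ann, "normal")
  r_all <- match(sprintf("g%03d", 1:10), rank_genes(ds, "DE_all"))
  r_pair <- match(sprintf("g%03d", 1:10), rank_genes(ds, "DE_pair"))
  expect_lt(median(r_pair), median(r_all))
  expect_true(all(r_pair <= 15))
})

test_that("rand_index matches brute force and its invariants", {
  expect_equal(rand_index(c(1, 1, 2), c(1, 1, 2)), 1)
  expect_equal(rand_index(c(1, 1, 2), c(1, 2, 2)), 1 / 3)
  expect_equal(rand_index(c(1, 2), c(1, 1)), 0)
  expect_error(rand_index(1:3, 1:4), "equal length")
  set.seed(9)
  for (i in 1:10) {
    a <- sample(1:3, 8, replace = TRUE)
    b <- sample(1:4, 8, replace = TRUE)
    expect_equal(rand_index(a, b), rand_index_bruteforce(a, b))
    expect_equal(rand_index(a, b), rand_index(b, a))              # symmetry
    relab <- c(9, 7, 8)[a]
    expect_equal(rand_index(relab, b), rand_index(a, b))          # renaming
  }
})

test_that("adjusted_rand_index is 1 on identity and ~0 under shuffling", {
  a <- rep(1:4, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  set.seed(4)
  aris <- replicate(50, adjusted_rand_index(a, sample(a)))
  expect_lt(abs(mean(aris)), 0.05)
})

test_that("all five clusterers recover well-separated blobs exactly", {
  set.seed(12)
  blob <- rbind(matrix(rnorm(10 * 4, 0), 10, 4),
                matrix(rnorm(10 * 4, 10), 10, 4))
  truth <- rep(1:2, each = 10)
  for (mth in c("kmeans", "pam", "agnes", "fanny", "gmm")) {
    lab <- cluster_samples(blob, mth, k = 2, seed = 3)
    expect_equal(rand_index(lab, truth), 1, info = mth)
    expect_equal(cluster_samples(blob, mth, k = 1, seed = 3),
                 rep(1L, 20), info = mth)
  }
  expect_error(cluster_samples(blob, "kmeans", k = 21), "between 1")
  # duplicated points always co-cluster under kmeans
  dup <- blob[rep(1:20, each = 2), ]
  lab <- cluster_samples(dup, "kmeans", k = 2, seed = 1)
  expect_true(all(lab[seq(1, 39, 2)] == lab[seq(2, 40, 2)]))
})

test_that("feature grid finds planted low-dimensional separation", {
  set.seed(31)
  n_s <- 36
  m <- matrix(rnorm(300 * n_s, 8, 1), 300, n_s,
              dimnames = list(sprintf("g%03d", 1:300),
                              sprintf("s%02d", 1:n_s)))
  ann <- setNames(rep(c("normal", "dzA", "dzB"), each = 12), colnames(m))
  shifts <- cbind(normal = 0, dzA = 2.5, dzB = -2.5)
  m[1:50, ] <- m[1:50, ] + rep(shifts[1, ann], each = 50)
  ds <- expression_dataset(m, ann, "normal")
  res <- evaluate_feature_grid(ds, sizes = c(10, 50, 100, 200, 300),
                               seed = 2)
  expect_true(all(res$grid$rand_index >= 0 & res$grid$rand_index <= 1))
  expect_lte(res$best$size, 200)
  at_max <- aggregate(rand_index ~ size, res$grid, mean)
  expect_gt(res$best$mean_rand_index,
            at_max$rand_index[at_max$size == 300])
})

test_that("a single configured clusterer reduces best to its argmax", {
  ds <- shifted_dataset(n_genes = 60, n_shift = 10, delta = 3, seed = 8)
  res <- evaluate_feature_grid(ds, sizes = c(10, 30, 60),
                               clusterers = "pam", seed = 1)
  agg <- aggregate(rand_index ~ method + size, res$grid, mean)
  expect_equal(res$best$mean_rand_index, max(agg$rand_index))
})

test_that("grid mean RI under shuffled labels matches the permutation null", {
  ds <- shifted_dataset(n_genes = 80, n_shift = 10, delta = 3, seed = 6)
  set.seed(99)
  shuffled <- ds$condition_of
  names_keep <- names(shuffled)
  shuffled <- setNames(sample(unname(shuffled)), names_keep)
  ds_null <- expression_dataset(ds$matrix, shuffled, "normal")
  res <- evaluate_feature_grid(ds_null, sizes = c(10, 40),
                               clusterers = c("kmeans", "pam"), seed = 2)
  # permutation oracle: expected RI of each found partition vs random labels
  set.seed(100)
  chance <- mean(vapply(seq_len(nrow(res$grid)), function(i) {
    sub <- t(ds_null$matrix[rank_genes(ds_null, res$grid$method[i])[
      seq_len(res$grid$size[i])], , drop = FALSE])
    part <- cluster_samples(sub, res$grid$clusterer[i], 2, seed = 2)
    mean(replicate(50, rand_index(part, sample(shuffled))))
  }, 0))
  expect_lt(abs(mean(res$grid$rand_index) - chance), 0.1)
})
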