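test_that("t statistic handles identical, degenerate and random inputs", {
  expect_equal(t_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(abs(t_statistic(c(0, 0), c(1, 1))), 1e6)
  expect_error(t_statistic(1, c(1, 2)),
               class = "methcall_insufficient_replication")
  set.seed(101)
  for (i in 1:20) {
    a <- rnorm(sample(3:8, 1)); b <- rnorm(sample(3:8, 1))
    expect_equal(t_statistic(a, b), oracle_pooled_t(a, b), tolerance = 1e-12)
    expect_equal(t_statistic(a, b, var_equal = FALSE),
                 unname(t.test(a, b)$statistic), tolerance = 1e-10)
  }
})

test_that("single-feature exhaustive maxT equals the hand enumeration", {
  # X = (1,2 | 5,6): of the 6 splits of 4 samples into 2+2, only the two
  # that separate {1,2} from {5,6} reach |t| = 5.657; the rest give
  # |t| <= 0.354, so p = 2/6.
  X <- matrix(c(1, 2, 5, 6), nrow = 1)
  res <- maxt_stepdown(X, c("a", "a", "b", "b"))
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, 6)
  expect_equal(res$p_raw, 1 / 3)
  expect_equal(res$p_adj, res$p_raw)
})

test_that("identical features get identical adjusted p-values", {
  x <- c(0.2, 0.3, 0.9, 0.8, 0.1, 0.85)
  X <- rbind(x, x, x, x)
  res <- maxt_stepdown(X, rep(c("a", "b"), each = 3))
  expect_equal(length(unique(res$p_adj)), 1)
  expect_equal(length(unique(res$p_raw)), 1)
})

test_that("exhaustive maxT matches the brute-force oracle on random data", {
  set.seed(55)
  X <- matrix(rnorm(8 * 8), nrow = 8)
  X[1:2, 5:8] <- X[1:2, 5:8] + 2          # two shifted features
  labels <- rep(c("a", "b"), each = 4)
  res <- maxt_stepdown(X, labels)
  orc <- oracle_maxt_exhaustive(X, labels)   # oracle works on |t|
  expect_equal(abs(res$t_obs), orc$t_obs, tolerance = 1e-12)
  expect_equal(res$p_raw, orc$p_raw, tolerance = 1e-12)
  expect_equal(res$p_adj, orc$p_adj, tolerance = 1e-12)
})

test_that("maxT invariants: p_adj >= p_raw, monotone in the ordering,
           invariant to sample order and label swap", {
  set.seed(56)
  X <- matrix(rnorm(10 * 9), nrow = 10)
  labels <- c(rep("a", 4), rep("b", 5))
  res <- maxt_stepdown(X, labels)
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  ord <- order(-abs(res$t_obs))
  expect_true(all(diff(res$p_adj[ord]) >= -1e-12))
  expect_true(all(res$p_raw > 0) && all(res$p_raw <= 1))

  perm <- sample(ncol(X))
  res_perm <- maxt_stepdown(X[, perm], labels[perm])
  expect_equal(res_perm$p_adj, res$p_adj, tolerance = 1e-12)
  swapped <- ifelse(labels == "a", "b", "a")
  res_swap <- maxt_stepdown(X, swapped)
  expect_equal(res_swap$p_adj, res$p_adj, tolerance = 1e-12)
})

test_that("sampled maxT uses the add-one estimator and respects the seed", {
  set.seed(57)
  X <- matrix(rnorm(5 * 12), nrow = 5)
  X[1, 7:12] <- X[1, 7:12] + 3
  labels <- rep(c("a", "b"), each = 6)    # choose(12,6) = 924 splits
  res <- maxt_stepdown(X, labels, n_perm = 200, seed = 9,
                       exhaustive_limit = 500)
  expect_false(res$exhaustive)
  expect_equal(res$n_perm, 200)
  expect_true(all(res$p_raw >= 1 / 201))
  expect_true(all(res$p_adj >= res$p_raw - 1e-12))
  res2 <- maxt_stepdown(X, labels, n_perm = 200, seed = 9,
                        exhaustive_limit = 500)
  expect_identical(res2$p_adj, res$p_adj)
})

test_that("maxT rejects degenerate groupings", {
  X <- matrix(rnorm(12), nrow = 3)
  expect_error(maxt_stepdown(X, rep("a", 4)), class = "methcall_config_error")
  expect_error(maxt_stepdown(X, c("a", "b", "b", "b")),
               class = "methcall_insufficient_replication")
})

test_that("missing values are excluded pairwise in the permutation t", {
  set.seed(58)
  X <- matrix(rnorm(4 * 8), nrow = 4)
  X[2, 1] <- NA
  res <- maxt_stepdown(X, rep(c("a", "b"), each = 4))
  Xc <- X[2, -1, drop = FALSE]
  direct <- t_statistic(X[2, 2:4], X[2, 5:8])
  expect_equal(res$t_obs[2], direct, tolerance = 1e-12)
})

test_that("BH FDR reproduces the hand formula and its properties", {
  expect_equal(bh_fdr(0.5), 0.5)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  set.seed(59)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))^sample(1:3, 1)
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
  }
  expect_error(bh_fdr(c(0.2, 1.4)), class = "methcall_config_error")
})

test_that("hypergeometric tail is exact and monotone", {
  expect_equal(hypergeom_tail(0, 3, 3, 10), 1)
  # P(X >= 2) for n=3, K=3, N=10: [C(3,2)C(7,1) + C(3,3)C(7,0)] / C(10,3)
  expect_equal(hypergeom_tail(2, 3, 3, 10), 22 / 120, tolerance = 1e-12)
  expect_error(hypergeom_tail(4, 3, 3, 10), class = "methcall_config_error")
  expect_error(hypergeom_tail(2, 3, 11, 10), class = "methcall_config_error")
  set.seed(60)
  for (i in 1:30) {
    N <- sample(5:20, 1); K <- sample(0:N, 1); n <- sample(1:N, 1)
    ks <- 0:min(n, K)
    p <- vapply(ks, hypergeom_tail, 0, n = n, K = K, N = N)
    expect_equal(p, vapply(ks, oracle_hyper_tail, 0, n = n, K = K, N = N),
                 tolerance = 1e-12)
    expect_true(all(diff(p) <= 1e-12))   # non-increasing in k
  }
})

test_that("Pearson concordance matches the closed-form and guards input", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_concordance(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_concordance(x, -x)$r, -1)
  set.seed(61)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  res <- pearson_concordance(a, b)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$n_pairs, 20)
  expect_true(res$p > 0 && res$p < 1)
  expect_error(pearson_concordance(c(1, 1, 1), c(1, 2, 3)),
               class = "methcall_undefined_correlation")
  expect_error(pearson_concordance(c(1, 2), c(1, 2)),
               class = "methcall_insufficient_replication")
})
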