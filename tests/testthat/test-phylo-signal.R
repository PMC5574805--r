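test_that("Brownian simulation is deterministic, degenerate on zero-length trees", {
  tr <- simulate_yule_tree(10, 1, seed = 61)
  x1 <- brownian_simulate(tr, seed = 3)
  x2 <- brownian_simulate(tr, seed = 3)
  expect_identical(x1, x2)
  expect_setequal(names(x1), tr$tip.label)
  tz <- tr
  tz$edge.length[] <- 0
  expect_equal(unname(brownian_simulate(tz, root_state = 2.5, seed = 1)),
               rep(2.5, 10))
  expect_error(brownian_simulate(tr, sigma2 = 0), "positive")
})

test_that("Brownian tip variance and covariance match the closed form", {
  tr <- simulate_yule_tree(10, 1, seed = 67)
  sigma2 <- 0.7
  n_rep <- 10000
  tips <- brownian_simulate(tr, sigma2 = sigma2, seed = 5, n_rep = n_rep)
  depths <- ape::node.depth.edgelength(tr)[seq_len(10)]
  names(depths) <- tr$tip.label
  cm <- cophenetic_matrix(tr)
  for (tip in tr$tip.label) {
    v <- var(tips[tip, ])
    expected <- sigma2 * depths[[tip]]
    se <- expected * sqrt(2 / (n_rep - 1))
    expect_lt(abs(v - expected), 3 * se)
  }
  # shared path length of a pair = (d_i + d_j - d_ij) / 2
  pairs <- utils::combn(tr$tip.label, 2)[, 1:5]
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    shared <- (depths[[i]] + depths[[j]] - cm[i, j]) / 2
    cv <- cov(tips[i, ], tips[j, ])
    se <- sigma2 * sqrt((depths[[i]] * depths[[j]] + shared^2) / (n_rep - 1))
    expect_lt(abs(cv - sigma2 * shared), 3 * se)
  }
})

test_that("proximity matrices match hand computations", {
  bal <- suppressWarnings(read_newick("((a,b),(c,d));"))
  a <- proximity_matrix(bal, "abouheif", row_normalize = FALSE)
  expect_equal(a["a", "b"], 1 / 2)
  expect_equal(a["a", "c"], 1 / 8)
  expect_equal(a, t(a))
  # star tree with k tips: all entries 1/k
  star <- suppressWarnings(read_newick("(a,b,c,d,e);"))
  s <- proximity_matrix(star, "abouheif", row_normalize = FALSE)
  expect_true(all(abs(s[upper.tri(s)] - 1 / 5) < 1e-12))
  # abouheif ignores branch lengths entirely
  bal2 <- read_newick("((a:9,b:0.1):4,(c:2,d:7):0.5);")
  expect_equal(proximity_matrix(bal2, "abouheif"), proximity_matrix(bal, "abouheif"))
  # rows sum to 1 after normalization for both kinds
  tr <- simulate_yule_tree(12, 1, seed = 71)
  for (kind in c("patristic_inverse", "abouheif")) {
    w <- proximity_matrix(tr, kind)
    expect_equal(unname(rowSums(w)), rep(1, 12), tolerance = 1e-12)
  }
})

test_that("Moran's I matches its closed form, ape, and affine invariance", {
  set.seed(73)
  for (n in c(4, 11, 25, 50)) {
    x <- setNames(rnorm(n), sprintf("s%02d", 1:n))
    w <- matrix(1, n, n, dimnames = list(names(x), names(x)))
    diag(w) <- 0
    expect_equal(morans_i(x, w), -1 / (n - 1), tolerance = 1e-12)
  }
  tr <- simulate_yule_tree(15, 1, seed = 79)
  x <- brownian_simulate(tr, seed = 2)
  w <- proximity_matrix(tr, "patristic_inverse")
  i_obs <- morans_i(x, w)
  expect_equal(i_obs, morans_i(5 * x - 3, w), tolerance = 1e-12)
  expect_equal(i_obs, ape::Moran.I(x[rownames(w)], w)$observed, tolerance = 1e-10)
  # clustered values on a two-clade tree have positive signal
  two <- suppressWarnings(read_newick("(((a,b),c),((d,e),f));"))
  xc <- setNames(c(1, 1, 1, -1, -1, -1) + rnorm(6, 0, 0.01),
                 c("a", "b", "c", "d", "e", "f"))
  expect_gt(morans_i(xc, proximity_matrix(two, "abouheif")), 0)
  expect_error(morans_i(setNames(rep(1, 6), letters[1:6]),
                        proximity_matrix(two, "abouheif")), "constant")
})

test_that("exhaustive signal test p equals exact enumeration at n = 6", {
  tr <- simulate_yule_tree(6, 1, seed = 83)
  w <- proximity_matrix(tr, "abouheif")
  set.seed(5)
  x <- setNames(rnorm(6), rownames(w))
  res <- signal_test(x, w, exhaustive = TRUE)
  expect_equal(res$n_permutations, 720)
  expect_equal(res$p_value, oracle_signal_exact_p(x[rownames(w)], w),
               tolerance = 1e-12)
})

test_that("functional identity signal is high for matching trees, null for shuffled tips", {
  tr <- simulate_yule_tree(50, 1, seed = 89)
  res <- functional_identity_signal(tr, tr, n_replicates = 40, n_perm = 99,
                                    seed = 4)
  # both statistics sit far above the null expectation of -1/(n-1); the
  # topology-only Cmean responds more strongly than inverse-patristic I
  expect_gt(median(res$moran_i$per_replicate$statistic), 0.1)
  expect_gt(median(res$abouheif_cmean$per_replicate$statistic), 0.3)
  # deterministic given seed
  res2 <- functional_identity_signal(tr, tr, n_replicates = 40, n_perm = 99,
                                     seed = 4)
  expect_identical(res$moran_i$per_replicate, res2$moran_i$per_replicate)
  # functional tree with permuted tips: statistics near the null expectation
  set.seed(97)
  shuf <- tr
  shuf$tip.label <- sample(shuf$tip.label)
  res3 <- functional_identity_signal(tr, shuf, n_replicates = 40, n_perm = 99,
                                     seed = 4)
  expect_lt(abs(res3$moran_i$observed - (-1 / 49)), 0.1)
  expect_lt(abs(res3$abouheif_cmean$observed - (-1 / 49)), 0.1)
})
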