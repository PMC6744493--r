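test_that("pseudo-distances are elementwise reciprocals with Inf off-network", {
  W <- matrix(c(0L, 2L, 0L,
                2L, 0L, 5L,
                0L, 5L, 0L), 3, 3)
  D <- pseudo_distance(W)
  expect_equal(D[1, 2], 0.5)
  expect_equal(D[2, 3], 0.2)
  expect_identical(D[1, 3], Inf)
  expect_equal(diag(D), rep(0, 3))

  set.seed(2)
  W <- matrix(rpois(49, 2), 7, 7)
  W <- W + t(W); diag(W) <- 0
  D <- pseudo_distance(W)
  idx <- upper.tri(W)
  expect_equal(D[idx][W[idx] > 0], 1 / W[idx][W[idx] > 0])
  expect_true(all(is.infinite(D[idx][W[idx] == 0])))
})

test_that("Gaussian affinity follows the kernel formula and its limits", {
  D <- matrix(c(0, 1, Inf,
                1, 0, 1e-9,
                Inf, 1e-9, 0), 3, 3)
  A <- gaussian_affinity(D, sigma = 1)
  expect_equal(A[1, 2], exp(-0.5))
  expect_equal(A[2, 3], 1, tolerance = 1e-12)  # D -> 0 approaches the kernel maximum
  expect_equal(A[1, 3], 0)                     # infinite distance vanishes
  expect_equal(diag(A), rep(0, 3))
  expect_error(gaussian_affinity(D, sigma = 0), "positive")
  # monotone: smaller distance never gives smaller affinity
  set.seed(3)
  d <- sort(runif(20, 0.1, 3))
  a <- exp(-d^2 / (2 * 0.7^2))
  expect_true(all(diff(a) <= 0))
})

test_that("sigma selection is the quantile of finite off-diagonal distances", {
  D <- matrix(Inf, 4, 4); diag(D) <- 0
  D[1, 2] <- D[2, 1] <- 0.1
  D[1, 3] <- D[3, 1] <- 0.2
  D[2, 3] <- D[3, 2] <- 0.3
  D[3, 4] <- D[4, 3] <- 0.4
  expect_equal(select_sigma(D, q = 0.5),
               unname(quantile(c(0.1, 0.2, 0.3, 0.4), 0.5)))
  # degenerate distribution: all distances equal c
  Dc <- matrix(0.25, 3, 3); diag(Dc) <- 0
  expect_equal(select_sigma(Dc, q = 0.9), 0.25)
  # explicit override passes through
  expect_equal(select_sigma(D, sigma = 0.05), 0.05)
  # edgeless network is rejected
  De <- matrix(Inf, 3, 3); diag(De) <- 0
  expect_error(select_sigma(De), "no edges")
})

test_that("two disjoint cliques are recovered exactly at k = 2", {
  pl <- planted_affinity(c(5, 5))
  labels <- spectral_cluster(pl$A, 2, seed = 1)
  expect_equal(ari(labels, pl$labels), 1)
})

test_that("k = n puts every node in its own module", {
  set.seed(5)
  A <- matrix(runif(36, 0.1, 1), 6, 6)
  A <- (A + t(A)) / 2; diag(A) <- 0
  labels <- spectral_cluster(A, 6, seed = 2)
  expect_equal(sort(unique(as.integer(labels))), 1:6)
})

test_that("planted blocks with weak background are recovered", {
  set.seed(6)
  pl <- planted_affinity(c(8, 10, 12), within = 1, between = 0.01)
  labels <- spectral_cluster(pl$A, 3, seed = 3)
  expect_equal(ari(labels, pl$labels), 1)
})

test_that("clustering is deterministic given a seed and permutation-consistent", {
  set.seed(8)
  pl <- planted_affinity(c(6, 6, 6), within = 1, between = 0.02)
  l1 <- spectral_cluster(pl$A, 3, seed = 11)
  l2 <- spectral_cluster(pl$A, 3, seed = 11)
  expect_identical(l1, l2)
  perm <- sample(nrow(pl$A))
  lp <- spectral_cluster(pl$A[perm, perm], 3, seed = 11)
  expect_equal(ari(lp, l1[perm]), 1)
})

test_that("isolated nodes go to a sink module instead of crashing", {
  pl <- planted_affinity(c(4, 4))
  A <- rbind(cbind(pl$A, 0), 0)
  rownames(A) <- colnames(A) <- paste0("g", 1:9)
  expect_warning(labels <- spectral_cluster(A, 2, seed = 1), "isolated")
  expect_equal(as.integer(labels["g9"]), 3L)
  expect_equal(ari(labels[1:8], pl$labels), 1)
})

test_that("consensus matrix is the co-clustering frequency of seeded runs", {
  set.seed(9)
  pl <- planted_affinity(c(5, 5, 5), within = 1, between = 0.05)
  runs <- 8
  cm <- consensus_modules(pl$A, 3, runs = runs, base_seed = 42)
  expect_true(isSymmetric(unclass(cm), check.attributes = FALSE))
  expect_equal(diag(cm), setNames(rep(1, 15), rownames(pl$A)))
  # independent recomputation from the same derived seed stream
  freq <- matrix(0, 15, 15)
  for (r in seq_len(runs)) {
    lab <- spectral_cluster(pl$A, 3,
                            seed = oncomodules:::derive_seed(42, r))
    freq <- freq + outer(lab, lab, "==")
  }
  expect_equal(unname(unclass(cm)), unname(freq / runs), ignore_attr = TRUE)
})

test_that("well-separated blocks give a 0/1 consensus and stability 1", {
  pl <- planted_affinity(c(6, 6), within = 1, between = 0)
  cm <- consensus_modules(pl$A, 2, runs = 10, base_seed = 5)
  expect_true(all(cm %in% c(0, 1)))
  expect_equal(consensus_stability(cm), 1)
})

noisy_block_weights <- function(sizes, within = 20, between_p = 0.05) {
  # integer co-regulation-style weights: Poisson within blocks, sparse
  # weight-1 edges between them
  n <- sum(sizes)
  lab <- rep(seq_along(sizes), sizes)
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w <- if (lab[i] == lab[j]) rpois(1, within) else rbinom(1, 1, between_p)
      W[i, j] <- W[j, i] <- as.integer(w)
    }
  }
  rownames(W) <- colnames(W) <- paste0("g", seq_len(n))
  list(W = W, labels = lab)
}

test_that("module count selection finds planted blocks and falls back on none", {
  set.seed(10)
  pl <- noisy_block_weights(c(15, 15, 15))
  D <- pseudo_distance(pl$W)
  A <- gaussian_affinity(D, select_sigma(D))
  sel <- select_module_count(A, candidate_ks = 2:6, runs = 20, base_seed = 7)
  expect_equal(sel$k, 3L)
  expect_true(all(sel$scores$stability >= 0 & sel$scores$stability <= 1))
  # single homogeneous block: no stable split, smallest candidate returned
  one <- noisy_block_weights(12)
  D1 <- pseudo_distance(one$W)
  A1 <- gaussian_affinity(D1, select_sigma(D1))
  sel1 <- select_module_count(A1, candidate_ks = 2:4, runs = 20, base_seed = 8)
  expect_equal(sel1$k, 2L)
})

test_that("final partition is reproducible and matches consensus majority on clean data", {
  pl <- planted_affinity(c(7, 7))
  p1 <- final_partition(pl$A, 2, seed = 99)
  p2 <- final_partition(pl$A, 2, seed = 99)
  expect_identical(p1, p2)
  expect_equal(ari(p1, pl$labels), 1)
})
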