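test_that("PAM recovers the exhaustive-medoid optimum in one dimension", {
  x <- c(0, 1, 10, 11)
  d <- as.matrix(dist(x))
  fit <- pam_cluster(d, 2)
  want <- oracle_pam2(d)
  expect_equal(ari(fit$labels, want$labels), 1)
  cost <- sum(vapply(seq_along(x),
                     function(i) d[i, fit$medoids[fit$labels[i]]], 0))
  expect_equal(cost, 2)
  expect_equal(cost, want$cost)
  # k = 1: the medoid minimizes total dissimilarity
  one <- pam_cluster(d, 1)
  expect_equal(sum(d[, one$medoids]), min(rowSums(d)))
  # duplicated points cluster at zero cost
  dd <- as.matrix(dist(c(3, 3, 9, 9)))
  fit2 <- pam_cluster(dd, 2)
  expect_equal(sum(dd[cbind(1:4, fit2$medoids[fit2$labels])]), 0)
  expect_error(pam_cluster(d, 4), "smaller")
})

test_that("PAM solutions are swap-local optima no better than the exhaustive bound", {
  set.seed(6)
  for (rep in 1:5) {
    X <- matrix(rnorm(24), 12, 2)
    d <- as.matrix(dist(X))
    fit <- pam_cluster(d, 2)
    want <- oracle_pam2(d)
    cost <- sum(vapply(1:12, function(i) d[i, fit$medoids[fit$labels[i]]], 0))
    # the exhaustive optimum is a lower bound on the SWAP local optimum
    expect_gte(cost + 1e-12, want$cost)
    # no single medoid/non-medoid exchange improves the solution
    for (m in seq_along(fit$medoids)) {
      others <- setdiff(seq_len(12), fit$medoids)
      for (o in others) {
        trial <- fit$medoids
        trial[m] <- o
        trial_cost <- sum(apply(d[, trial, drop = FALSE], 1, min))
        expect_gte(trial_cost + 1e-9, cost)
      }
    }
  }
})

test_that("consensus entries are co-clustering frequencies with unit diagonal", {
  set.seed(7)
  X <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 8, 0.3), 15, 2))
  rownames(X) <- paste0("p", 1:30)
  cm <- consensus_cluster_patients(X, 2, resamples = 30, seed = 2)
  expect_true(isSymmetric(unclass(cm), check.attributes = FALSE))
  expect_equal(unname(diag(cm)), rep(1, 30))
  expect_true(all(cm >= 0 & cm <= 1))
  # two far blobs: within-consensus 1, between 0
  within <- cm[1:15, 1:15]
  between <- cm[1:15, 16:30]
  expect_true(all(within == 1))
  expect_true(all(between == 0))
  # full subsampling with deterministic PAM gives a 0/1 matrix
  cm_full <- consensus_cluster_patients(X, 2, resamples = 5,
                                        subsample_fraction = 1, seed = 3)
  expect_true(all(cm_full %in% c(0, 1)))
})

test_that("consensus-CDF area matches the hand-computed step integral", {
  # 4 patients in 2 perfect clusters of 2: upper triangle {1,0,0,0,0,1}
  cm <- matrix(0, 4, 4); diag(cm) <- 1
  cm[1, 2] <- cm[2, 1] <- 1
  cm[3, 4] <- cm[4, 3] <- 1
  expect_equal(consensus_auc(cm), 2 / 3)
  all1 <- matrix(1, 3, 3)
  expect_equal(consensus_auc(all1), 0)
  all0 <- diag(3)
  expect_equal(consensus_auc(all0), 1)
  expect_error(consensus_auc(matrix(1, 1, 1)))
})

test_that("group-count selection finds three planted blobs and falls back to 2", {
  set.seed(8)
  X <- rbind(matrix(rnorm(40, 0), 20, 2),
             matrix(rnorm(40, 6), 20, 2),
             cbind(rnorm(20, 12), rnorm(20, 0)))
  rownames(X) <- paste0("p", 1:60)
  sel <- select_group_count(X, ks = 2:6, resamples = 40, seed = 3)
  expect_equal(sel$k, 3L)
  expect_true(all(sel$scores$auc >= 0 & sel$scores$auc <= 1))
  # structureless data: nothing qualifies, smallest candidate returned
  set.seed(88)
  noise <- matrix(rnorm(120), 40, 3, dimnames = list(paste0("p", 1:40), NULL))
  seln <- select_group_count(noise, ks = 2:5, resamples = 30, seed = 4)
  expect_equal(seln$k, 2L)
})

test_that("nested blobs give non-decreasing consensus-CDF area in k", {
  set.seed(9)
  centres <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  X <- do.call(rbind, lapply(1:4, function(i) {
    sweep(matrix(rnorm(24, 0, 0.4), 12, 2), 2, centres[i, ], "+")
  }))
  rownames(X) <- paste0("p", 1:48)
  aucs <- vapply(2:5, function(k) {
    consensus_auc(consensus_cluster_patients(X, k, resamples = 30, seed = k))
  }, 0)
  expect_true(all(diff(aucs) >= -1e-6))
})

test_that("final group assignment is reproducible with medoids in-cluster", {
  set.seed(10)
  X <- rbind(matrix(rnorm(30, 0, 0.5), 15, 2),
             matrix(rnorm(30, 7, 0.5), 15, 2))
  rownames(X) <- paste0("p", 1:30)
  l1 <- assign_patient_groups(X, 2, seed = 5)
  l2 <- assign_patient_groups(X, 2, seed = 5)
  expect_identical(l1, l2)
  expect_equal(ari(l1, rep(1:2, each = 15)), 1)
  med <- attr(l1, "medoids")
  expect_equal(unname(l1[med]), 1:2)
})
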