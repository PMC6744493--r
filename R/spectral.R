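#' Pseudo-distances from co-regulation weights
#'
#' Converts the integer weight matrix of a DEG network into a pseudo-distance
#' matrix: `D_ij = 1 / W_ij` for positive weights, `Inf` where no edge
#' exists, and 0 on the diagonal. Frequently co-regulated pairs therefore
#' become close, never co-regulated pairs infinitely far.
#'
#' @param network A `deg_network` object, or a symmetric nonnegative weight
#'   matrix.
#' @return Numeric matrix of pseudo-distances.
#' @export
pseudo_distance <- function(network) {
  W <- if (inherits(network, "deg_network")) network$W else network
  stopifnot(is.matrix(W), nrow(W) == ncol(W), all(W >= 0))
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  dimnames(D) <- dimnames(W)
  D
}

#' Gaussian-kernel affinity from pseudo-distances
#'
#' `A_ij = exp(-D_ij^2 / (2 sigma^2))` off the diagonal, with `A_ij = 0`
#' where `D_ij` is infinite and a zero diagonal (the convention the spectral
#' algorithm expects). The negative exponent maps short pseudo-distances to
#' affinities near 1 and suppresses long ones.
#'
#' @param D Pseudo-distance matrix from [pseudo_distance()].
#' @param sigma Positive kernel bandwidth.
#' @return Affinity matrix in \[0, 1\] with zero diagonal.
#' @export
gaussian_affinity <- function(D, sigma) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (!is_scalar_number(sigma) || sigma <= 0) {
    stop("sigma must be a positive scalar", call. = FALSE)
  }
  A <- exp(-D^2 / (2 * sigma^2))
  A[is.infinite(D)] <- 0
  diag(A) <- 0
  dimnames(A) <- dimnames(D)
  A
}

#' Kernel bandwidth from the pseudo-distance distribution
#'
#' Returns the `q`-quantile of the finite off-diagonal pseudo-distances.
#' The median (default) places the kernel shoulder in the middle of the
#' observed distance distribution, so that shorter-than-typical distances
#' receive high affinity and longer-than-typical ones are suppressed. Pass
#' `sigma` to override with a fixed value (e.g. 0.05 or 0.1).
#'
#' @param D Pseudo-distance matrix.
#' @param q Quantile in (0, 1); default 0.5.
#' @param sigma Optional fixed bandwidth returned unchanged.
#' @return Positive scalar bandwidth.
#' @export
select_sigma <- function(D, q = 0.5, sigma = NULL) {
  if (!is.null(sigma)) {
    stopifnot(is_scalar_number(sigma), sigma > 0)
    return(sigma)
  }
  vals <- D[upper.tri(D)]
  vals <- vals[is.finite(vals) & vals > 0]
  if (length(vals) == 0L) {
    stop("all pseudo-distances are infinite: the network has no edges",
         call. = FALSE)
  }
  as.numeric(stats::quantile(vals, probs = q, names = FALSE))
}

# Normalized spectral embedding: D^{-1/2} A D^{-1/2}, top-k eigenvectors,
# rows scaled to unit length. Expects no zero-degree rows. Eigenvector sign
# fixed so the first component of magnitude > 1e-12 is positive, making the
# embedding deterministic under eigen-solver sign ambiguity.
spectral_embedding <- function(A, k) {
  deg <- rowSums(A)
  stopifnot(all(deg > 0), k >= 1, k <= nrow(A))
  s <- 1 / sqrt(deg)
  L <- A * outer(s, s)
  e <- eigen(L, symmetric = TRUE)
  V <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) > 0L && V[nz[1L], j] < 0) V[, j] <- -V[, j]
  }
  rn <- sqrt(rowSums(V^2))
  rn[rn == 0] <- 1
  V / rn
}

# Plain Lloyd k-means with random distinct-row initialization. Ties in the
# nearest-centre assignment break to the lowest centre index; a centre left
# empty is re-seeded at the point currently farthest from its own centre.
kmeans_lloyd <- function(x, k, iter_max = 300L, tol = 1e-6) {
  n <- nrow(x)
  stopifnot(k >= 1, k <= n)
  centres <- x[sample.int(n, k), , drop = FALSE]
  labels <- integer(n)
  xsq <- rowSums(x^2)
  for (it in seq_len(iter_max)) {
    d2 <- outer(xsq, rowSums(centres^2), "+") - 2 * x %*% t(centres)
    labels <- max.col(-d2, ties.method = "first")
    repeat {
      sizes <- tabulate(labels, k)
      empty <- which(sizes == 0L)
      if (length(empty) == 0L) break
      cur <- d2[cbind(seq_len(n), labels)]
      cur[sizes[labels] <= 1L] <- -Inf   # never steal from a singleton
      labels[which.max(cur)] <- empty[1L]
    }
    new_centres <- centres
    for (j in seq_len(k)) {
      new_centres[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    }
    shift <- max(rowSums((new_centres - centres)^2))
    centres <- new_centres
    if (shift < tol) break
  }
  labels
}

#' Spectral clustering of an affinity matrix
#'
#' Normalized spectral clustering: the affinity matrix is degree-normalized,
#' the `k` largest-eigenvalue eigenvectors form an embedding whose rows are
#' scaled to unit length, and k-means with random centre initialization
#' assigns module labels. Isolated nodes (zero degree) cannot enter the
#' degree normalization; they are collected into one extra sink module
#' labelled `k + 1`, with a warning.
#'
#' @param A Affinity matrix (symmetric, nonnegative, zero diagonal).
#' @param k Number of modules (>= 2, <= number of connected nodes).
#' @param seed Integer seed for the k-means initialization.
#' @return Named integer vector of labels in `1..k` (plus `k + 1` for
#'   isolated nodes), with attributes `k` and `seed`.
#' @export
spectral_cluster <- function(A, k, seed = 1L) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), k >= 2)
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(A)))
  connected <- rowSums(A) > 0
  if (!all(connected)) {
    warning(sprintf("%d isolated node(s) assigned to sink module %d",
                    sum(!connected), k + 1L), call. = FALSE)
  }
  if (k > sum(connected)) {
    stop("k exceeds the number of connected nodes", call. = FALSE)
  }
  V <- spectral_embedding(A[connected, connected, drop = FALSE], k)
  lab_conn <- with_seed(seed, kmeans_lloyd(V, k))
  labels <- integer(nrow(A))
  labels[connected] <- lab_conn
  labels[!connected] <- k + 1L
  names(labels) <- nodes
  attr(labels, "k") <- as.integer(k)
  attr(labels, "seed") <- as.integer(seed)
  labels
}

#' Consensus matrix over repeated spectral clustering runs
#'
#' Repeats the k-means stage of spectral clustering `runs` times with
#' different random initializations on the (fixed) spectral embedding; entry
#' (i, j) of the consensus matrix is the fraction of runs in which nodes i
#' and j received the same label. All nodes enter every run.
#'
#' @param A Affinity matrix.
#' @param k Number of modules.
#' @param runs Number of independent runs (default 100).
#' @param base_seed Seed from which the per-run seeds are derived.
#' @return Symmetric consensus matrix with unit diagonal and attribute
#'   `runs`.
#' @export
consensus_modules <- function(A, k, runs = 100L, base_seed = 1L) {
  stopifnot(runs >= 2)
  nodes <- rownames(A)
  connected <- rowSums(A) > 0
  if (k > sum(connected)) {
    stop("k exceeds the number of connected nodes", call. = FALSE)
  }
  V <- spectral_embedding(A[connected, connected, drop = FALSE], k)
  n <- nrow(A)
  M <- matrix(0, n, n)
  full_labels <- integer(n)
  for (r in seq_len(runs)) {
    lab <- with_seed(derive_seed(base_seed, r), kmeans_lloyd(V, k))
    full_labels[connected] <- lab
    full_labels[!connected] <- k + 1L
    M <- M + outer(full_labels, full_labels, "==")
  }
  M <- M / runs
  dimnames(M) <- list(nodes, nodes)
  attr(M, "runs") <- as.integer(runs)
  M
}

#' Stability of a consensus matrix (1 - PAC)
#'
#' Fraction of off-diagonal upper-triangle consensus entries lying outside
#' the ambiguity band: entries at or below `band[1]` or at or above
#' `band[2]` count as stable. Perfectly reproducible clusterings score 1.
#'
#' @param consensus Consensus matrix.
#' @param band Ambiguity band, default `c(0.1, 0.9)`.
#' @return Scalar in \[0, 1\].
#' @export
consensus_stability <- function(consensus, band = c(0.1, 0.9)) {
  vals <- consensus[upper.tri(consensus)]
  mean(vals <= band[1L] | vals >= band[2L])
}

#' Choose the number of DEG modules by consensus stability
#'
#' For each candidate `k`, a consensus matrix over repeated spectral
#' clustering runs is scored by [consensus_stability()]. Scanning the
#' candidates in ascending order, the chosen `k` is the last one on the
#' initial high-stability run: starting from the first candidate that
#' reaches `stability_floor`, the scan advances while the score is
#' non-decreasing and stops at the first drop — increasing `k` beyond
#' the true module count splits genuine modules differently from run to
#' run, which can only lower the score. If no candidate reaches the floor
#' the smallest candidate is returned. When `candidate_ks` is `NULL` a
#' coarse scan over 5, 10, 15, 20 is refined around the most stable coarse
#' value.
#'
#' @param A Affinity matrix.
#' @param candidate_ks Integer vector of candidate module counts, or `NULL`
#'   for the coarse-then-fine scan.
#' @param runs Consensus runs per candidate.
#' @param stability_floor Minimum acceptable stability (default 0.8).
#' @param band Ambiguity band passed to [consensus_stability()].
#' @param base_seed Seed for the consensus runs.
#' @return List with `k` (chosen count) and `scores` (data frame `k`,
#'   `stability`), for audit.
#' @export
select_module_count <- function(A, candidate_ks = NULL, runs = 100L,
                                stability_floor = 0.8, band = c(0.1, 0.9),
                                base_seed = 1L) {
  n_conn <- sum(rowSums(A) > 0)
  score_k <- function(k) {
    consensus_stability(consensus_modules(A, k, runs = runs,
                                          base_seed = derive_seed(base_seed, k)),
                        band = band)
  }
  if (is.null(candidate_ks)) {
    coarse <- c(5L, 10L, 15L, 20L)
    coarse <- coarse[coarse >= 2L & coarse <= n_conn]
    if (length(coarse) == 0L) coarse <- 2L
    coarse_scores <- vapply(coarse, score_k, 0)
    best <- coarse[which.max(coarse_scores)]
    lo <- max(2L, best - 4L)
    hi <- min(n_conn, best + 4L)
    fine <- setdiff(seq(lo, hi), coarse)
    fine_scores <- vapply(fine, score_k, 0)
    ks <- c(coarse, fine)
    scores <- c(coarse_scores, fine_scores)
  } else {
    ks <- sort(unique(as.integer(candidate_ks)))
    stopifnot(length(ks) >= 1L, all(ks >= 2L), all(ks <= n_conn))
    scores <- vapply(ks, score_k, 0)
  }
  ord <- order(ks)
  ks <- ks[ord]
  scores <- scores[ord]
  first_pass <- which(scores >= stability_floor)
  if (length(first_pass) == 0L) {
    chosen <- min(ks)
  } else {
    i <- first_pass[1L]
    while (i < length(ks) && scores[i + 1L] >= scores[i] &&
           scores[i + 1L] >= stability_floor) {
      i <- i + 1L
    }
    chosen <- ks[i]
  }
  list(k = as.integer(chosen),
       scores = data.frame(k = ks, stability = scores))
}

#' Final module partition at the selected k
#'
#' One additional seeded spectral clustering run at the chosen module
#' count; the seed is recorded on the result so the partition can be
#' reproduced bit for bit.
#'
#' @param A Affinity matrix.
#' @param k Selected module count.
#' @param seed Integer seed.
#' @return Named integer label vector as in [spectral_cluster()].
#' @export
final_partition <- function(A, k, seed = 1L) {
  spectral_cluster(A, k, seed = seed)
}
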