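#' PAM (k-medoids) clustering of a dissimilarity matrix
#'
#' Thin, validated wrapper around [cluster::pam()] (BUILD + SWAP to a local
#' optimum of the summed dissimilarity to medoids). PAM is deterministic for
#' a given dissimilarity matrix, which makes the surrounding consensus
#' machinery reproducible.
#'
#' @param diss Square symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of clusters, `1 <= k < n`.
#' @return List with `labels` (integer vector) and `medoids` (indices into
#'   the rows of `diss`).
#' @export
pam_cluster <- function(diss, k) {
  stopifnot(is.matrix(diss), nrow(diss) == ncol(diss))
  n <- nrow(diss)
  if (k >= n) {
    stop("k must be smaller than the number of observations", call. = FALSE)
  }
  if (max(abs(diss - t(diss))) > 1e-10 || any(abs(diag(diss)) > 1e-10)) {
    stop("diss must be symmetric with zero diagonal", call. = FALSE)
  }
  fit <- cluster::pam(stats::as.dist(diss), k = k, diss = TRUE,
                      pamonce = 5, cluster.only = FALSE)
  list(labels = as.integer(fit$clustering),
       medoids = as.integer(fit$id.med))
}

#' Consensus matrix from subsampled PAM clusterings
#'
#' Repeatedly subsamples patients without replacement, clusters each
#' subsample with PAM on Euclidean dissimilarities, and records for every
#' patient pair the fraction of co-sampled resamples in which the pair was
#' co-clustered. Pairs never co-sampled get consensus 0 with a warning
#' (negligible probability at the default 100+ resamples at 80%).
#'
#' @param features Numeric matrix, patients x features (normally z-scored).
#' @param k Number of groups.
#' @param resamples Number of subsampling rounds (default 100).
#' @param subsample_fraction Fraction of patients per round (default 0.8).
#' @param seed Integer seed driving the subsampling.
#' @return Symmetric consensus matrix with unit diagonal and attributes
#'   `resamples` and `k`.
#' @export
consensus_cluster_patients <- function(features, k, resamples = 100L,
                                       subsample_fraction = 0.8, seed = 1L) {
  stopifnot(is.matrix(features), resamples >= 2,
            subsample_fraction > 0, subsample_fraction <= 1)
  n <- nrow(features)
  m <- max(2L, floor(subsample_fraction * n))
  if (k >= m) {
    stop("k must be smaller than the subsample size", call. = FALSE)
  }
  d <- as.matrix(stats::dist(features))
  together <- matrix(0, n, n)
  sampled <- matrix(0, n, n)
  with_seed(seed, {
    for (r in seq_len(resamples)) {
      idx <- sort(sample.int(n, m))
      lab <- pam_cluster(d[idx, idx, drop = FALSE], k)$labels
      co <- outer(lab, lab, "==")
      together[idx, idx] <- together[idx, idx] + co
      sampled[idx, idx] <- sampled[idx, idx] + 1
    }
  })
  if (any(sampled[upper.tri(sampled)] == 0)) {
    warning("some patient pairs were never co-sampled; their consensus is set to 0",
            call. = FALSE)
  }
  consensus <- ifelse(sampled > 0, together / pmax(sampled, 1), 0)
  diag(consensus) <- 1
  dimnames(consensus) <- list(rownames(features), rownames(features))
  attr(consensus, "resamples") <- as.integer(resamples)
  attr(consensus, "k") <- as.integer(k)
  consensus
}

#' Area under the consensus CDF
#'
#' Area on \[0, 1\] under the empirical cumulative distribution function of
#' the upper-triangle consensus entries. Equals the step-function integral
#' `sum over sorted entries of (1 - value) / n_pairs`; 0 when every pair is
#' always co-clustered, 1 when no pair ever is. Larger areas mean more
#' pairs split apart; the increase of this area with k drives group-count
#' selection.
#'
#' @param consensus Consensus matrix (at least 2 x 2).
#' @return Scalar in \[0, 1\].
#' @export
consensus_auc <- function(consensus) {
  stopifnot(is.matrix(consensus), nrow(consensus) >= 2L)
  vals <- consensus[upper.tri(consensus)]
  mean(1 - vals)
}

#' Choose the number of patient groups by consensus-CDF area
#'
#' Runs [consensus_cluster_patients()] for each candidate `k`, computes the
#' consensus-CDF area (AUCDFC) and the consensus stability (1 - PAC). A
#' candidate qualifies when its relative AUCDFC increase over the previous
#' candidate reaches `delta_threshold` and its stability clears
#' `stability_floor` (group overlap on the consensus matrix stays low).
#' Scanning candidates in ascending order, the chosen `k` is the stability
#' peak of the initial qualifying run: from the first qualifying candidate
#' the scan advances while candidates keep qualifying with
#' non-decreasing stability, and stops at the first drop — beyond the true group
#' count, resamples split genuine groups inconsistently and stability can
#' only fall. If no candidate qualifies the smallest candidate is
#' returned.
#'
#' @param features Numeric matrix, patients x features.
#' @param ks Candidate group counts (default `2:15`).
#' @param resamples Resampling rounds per candidate.
#' @param subsample_fraction Fraction of patients per round.
#' @param delta_threshold Minimum relative AUCDFC increase (default 0.03).
#' @param stability_floor Minimum consensus stability (default 0.8).
#' @param band Ambiguity band for [consensus_stability()].
#' @param seed Integer seed.
#' @return List with `k` and a decision table `scores` (columns `k`, `auc`,
#'   `delta`, `stability`, `passes`).
#' @export
select_group_count <- function(features, ks = 2:15, resamples = 100L,
                               subsample_fraction = 0.8,
                               delta_threshold = 0.03, stability_floor = 0.8,
                               band = c(0.1, 0.9), seed = 1L) {
  ks <- sort(unique(as.integer(ks)))
  stopifnot(length(ks) >= 2L, all(ks >= 2L))
  auc <- numeric(length(ks))
  stab <- numeric(length(ks))
  for (i in seq_along(ks)) {
    cm <- consensus_cluster_patients(features, ks[i], resamples = resamples,
                                     subsample_fraction = subsample_fraction,
                                     seed = derive_seed(seed, ks[i]))
    auc[i] <- consensus_auc(cm)
    stab[i] <- consensus_stability(cm, band = band)
  }
  delta <- c(auc[1L],
             ifelse(auc[-length(auc)] > 0,
                    diff(auc) / auc[-length(auc)],
                    Inf))
  passes <- delta >= delta_threshold & stab >= stability_floor
  if (!any(passes)) {
    chosen <- min(ks)
  } else {
    i <- which(passes)[1L]
    while (i < length(ks) && passes[i + 1L] && stab[i + 1L] >= stab[i]) {
      i <- i + 1L
    }
    chosen <- ks[i]
  }
  list(k = as.integer(chosen),
       scores = data.frame(k = ks, auc = auc, delta = delta,
                           stability = stab, passes = passes))
}

#' Final patient group assignment
#'
#' PAM on the full feature table at the selected group count; the seed and
#' the medoid patients are recorded for reproducibility (PAM itself is
#' deterministic).
#'
#' @param features Numeric matrix, patients x features.
#' @param k Selected group count.
#' @param seed Integer seed, recorded on the result.
#' @return Named integer label vector with attributes `k`, `seed` and
#'   `medoids` (patient identifiers).
#' @export
assign_patient_groups <- function(features, k, seed = 1L) {
  d <- as.matrix(stats::dist(features))
  fit <- pam_cluster(d, k)
  labels <- stats::setNames(fit$labels, rownames(features))
  attr(labels, "k") <- as.integer(k)
  attr(labels, "seed") <- as.integer(seed)
  attr(labels, "medoids") <- rownames(features)[fit$medoids]
  labels
}
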