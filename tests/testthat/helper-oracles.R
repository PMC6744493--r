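# Independent oracles used across the suite. These are deliberately naive
# (nested loops, exhaustive enumeration) and share no code with the
# package implementation.

# Adjusted Rand index between two label vectors.
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- si * sj / choose(n, 2)
  denom <- (si + sj) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

# Brute-force implementation of the four filtering standards, looping over
# tumours and genes one comparison at a time.
oracle_filter <- function(assignments, observations, th) {
  valid <- assignments[assignments$posterior > th$posterior_floor, , drop = FALSE]

  driver_calls <- list()
  for (t in unique(valid$tumour_id)) {
    rows_t <- valid[valid$tumour_id == t, , drop = FALSE]
    for (s in unique(rows_t$sga)) {
      degs <- unique(rows_t$deg[rows_t$sga == s])
      if (length(degs) >= th$min_degs_per_driver) {
        driver_calls[[length(driver_calls) + 1L]] <- c(t, s)
      }
    }
  }
  drv <- if (length(driver_calls)) do.call(rbind, driver_calls) else
    matrix(character(), ncol = 2)

  sig_drivers <- character()
  for (s in unique(drv[, 2])) {
    n_drv <- length(unique(drv[drv[, 2] == s, 1]))
    n_obs <- length(unique(observations$tumour_id[observations$sga == s]))
    if (n_drv >= th$min_driver_tumours && n_drv / n_obs >= th$min_driver_fraction) {
      sig_drivers <- c(sig_drivers, s)
    }
  }

  sig_rels <- list()
  for (s in sig_drivers) {
    n_driver_tum <- length(unique(drv[drv[, 2] == s, 1]))
    rows_s <- valid[valid$sga == s, , drop = FALSE]
    for (d in unique(rows_s$deg)) {
      n_t <- length(unique(rows_s$tumour_id[rows_s$deg == d]))
      if (n_t >= th$min_relationship_tumours ||
          n_t / n_driver_tum >= th$min_relationship_fraction) {
        sig_rels[[length(sig_rels) + 1L]] <- c(s, d)
      }
    }
  }
  rels <- if (length(sig_rels)) do.call(rbind, sig_rels) else
    matrix(character(), ncol = 2)

  keep <- logical(nrow(valid))
  for (i in seq_len(nrow(valid))) {
    keep[i] <- any(rels[, 1] == valid$sga[i] & rels[, 2] == valid$deg[i])
  }

  list(driver_calls = drv[order(drv[, 1], drv[, 2]), , drop = FALSE],
       significant_drivers = sort(sig_drivers),
       significant_relationships = rels[order(rels[, 1], rels[, 2]), , drop = FALSE],
       significant_assignments = valid[keep, , drop = FALSE])
}

# Random assignment/observation instance respecting the one-cause rule.
random_instance <- function(n_tumours = 20, n_sgas = 8, n_degs = 15,
                            p_deg = 0.5) {
  tumours <- paste0("t", seq_len(n_tumours))
  sgas <- paste0("s", seq_len(n_sgas))
  degs <- paste0("d", seq_len(n_degs))
  rows <- list()
  obs <- list()
  for (t in tumours) {
    hit <- degs[stats::runif(n_degs) < p_deg]
    causes <- sample(sgas, length(hit), replace = TRUE)
    if (length(hit)) {
      rows[[t]] <- data.frame(tumour_id = t, sga = causes, deg = hit,
                              posterior = stats::runif(length(hit)),
                              stringsAsFactors = FALSE)
    }
    extra <- sample(sgas, sample.int(3, 1))
    obs[[t]] <- data.frame(tumour_id = t, sga = unique(c(causes, extra)),
                           stringsAsFactors = FALSE)
  }
  list(assignments = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       observations = do.call(rbind, c(obs, list(make.row.names = FALSE))))
}

# Loose thresholds under which small random instances produce non-trivial
# outcomes at every standard.
small_thresholds <- function() {
  filter_thresholds(posterior_floor = 0.3, min_degs_per_driver = 2L,
                    min_driver_tumours = 3L, min_driver_fraction = 0.25,
                    min_relationship_tumours = 4L,
                    min_relationship_fraction = 0.3)
}

# Exact upper-tail hypergeometric probability by enumerating all draw
# compositions with choose().
oracle_hypergeom <- function(overlap, n_set, n_universe, n_draw) {
  total <- 0
  for (x in overlap:min(n_set, n_draw)) {
    if (n_draw - x > n_universe - n_set) next
    total <- total + choose(n_set, x) * choose(n_universe - n_set, n_draw - x)
  }
  total / choose(n_universe, n_draw)
}

# Harrell's C by exhaustive pair enumeration (small n only).
oracle_cindex <- function(scores, time, event) {
  conc <- 0
  comp <- 0
  n <- length(time)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      early <- if (time[i] < time[j]) i else if (time[j] < time[i]) j else NA
      if (is.na(early)) next           # tied times: not comparable here
      if (event[early] != 1) next
      comp <- comp + 1
      late <- if (early == i) j else i
      if (scores[early] > scores[late]) conc <- conc + 1
      else if (scores[early] == scores[late]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Exhaustive k = 2 medoid search minimizing summed dissimilarity.
oracle_pam2 <- function(d) {
  n <- nrow(d)
  best <- NULL
  best_cost <- Inf
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cost <- sum(pmin(d[, i], d[, j]))
      if (cost < best_cost) {
        best_cost <- cost
        best <- as.integer(d[, i] > d[, j]) + 1L
      }
    }
  }
  list(labels = best, cost = best_cost)
}

# Weighted block affinity matrix with planted modules.
planted_affinity <- function(sizes, within = 1, between = 0) {
  n <- sum(sizes)
  labels <- rep(seq_along(sizes), sizes)
  A <- matrix(between, n, n)
  for (b in seq_along(sizes)) {
    idx <- which(labels == b)
    A[idx, idx] <- within
  }
  diag(A) <- 0
  rownames(A) <- colnames(A) <- paste0("g", seq_len(n))
  list(A = A, labels = labels)
}
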