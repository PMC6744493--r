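#' Specification of a synthetic tumour cohort
#'
#' Describes a cohort with planted pathway structure: each pathway owns a
#' small set of interchangeable driver SGAs and a signature set of DEGs.
#' In a tumour where a pathway is active, one of its drivers is observed
#' and assigned (with high posterior) as the cause of a random subset of
#' the signature; passenger SGAs are sprinkled in with few, low-posterior
#' assignments. Tumours belong to archetypal disease mechanisms: each
#' patient draws one of `n_archetypes` binary pathway-activation profiles
#' and flips each pathway independently with probability
#' `archetype_flip_rate`, so that patients form genuine subgroups with
#' distinct combinations of pathway aberrations. Expression tracks pathway
#' activation, and survival hazard is log-linear in the activation vector.
#' The defaults describe a cohort of 200 tumours with 5 pathways of 40
#' signature DEGs each — large enough
#' for every filtering standard and both clustering stages to operate,
#' small enough to regenerate in seconds.
#'
#' @param n_tumours Number of tumours (= patients).
#' @param n_pathways Number of planted pathways (modules).
#' @param drivers_per_pathway Interchangeable driver SGAs per pathway.
#' @param signature_size Signature DEGs per pathway.
#' @param signature_overlap Fraction of each signature shared with the next
#'   pathway (0 = disjoint signatures).
#' @param n_passengers Number of passenger SGAs in the pool.
#' @param n_archetypes Number of archetypal activation profiles (patient
#'   subgroups).
#' @param archetype_flip_rate Per-pathway probability that a patient's
#'   activation deviates from their archetype.
#' @param archetypes Optional binary matrix (`n_archetypes` x
#'   `n_pathways`) of activation profiles; the default uses a fixed
#'   balanced design for 4 archetypes over 5 pathways (each pathway active
#'   in half the archetypes, pairwise Hamming distance >= 3) and a seeded
#'   maximin-distance search otherwise.
#' @param pathway_activation_rate Marginal probability a pathway is active
#'   in a randomly drawn archetype (used only when archetypes are
#'   searched, not for the fixed default design).
#' @param deg_assignment_rate Probability an active driver is assigned to
#'   each individual signature DEG (at least `min_degs_per_assignment` are
#'   always assigned).
#' @param min_degs_per_assignment Lower bound on DEGs per active driver.
#' @param passenger_obs_rate Probability a passenger SGA is observed in a
#'   tumour.
#' @param passenger_assignment_rate Probability an observed passenger picks
#'   up 1-3 low-posterior assignments.
#' @param driver_spurious_obs_rate Probability a driver is observed in a
#'   tumour whose pathway is inactive (observation without causal role).
#' @param posterior_true Range of posteriors for planted assignments
#'   (uniform).
#' @param posterior_noise Range of posteriors for passenger assignments.
#' @param expression_effect Mean expression shift of signature genes in
#'   activated patients.
#' @param expression_noise_sd Standard deviation of expression noise.
#' @param platform_dropout Fraction of DEGs absent from the expression
#'   platform (exercises effective-DEG handling).
#' @param hazard_coefficients Log-hazard coefficient per pathway (recycled
#'   to `n_pathways`).
#' @param baseline_hazard Baseline exponential hazard per day.
#' @param censoring_fraction Target fraction of censored patients; the
#'   uniform censoring horizon is tuned to it by bisection.
#' @return Object of class `cohort_spec` (a named list).
#' @export
cohort_spec <- function(n_tumours = 200L,
                        n_pathways = 5L,
                        drivers_per_pathway = 2L,
                        signature_size = 40L,
                        signature_overlap = 0,
                        n_passengers = 30L,
                        n_archetypes = 4L,
                        archetype_flip_rate = 0.05,
                        archetypes = NULL,
                        pathway_activation_rate = 0.5,
                        deg_assignment_rate = 0.6,
                        min_degs_per_assignment = 5L,
                        passenger_obs_rate = 0.15,
                        passenger_assignment_rate = 0.5,
                        driver_spurious_obs_rate = 0.05,
                        posterior_true = c(0.7, 1.0),
                        posterior_noise = c(0.0, 0.4),
                        expression_effect = 2.0,
                        expression_noise_sd = 1.0,
                        platform_dropout = 0.1,
                        hazard_coefficients = c(0.8, 0.6, -0.5, 0.4, -0.6),
                        baseline_hazard = 1 / 1500,
                        censoring_fraction = 0.3) {
  spec <- list(n_tumours = as.integer(n_tumours),
               n_pathways = as.integer(n_pathways),
               drivers_per_pathway = as.integer(drivers_per_pathway),
               signature_size = as.integer(signature_size),
               signature_overlap = signature_overlap,
               n_passengers = as.integer(n_passengers),
               n_archetypes = as.integer(n_archetypes),
               archetype_flip_rate = archetype_flip_rate,
               archetypes = archetypes,
               pathway_activation_rate = pathway_activation_rate,
               deg_assignment_rate = deg_assignment_rate,
               min_degs_per_assignment = as.integer(min_degs_per_assignment),
               passenger_obs_rate = passenger_obs_rate,
               passenger_assignment_rate = passenger_assignment_rate,
               driver_spurious_obs_rate = driver_spurious_obs_rate,
               posterior_true = posterior_true,
               posterior_noise = posterior_noise,
               expression_effect = expression_effect,
               expression_noise_sd = expression_noise_sd,
               platform_dropout = platform_dropout,
               hazard_coefficients = rep_len(hazard_coefficients, n_pathways),
               baseline_hazard = baseline_hazard,
               censoring_fraction = censoring_fraction)
  with(spec, stopifnot(
    n_tumours >= 1L, n_pathways >= 1L, drivers_per_pathway >= 1L,
    signature_size >= min_degs_per_assignment,
    signature_overlap >= 0, signature_overlap < 1,
    n_archetypes >= 1L, archetype_flip_rate >= 0, archetype_flip_rate < 0.5,
    is.null(archetypes) ||
      (is.matrix(archetypes) && nrow(archetypes) == n_archetypes &&
         ncol(archetypes) == n_pathways && all(archetypes %in% c(0L, 1L))),
    pathway_activation_rate > 0, pathway_activation_rate <= 1,
    deg_assignment_rate > 0, deg_assignment_rate <= 1,
    passenger_obs_rate >= 0, passenger_obs_rate <= 1,
    passenger_assignment_rate >= 0, passenger_assignment_rate <= 1,
    posterior_true[1] <= posterior_true[2], posterior_true[2] <= 1,
    posterior_noise[1] >= 0, posterior_noise[1] <= posterior_noise[2],
    expression_noise_sd >= 0, baseline_hazard > 0,
    censoring_fraction >= 0, censoring_fraction < 1))
  structure(spec, class = "cohort_spec")
}

# Archetypal activation profiles. For the canonical 4-archetype,
# 5-pathway configuration a fixed balanced design is used: every pathway
# is active in exactly half the archetypes, no archetype is inactive
# everywhere, and pairwise Hamming distances are >= 3 so the mechanisms
# are genuinely distinct. Other shapes fall back to a maximin-Hamming
# random search over non-degenerate profiles (consuming the cohort's RNG
# stream, hence reproducible for a given seed).
default_archetypes <- function(G, P, activation_rate) {
  if (G == 4L && P == 5L) {
    return(matrix(c(1L, 1L, 0L, 0L, 0L,
                    0L, 0L, 1L, 1L, 0L,
                    1L, 0L, 0L, 1L, 1L,
                    0L, 1L, 1L, 0L, 1L),
                  nrow = 4L, byrow = TRUE))
  }
  best <- NULL
  best_d <- -1L
  for (try in 1:200) {
    cand <- matrix(stats::rbinom(G * P, 1L, activation_rate), G, P)
    if (any(rowSums(cand) == 0L)) next
    if (G == 1L) return(cand)
    d <- min(stats::dist(cand, method = "manhattan"))
    if (d > best_d) {
      best_d <- d
      best <- cand
    }
  }
  if (is.null(best)) {
    stop("could not construct non-degenerate archetype profiles", call. = FALSE)
  }
  best
}

# Tune the uniform censoring horizon c so that the expected censored
# fraction, given the realized event times, matches the target:
# P(censored | T = t, C ~ U(0, c)) = min(t / c, 1).
tune_censoring_horizon <- function(times, target) {
  expected_censored <- function(cc) mean(pmin(times / cc, 1))
  lo <- min(times) / 2
  hi <- max(times) * 1e4
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected_censored(mid) > target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a synthetic cohort with planted pathway structure
#'
#' Produces the six input tables the pipeline consumes (causal assignments,
#' SGA observations, expression, clinical covariates, survival, and, via
#' [planted_gene_sets()], gene-set collections), plus the ground truth that
#' generated them. The one-cause rule (each DEG has at most one assigned
#' SGA cause per tumour) is enforced by construction and asserted before
#' returning.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return Object of class `synthetic_cohort`: list with `assignments`,
#'   `observations`, `expression` (patients x genes matrix), `clinical`,
#'   `survival`, and `truth` (pathway drivers, signatures, activation
#'   matrix, hazard coefficients).
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(seed, generate_cohort_impl(spec, seed))
}

generate_cohort_impl <- function(spec, seed) {
  P <- spec$n_pathways
  tumours <- sprintf("T%03d", seq_len(spec$n_tumours))

  drivers <- lapply(seq_len(P), function(p) {
    sprintf("DRV%d_%d", p, seq_len(spec$drivers_per_pathway))
  })
  passengers <- sprintf("PSG%02d", seq_len(spec$n_passengers))

  # Signatures: consecutive pathways may share a configurable slice.
  n_shared <- floor(spec$signature_overlap * spec$signature_size)
  signatures <- vector("list", P)
  counter <- 0L
  for (p in seq_len(P)) {
    n_new <- spec$signature_size - if (p > 1L) n_shared else 0L
    new_genes <- sprintf("DEG%04d", counter + seq_len(n_new))
    counter <- counter + n_new
    shared <- if (p > 1L && n_shared > 0L) {
      utils::tail(signatures[[p - 1L]], n_shared)
    } else {
      character()
    }
    signatures[[p]] <- c(shared, new_genes)
  }
  all_degs <- unique(unlist(signatures))

  # Archetypal disease mechanisms: a binary activation profile per patient
  # subgroup, plus per-pathway flip noise.
  archetypes <- spec$archetypes
  if (is.null(archetypes)) {
    archetypes <- default_archetypes(spec$n_archetypes, P,
                                     spec$pathway_activation_rate)
  }
  patient_group <- sample.int(nrow(archetypes), spec$n_tumours, replace = TRUE)
  activation <- archetypes[patient_group, , drop = FALSE]
  flips <- matrix(stats::runif(spec$n_tumours * P) < spec$archetype_flip_rate,
                  spec$n_tumours, P)
  activation <- abs(activation - flips)
  storage.mode(activation) <- "integer"
  dimnames(activation) <- list(tumours, paste0("pathway_", seq_len(P)))
  # A tumour with no active pathway gets one, so every tumour has a driver.
  none <- rowSums(activation) == 0L
  if (any(none)) {
    activation[cbind(which(none), sample.int(P, sum(none), replace = TRUE))] <- 1L
  }

  assign_rows <- list()
  obs_rows <- list()
  for (i in seq_len(spec$n_tumours)) {
    taken <- character()          # DEGs already assigned in this tumour
    t_assign <- list()
    t_obs <- character()
    for (p in seq_len(P)) {
      if (activation[i, p] == 1L) {
        drv <- drivers[[p]][sample.int(spec$drivers_per_pathway, 1L)]
        t_obs <- c(t_obs, drv)
        pool <- setdiff(signatures[[p]], taken)
        n_pick <- sum(stats::runif(length(pool)) < spec$deg_assignment_rate)
        n_pick <- min(length(pool), max(spec$min_degs_per_assignment, n_pick))
        if (n_pick > 0L) {
          degs <- pool[sample.int(length(pool), n_pick)]
          taken <- c(taken, degs)
          t_assign[[length(t_assign) + 1L]] <- data.frame(
            tumour_id = tumours[i], sga = drv, deg = degs,
            posterior = stats::runif(n_pick, spec$posterior_true[1],
                                     spec$posterior_true[2]),
            stringsAsFactors = FALSE)
        }
      } else if (stats::runif(1) < spec$driver_spurious_obs_rate) {
        t_obs <- c(t_obs, drivers[[p]][sample.int(spec$drivers_per_pathway, 1L)])
      }
    }
    psg_obs <- passengers[stats::runif(spec$n_passengers) < spec$passenger_obs_rate]
    t_obs <- c(t_obs, psg_obs)
    for (psg in psg_obs) {
      if (stats::runif(1) < spec$passenger_assignment_rate) {
        pool <- setdiff(all_degs, taken)
        n_pick <- min(length(pool), sample.int(3L, 1L))
        if (n_pick > 0L) {
          degs <- pool[sample.int(length(pool), n_pick)]
          taken <- c(taken, degs)
          t_assign[[length(t_assign) + 1L]] <- data.frame(
            tumour_id = tumours[i], sga = psg, deg = degs,
            posterior = stats::runif(n_pick, spec$posterior_noise[1],
                                     spec$posterior_noise[2]),
            stringsAsFactors = FALSE)
        }
      }
    }
    assign_rows[[i]] <- do.call(rbind, t_assign)
    obs_rows[[i]] <- data.frame(tumour_id = tumours[i], sga = unique(t_obs),
                                stringsAsFactors = FALSE)
  }
  assignments <- do.call(rbind, assign_rows)
  rownames(assignments) <- NULL
  observations <- do.call(rbind, obs_rows)
  rownames(observations) <- NULL

  # Hard assertion of the one-cause rule.
  stopifnot(!anyDuplicated(paste(assignments$tumour_id, assignments$deg)))

  # Expression: signature genes shift by the effect size in activated
  # patients; everything rides on Gaussian noise. A platform dropout slice
  # of DEGs is withheld from the matrix.
  platform <- all_degs
  n_drop <- floor(spec$platform_dropout * length(all_degs))
  if (n_drop > 0L) {
    platform <- setdiff(platform, sample(all_degs, n_drop))
  }
  platform <- sort(platform)
  expression <- matrix(stats::rnorm(spec$n_tumours * length(platform),
                                    sd = spec$expression_noise_sd),
                       spec$n_tumours, length(platform),
                       dimnames = list(tumours, platform))
  for (p in seq_len(P)) {
    genes <- intersect(signatures[[p]], platform)
    active <- activation[, p] == 1L
    expression[active, genes] <- expression[active, genes] + spec$expression_effect
  }

  # Clinical covariates: age plus two binary markers, the first associated
  # with pathway 1 activation.
  age <- round(stats::rnorm(spec$n_tumours, 60, 10), 1)
  marker1 <- stats::rbinom(spec$n_tumours, 1L,
                           ifelse(activation[, 1L] == 1L, 0.7, 0.3))
  marker2 <- stats::rbinom(spec$n_tumours, 1L, 0.5)
  clinical <- data.frame(patient_id = tumours, age = age,
                         marker1 = marker1, marker2 = marker2,
                         stringsAsFactors = FALSE)

  # Survival: exponential with log-hazard linear in pathway activation,
  # censoring uniform on a horizon tuned to the target censored fraction.
  log_hazard <- log(spec$baseline_hazard) +
    as.vector(activation %*% spec$hazard_coefficients)
  true_time <- stats::rexp(spec$n_tumours, rate = exp(log_hazard))
  if (spec$censoring_fraction > 0) {
    horizon <- tune_censoring_horizon(true_time, spec$censoring_fraction)
    cens_time <- stats::runif(spec$n_tumours, 0, horizon)
  } else {
    cens_time <- rep(Inf, spec$n_tumours)
  }
  event <- as.integer(true_time <= cens_time)
  time <- pmin(true_time, cens_time)
  survival <- data.frame(patient_id = tumours,
                         time = round(pmax(time, 1 / 24), 3),
                         event = event, stringsAsFactors = FALSE)

  truth <- list(drivers = stats::setNames(drivers, paste0("pathway_", seq_len(P))),
                signatures = stats::setNames(signatures, paste0("pathway_", seq_len(P))),
                passengers = passengers,
                archetypes = archetypes,
                patient_group = stats::setNames(patient_group, tumours),
                activation = activation,
                hazard_coefficients = spec$hazard_coefficients,
                platform = platform,
                seed = as.integer(seed))

  structure(list(assignments = assignments, observations = observations,
                 expression = expression, clinical = clinical,
                 survival = survival, truth = truth, spec = spec),
            class = "synthetic_cohort")
}

#' Gene-set collection with planted signatures
#'
#' Builds a GMT-style collection containing each planted pathway signature
#' plus random decoy sets drawn from the DEG universe, for exercising the
#' gene-set overlap ranking.
#'
#' @param cohort A `synthetic_cohort`.
#' @param n_decoys Number of random decoy sets.
#' @param decoy_size Genes per decoy set.
#' @param seed Integer seed for the decoys.
#' @return Named list of character vectors.
#' @export
planted_gene_sets <- function(cohort, n_decoys = 20L, decoy_size = 40L,
                              seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  universe <- unique(unlist(cohort$truth$signatures))
  decoys <- with_seed(seed, {
    lapply(seq_len(n_decoys), function(i) {
      sample(universe, min(decoy_size, length(universe)))
    })
  })
  names(decoys) <- sprintf("DECOY_SET_%02d", seq_len(n_decoys))
  c(stats::setNames(cohort$truth$signatures,
                    paste0("PLANTED_", toupper(names(cohort$truth$signatures)))),
    decoys)
}

#' Write a synthetic cohort to disk
#'
#' Writes `assignments.tsv`, `observations.tsv`, `expression.tsv`,
#' `clinical.tsv`, `survival.tsv` and `truth.json` into `dir`, in the
#' formats the pipeline readers expect.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(cohort$assignments, "assignments.tsv")
  tsv(cohort$observations, "observations.tsv")
  expr <- data.frame(patient_id = rownames(cohort$expression),
                     cohort$expression, check.names = FALSE)
  tsv(expr, "expression.tsv")
  tsv(cohort$clinical, "clinical.tsv")
  tsv(cohort$survival, "survival.tsv")
  truth <- cohort$truth
  truth$activation <- as.data.frame(truth$activation)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a synthetic cohort written by [write_cohort()]
#'
#' @param dir Directory with the cohort files.
#' @return A `synthetic_cohort`-shaped list (without the generating spec).
#' @export
read_cohort <- function(dir) {
  assignments <- read_assignments(file.path(dir, "assignments.tsv"))
  observations <- read_observations(file.path(dir, "observations.tsv"))
  expression <- read_expression_matrix(file.path(dir, "expression.tsv"))
  clinical <- read_clinical(file.path(dir, "clinical.tsv"))
  survival <- read_survival(file.path(dir, "survival.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  if (!is.null(truth$activation)) {
    truth$activation <- as.matrix(truth$activation)
    rownames(truth$activation) <- rownames(expression)
  }
  structure(list(assignments = assignments, observations = observations,
                 expression = expression, clinical = clinical,
                 survival = survival, truth = truth),
            class = "synthetic_cohort")
}
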