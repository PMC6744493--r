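#' Thresholds for the causal-assignment filtering standards
#'
#' Bundles the cut-offs used by the four filtering standards that separate
#' recurrent driver SGAs and their robust SGA->DEG relationships from noise:
#' a posterior floor, a per-tumour driver call ("cause of 5 or more DEGs"),
#' a cohort-level driver significance rule (called driver in at least 30
#' tumours AND in at least 25% of the tumours where the SGA is observed),
#' and a relationship significance rule (the DEG is caused by the SGA in at
#' least 50 tumours OR in at least 20% of the tumours where the SGA is
#' called a driver).
#'
#' @param posterior_floor Posterior probability floor; assignments with
#'   posterior strictly greater than this survive standard 1. Stands in for
#'   a permutation-calibrated threshold and may be a single scalar applied
#'   globally.
#' @param min_degs_per_driver Minimum number of distinct DEGs an SGA must
#'   cause within one tumour to be called a driver there.
#' @param min_driver_tumours Minimum number of tumours in which an SGA must
#'   be called a driver.
#' @param min_driver_fraction Minimum fraction of observed-SGA tumours in
#'   which the SGA must be called a driver.
#' @param min_relationship_tumours Minimum number of tumours supporting an
#'   SGA->DEG pair for relationship significance (the count branch).
#' @param min_relationship_fraction Minimum fraction of the SGA's driver
#'   tumours supporting the pair (the fraction branch of the disjunction).
#' @return An object of class `filter_thresholds` (a named list).
#' @export
filter_thresholds <- function(posterior_floor = 0.5,
                              min_degs_per_driver = 5L,
                              min_driver_tumours = 30L,
                              min_driver_fraction = 0.25,
                              min_relationship_tumours = 50L,
                              min_relationship_fraction = 0.20) {
  stopifnot(is_scalar_number(posterior_floor), posterior_floor >= 0, posterior_floor <= 1,
            is_scalar_number(min_degs_per_driver), min_degs_per_driver >= 1,
            is_scalar_number(min_driver_tumours), min_driver_tumours >= 1,
            is_scalar_number(min_driver_fraction), min_driver_fraction > 0, min_driver_fraction <= 1,
            is_scalar_number(min_relationship_tumours), min_relationship_tumours >= 1,
            is_scalar_number(min_relationship_fraction), min_relationship_fraction > 0,
            min_relationship_fraction <= 1)
  structure(list(posterior_floor = posterior_floor,
                 min_degs_per_driver = as.integer(min_degs_per_driver),
                 min_driver_tumours = as.integer(min_driver_tumours),
                 min_driver_fraction = min_driver_fraction,
                 min_relationship_tumours = as.integer(min_relationship_tumours),
                 min_relationship_fraction = min_relationship_fraction),
            class = "filter_thresholds")
}

validate_assignments <- function(assignments) {
  stop_missing_columns(assignments, c("tumour_id", "sga", "deg", "posterior"),
                       "assignment table")
  if (any(!is.finite(assignments$posterior)) ||
      any(assignments$posterior < 0) || any(assignments$posterior > 1)) {
    stop("assignment posteriors must lie in [0, 1]", call. = FALSE)
  }
  invisible(assignments)
}

# Collapse duplicate (tumour, sga, deg) rows keeping the maximum posterior.
collapse_duplicates <- function(assignments) {
  key <- paste(assignments$tumour_id, assignments$sga, assignments$deg, sep = "\r")
  if (!anyDuplicated(key)) {
    return(assignments)
  }
  warning("duplicate (tumour, sga, deg) assignment rows collapsed to the maximum posterior",
          call. = FALSE)
  keep <- !duplicated(key)
  best <- tapply(assignments$posterior, key, max)
  out <- assignments[keep, , drop = FALSE]
  out$posterior <- as.numeric(best[paste(out$tumour_id, out$sga, out$deg, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Standard 1: keep assignments whose posterior clears the floor
#'
#' Retains exactly the causal assignments whose posterior probability is
#' strictly greater than `posterior_floor`, preserving row order. Duplicate
#' (tumour, SGA, DEG) rows are collapsed beforehand, keeping the maximum
#' posterior, with a warning.
#'
#' @param assignments Data frame with columns `tumour_id`, `sga`, `deg`,
#'   `posterior`.
#' @param posterior_floor Scalar floor in \[0, 1\].
#' @return The filtered assignment data frame.
#' @export
filter_valid_assignments <- function(assignments, posterior_floor = 0.5) {
  validate_assignments(assignments)
  stopifnot(is_scalar_number(posterior_floor),
            posterior_floor >= 0, posterior_floor <= 1)
  assignments <- collapse_duplicates(assignments)
  out <- assignments[assignments$posterior > posterior_floor, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard 2: per-tumour driver calls
#'
#' An SGA is called a driver in a tumour when it is the assigned cause of at
#' least `min_degs_per_driver` distinct DEGs in that tumour.
#'
#' @param assignments Posterior-filtered assignment table.
#' @param thresholds A [filter_thresholds()] object (only
#'   `min_degs_per_driver` is used).
#' @return Data frame with columns `tumour_id`, `sga`, `n_degs`, one row per
#'   driver call.
#' @export
call_tumour_drivers <- function(assignments, thresholds = filter_thresholds()) {
  validate_assignments(assignments)
  if (nrow(assignments) == 0L) {
    return(data.frame(tumour_id = character(), sga = character(),
                      n_degs = integer(), stringsAsFactors = FALSE))
  }
  key <- paste(assignments$tumour_id, assignments$sga, sep = "\r")
  n_degs <- tapply(assignments$deg, key, function(d) length(unique(d)))
  keep <- n_degs >= thresholds$min_degs_per_driver
  keys <- names(n_degs)[keep]
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(tumour_id = vapply(parts, `[`, "", 1L),
                    sga = vapply(parts, `[`, "", 2L),
                    n_degs = as.integer(n_degs[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$tumour_id, out$sga), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard 3: cohort-level significant drivers
#'
#' An SGA is a significant driver when it is called a driver in at least
#' `min_driver_tumours` tumours AND those driver calls make up at least
#' `min_driver_fraction` of the tumours where the SGA was observed as a
#' somatic alteration.
#'
#' @param driver_calls Output of [call_tumour_drivers()].
#' @param observations Data frame with columns `tumour_id`, `sga`, one row
#'   per observed somatic alteration.
#' @param thresholds A [filter_thresholds()] object.
#' @return Data frame with columns `sga`, `n_driver_tumours`,
#'   `n_observed_tumours`, `driver_fraction`, restricted to significant
#'   drivers.
#' @export
call_significant_drivers <- function(driver_calls, observations,
                                     thresholds = filter_thresholds()) {
  stop_missing_columns(driver_calls, c("tumour_id", "sga"), "driver call table")
  stop_missing_columns(observations, c("tumour_id", "sga"), "observation table")
  sgas <- unique(driver_calls$sga)
  if (length(sgas) == 0L) {
    return(data.frame(sga = character(), n_driver_tumours = integer(),
                      n_observed_tumours = integer(), driver_fraction = numeric(),
                      stringsAsFactors = FALSE))
  }
  obs_key <- unique(paste(observations$tumour_id, observations$sga, sep = "\r"))
  obs_sga <- vapply(strsplit(obs_key, "\r", fixed = TRUE), `[`, "", 2L)
  n_obs <- table(obs_sga)
  drv_key <- unique(paste(driver_calls$tumour_id, driver_calls$sga, sep = "\r"))
  drv_sga <- vapply(strsplit(drv_key, "\r", fixed = TRUE), `[`, "", 2L)
  n_drv <- table(drv_sga)

  n_driver <- as.integer(n_drv[sgas])
  n_observed <- as.integer(n_obs[sgas])
  n_observed[is.na(n_observed)] <- 0L
  if (any(n_observed == 0L)) {
    stop(sprintf("SGA(s) called driver but never observed: %s",
                 paste(sgas[n_observed == 0L], collapse = ", ")), call. = FALSE)
  }
  frac <- n_driver / n_observed
  keep <- n_driver >= thresholds$min_driver_tumours &
    frac >= thresholds$min_driver_fraction
  out <- data.frame(sga = sgas, n_driver_tumours = n_driver,
                    n_observed_tumours = n_observed, driver_fraction = frac,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$sga), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Standard 4: significant SGA->DEG relationships
#'
#' A pair is significant when the SGA is a significant driver AND the DEG is
#' caused by that SGA in at least `min_relationship_tumours` tumours OR in
#' at least `min_relationship_fraction` of the tumours where the SGA is
#' called a driver (a disjunction).
#'
#' @param assignments Posterior-filtered assignment table.
#' @param significant_drivers Output of [call_significant_drivers()] (or a
#'   character vector of SGA symbols).
#' @param driver_calls Output of [call_tumour_drivers()].
#' @param thresholds A [filter_thresholds()] object.
#' @return Data frame with columns `sga`, `deg`, `n_tumours`,
#'   `driver_tumours`, `fraction`.
#' @export
call_significant_relationships <- function(assignments, significant_drivers,
                                           driver_calls,
                                           thresholds = filter_thresholds()) {
  validate_assignments(assignments)
  sig_sgas <- if (is.data.frame(significant_drivers)) significant_drivers$sga
              else as.character(significant_drivers)
  empty <- data.frame(sga = character(), deg = character(), n_tumours = integer(),
                      driver_tumours = integer(), fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (length(sig_sgas) == 0L || nrow(assignments) == 0L) {
    return(empty)
  }
  drv_key <- unique(paste(driver_calls$tumour_id, driver_calls$sga, sep = "\r"))
  drv_sga <- vapply(strsplit(drv_key, "\r", fixed = TRUE), `[`, "", 2L)
  n_driver_tumours <- table(drv_sga)

  a <- assignments[assignments$sga %in% sig_sgas, , drop = FALSE]
  if (nrow(a) == 0L) {
    return(empty)
  }
  pair_key <- paste(a$sga, a$deg, sep = "\r")
  n_tum <- tapply(a$tumour_id, pair_key, function(t) length(unique(t)))
  parts <- strsplit(names(n_tum), "\r", fixed = TRUE)
  sga <- vapply(parts, `[`, "", 1L)
  deg <- vapply(parts, `[`, "", 2L)
  drv_n <- as.integer(n_driver_tumours[sga])
  drv_n[is.na(drv_n)] <- 0L
  frac <- ifelse(drv_n > 0L, as.numeric(n_tum) / drv_n, 0)
  keep <- as.integer(n_tum) >= thresholds$min_relationship_tumours |
    frac >= thresholds$min_relationship_fraction
  out <- data.frame(sga = sga, deg = deg, n_tumours = as.integer(n_tum),
                    driver_tumours = drv_n, fraction = frac,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  out <- out[order(out$sga, out$deg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Restrict an assignment table to significant relationships
#'
#' Keeps assignments whose (SGA, DEG) pair appears in the significant
#' relationship set. Tumours left without any significant assignment simply
#' disappear from the table and hence from downstream tumour counts.
#'
#' @param assignments Assignment table.
#' @param significant_relationships Output of
#'   [call_significant_relationships()] (columns `sga`, `deg` are used).
#' @return The projected assignment data frame.
#' @export
project_to_significant <- function(assignments, significant_relationships) {
  validate_assignments(assignments)
  sig_key <- paste(significant_relationships$sga, significant_relationships$deg,
                   sep = "\r")
  key <- paste(assignments$sga, assignments$deg, sep = "\r")
  out <- assignments[key %in% sig_key, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply all four filtering standards
#'
#' Convenience wrapper chaining [filter_valid_assignments()],
#' [call_tumour_drivers()], [call_significant_drivers()],
#' [call_significant_relationships()] and [project_to_significant()].
#'
#' @param assignments Raw assignment table.
#' @param observations SGA observation table (`tumour_id`, `sga`).
#' @param thresholds A [filter_thresholds()] object.
#' @return A list with elements `valid_assignments`, `driver_calls`,
#'   `significant_drivers`, `significant_relationships` and
#'   `significant_assignments`.
#' @export
apply_filter_standards <- function(assignments, observations,
                                   thresholds = filter_thresholds()) {
  valid <- filter_valid_assignments(assignments, thresholds$posterior_floor)
  drivers <- call_tumour_drivers(valid, thresholds)
  sig_drivers <- call_significant_drivers(drivers, observations, thresholds)
  rels <- call_significant_relationships(valid, sig_drivers, drivers, thresholds)
  sig <- project_to_significant(valid, rels)
  list(valid_assignments = valid,
       driver_calls = drivers,
       significant_drivers = sig_drivers,
       significant_relationships = rels,
       significant_assignments = sig)
}
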