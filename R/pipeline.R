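#' Pipeline configuration
#'
#' Collects every tunable the end-to-end pipeline uses, with the defaults
#' the package recommends. Any entry can be overridden by name.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return Object of class `pipeline_config` (a named list).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    thresholds = filter_thresholds(),
    node_min_fraction = 0.10,
    min_edge_weight = 1L,
    sigma = NULL,                 # NULL = median pseudo-distance
    sigma_quantile = 0.5,
    k_modules = NULL,             # NULL = stability-based selection
    module_candidate_ks = 2:8,
    module_runs = 100L,
    module_stability_floor = 0.8,
    dominance_threshold = 0.10,
    group_ks = 2:15,
    group_resamples = 100L,
    subsample_fraction = 0.8,
    group_delta_threshold = 0.03,
    group_stability_floor = 0.8,
    complete_cases = TRUE)
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0L) {
    stop(sprintf("unknown pipeline option(s): %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  cfg[names(overrides)] <- overrides
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Chains all stages: filtering standards, DEG network construction,
#' spectral consensus modules, dominant-SGA attribution, module patient
#' features, PAM consensus patient groups (both with and without clinical
#' covariates), and survival evaluation (Kaplan-Meier per group, log-rank
#' tests, Cox models with C-index). Every stochastic stage derives its seed
#' from `seed`, so the whole run is reproducible.
#'
#' @param cohort A `synthetic_cohort`, or any list with elements
#'   `assignments`, `observations`, `expression`, `clinical`, `survival`.
#' @param config A [pipeline_config()].
#' @param seed Integer master seed.
#' @return A named list of stage outputs plus a `manifest` recording
#'   configuration, seeds and table digests.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), seed = 1L) {
  stopifnot(inherits(config, "pipeline_config"))

  filtered <- apply_filter_standards(cohort$assignments, cohort$observations,
                                     config$thresholds)
  sig <- filtered$significant_assignments
  if (nrow(sig) == 0L) stop("pipeline aborted at stage 'filter': no significant assignments",
                            call. = FALSE)

  nodes <- filter_network_nodes(sig, config$node_min_fraction)
  instances <- enumerate_coregulation(sig, nodes)
  network <- build_deg_network(instances, nodes, config$min_edge_weight)
  if (length(network$nodes) < 3L) {
    stop("pipeline aborted at stage 'network': fewer than 3 nodes", call. = FALSE)
  }

  D <- pseudo_distance(network)
  sigma <- select_sigma(D, q = config$sigma_quantile, sigma = config$sigma)
  A <- gaussian_affinity(D, sigma)
  if (is.null(config$k_modules)) {
    ks <- config$module_candidate_ks
    ks <- ks[ks <= sum(rowSums(A) > 0)]
    sel <- select_module_count(A, candidate_ks = ks, runs = config$module_runs,
                               stability_floor = config$module_stability_floor,
                               base_seed = derive_seed(seed, 11L))
    k_modules <- sel$k
    module_scores <- sel$scores
  } else {
    k_modules <- config$k_modules
    module_scores <- NULL
  }
  partition <- final_partition(A, k_modules, seed = derive_seed(seed, 12L))
  dominance <- dominant_sgas(partition, network$provenance,
                             config$dominance_threshold)

  mf <- module_feature_table(partition, cohort$expression)
  features_all <- zscore_normalize(
    assemble_features(mf, cohort$clinical, config$complete_cases))
  features_modules <- zscore_normalize(
    assemble_features(mf, NULL, config$complete_cases))

  surv <- cohort$survival
  groupings <- list()
  survival_reports <- list()
  for (regime in c("all_features", "modules_only")) {
    feats <- if (regime == "all_features") features_all else features_modules
    ks <- config$group_ks
    ks <- ks[ks < max(2L, floor(config$subsample_fraction * nrow(feats)))]
    sel <- select_group_count(feats, ks = ks, resamples = config$group_resamples,
                              subsample_fraction = config$subsample_fraction,
                              delta_threshold = config$group_delta_threshold,
                              stability_floor = config$group_stability_floor,
                              seed = derive_seed(seed, 21L))
    labels <- assign_patient_groups(feats, sel$k, seed = derive_seed(seed, 22L))
    groupings[[regime]] <- list(k = sel$k, scores = sel$scores, labels = labels)

    idx <- match(names(labels), surv$patient_id)
    ok <- !is.na(idx)
    time <- surv$time[idx[ok]]
    event <- surv$event[idx[ok]]
    glab <- labels[ok]
    km <- lapply(split(seq_along(glab), glab), function(ii) {
      kaplan_meier(time[ii], event[ii])
    })
    lr <- logrank_test(time, event, glab)
    cox <- tryCatch(cox_fit_by_group(feats[ok, , drop = FALSE], time, event, glab),
                    error = function(e) {
                      warning(sprintf("Cox stage failed (%s): %s", regime,
                                      conditionMessage(e)), call. = FALSE)
                      NULL
                    })
    survival_reports[[regime]] <- list(kaplan_meier = km, logrank = lr, cox = cox)
  }

  manifest <- list(
    seed = as.integer(seed),
    config = unclass(config),
    sigma = sigma,
    k_modules = as.integer(k_modules),
    group_k = lapply(groupings, `[[`, "k"),
    counts = list(assignments_in = nrow(cohort$assignments),
                  significant_assignments = nrow(sig),
                  network_nodes = length(network$nodes),
                  patients = nrow(features_all)),
    digests = list(significant_assignments = table_digest(sig),
                   partition = table_digest(data.frame(deg = names(partition),
                                                       module = as.integer(partition))),
                   labels_all = table_digest(data.frame(
                     patient = names(groupings$all_features$labels),
                     group = as.integer(groupings$all_features$labels))),
                   labels_modules = table_digest(data.frame(
                     patient = names(groupings$modules_only$labels),
                     group = as.integer(groupings$modules_only$labels)))))

  list(filtered = filtered, network = network, sigma = sigma,
       module_scores = module_scores, partition = partition,
       dominance = dominance, features_all = features_all,
       features_modules = features_modules, groupings = groupings,
       survival = survival_reports, manifest = manifest)
}

# MD5 digest of a table via its serialized TSV text, for manifest
# reproducibility checks.
table_digest <- function(df) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f), add = TRUE)
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  unname(tools::md5sum(f))
}
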