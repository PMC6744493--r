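#' Dominant SGAs of each DEG module
#'
#' For every module, counts the co-regulation instances whose DEG pair lies
#' wholly inside the module, grouped by the shared SGA. An SGA is dominant
#' when its share of the module's internal instances is strictly greater
#' than `threshold` ("over 10%" by default). Proportions within a module
#' sum to 1 because each instance carries exactly one SGA.
#'
#' @param partition Named integer label vector (DEG -> module), e.g. from
#'   [final_partition()].
#' @param provenance Co-regulation instance table with columns `tumour_id`,
#'   `sga`, `deg_a`, `deg_b` (a `deg_network`'s `provenance`).
#' @param threshold Dominance threshold on the instance proportion.
#' @return Data frame with columns `module`, `sga`, `n_instances`,
#'   `proportion`, `dominant`, sorted by module then decreasing proportion.
#'   Modules with zero internal instances are absent (not an error).
#' @export
dominant_sgas <- function(partition, provenance, threshold = 0.10) {
  stop_missing_columns(provenance, c("tumour_id", "sga", "deg_a", "deg_b"),
                       "provenance table")
  mod_a <- partition[provenance$deg_a]
  mod_b <- partition[provenance$deg_b]
  internal <- !is.na(mod_a) & !is.na(mod_b) & mod_a == mod_b
  p <- provenance[internal, , drop = FALSE]
  if (nrow(p) == 0L) {
    return(data.frame(module = integer(), sga = character(),
                      n_instances = integer(), proportion = numeric(),
                      dominant = logical(), stringsAsFactors = FALSE))
  }
  module <- as.integer(partition[p$deg_a])
  key <- paste(module, p$sga, sep = "\r")
  counts <- table(key)
  parts <- strsplit(names(counts), "\r", fixed = TRUE)
  out <- data.frame(module = as.integer(vapply(parts, `[`, "", 1L)),
                    sga = vapply(parts, `[`, "", 2L),
                    n_instances = as.integer(counts),
                    stringsAsFactors = FALSE)
  totals <- tapply(out$n_instances, out$module, sum)
  out$proportion <- out$n_instances / as.numeric(totals[as.character(out$module)])
  out$dominant <- out$proportion > threshold
  out <- out[order(out$module, -out$proportion, out$sga), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric overlap p-value
#'
#' Probability of observing at least the seen overlap between a module's
#' genes and a gene set, drawing `|module|` genes without replacement from a
#' universe containing `|set|` successes: `P(X >= overlap)`.
#'
#' @param module_genes Character vector of module gene symbols.
#' @param gene_set Character vector of gene-set members.
#' @param universe Character vector of background genes (typically all
#'   network DEGs).
#' @return List with `overlap`, `p_value`, and the marginals `n_module`,
#'   `n_set`, `n_universe` actually used (all intersected with the
#'   universe).
#' @export
hypergeom_overlap <- function(module_genes, gene_set, universe) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) {
    stop("universe must be non-empty", call. = FALSE)
  }
  module_genes <- intersect(unique(module_genes), universe)
  set_in <- intersect(unique(gene_set), universe)
  overlap <- length(intersect(module_genes, set_in))
  m <- length(set_in)
  n <- length(universe) - m
  k <- length(module_genes)
  p <- stats::phyper(overlap - 1L, m, n, k, lower.tail = FALSE)
  list(overlap = overlap, p_value = p,
       n_module = k, n_set = m, n_universe = length(universe))
}

#' Rank gene sets by overlap with a module
#'
#' Scores every set of a collection against one module with
#' [hypergeom_overlap()] and returns the `top_n` sets sorted by ascending
#' p-value, ties broken by larger overlap then set name.
#'
#' @param module_genes Character vector of module gene symbols.
#' @param collection Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param universe Background gene symbols.
#' @param top_n Number of sets to return (default 10).
#' @return Data frame with columns `set`, `overlap`, `n_set`, `p_value`.
#' @export
rank_gene_sets <- function(module_genes, collection, universe, top_n = 10L) {
  stopifnot(length(collection) >= 1L, !is.null(names(collection)))
  rows <- lapply(names(collection), function(nm) {
    h <- hypergeom_overlap(module_genes, collection[[nm]], universe)
    data.frame(set = nm, overlap = h$overlap, n_set = h$n_set,
               p_value = h$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, -out$overlap, out$set), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_n)
}

#' Per-module composition report
#'
#' Mirrors the per-module summary used for cohort reports: module size,
#' number of effective DEGs (members present on the expression platform)
#' and the dominant SGAs with their co-regulation proportions.
#'
#' @param partition Named integer label vector.
#' @param dominance Output of [dominant_sgas()].
#' @param expression_genes Optional character vector of platform genes; when
#'   given, effective DEG counts are included.
#' @return Data frame with one row per module.
#' @export
module_report <- function(partition, dominance, expression_genes = NULL) {
  modules <- sort(unique(as.integer(partition)))
  rows <- lapply(modules, function(m) {
    genes <- names(partition)[partition == m]
    dom <- dominance[dominance$module == m & dominance$dominant, , drop = FALSE]
    data.frame(module = m,
               n_deg = length(genes),
               n_effective_deg = if (is.null(expression_genes)) NA_integer_
                                 else length(intersect(genes, expression_genes)),
               dominant_sgas = paste(sprintf("%s (%.1f%%)", dom$sga,
                                             100 * dom$proportion),
                                     collapse = "; "),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
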