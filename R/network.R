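#' DEG node frequency filter
#'
#' A DEG becomes a network node only when it is the target of a significant
#' assignment in strictly more than `min_fraction` of the tumours that carry
#' at least one significant assignment.
#'
#' @param significant_assignments Assignment table after the filtering
#'   standards.
#' @param min_fraction Node frequency cut-off (default 0.10, i.e. "more than
#'   10% of the tumours").
#' @return Character vector of retained DEG symbols, sorted.
#' @export
filter_network_nodes <- function(significant_assignments, min_fraction = 0.10) {
  validate_assignments(significant_assignments)
  n_tumours <- length(unique(significant_assignments$tumour_id))
  if (n_tumours == 0L) {
    stop("no tumours with significant assignments; cannot build a network",
         call. = FALSE)
  }
  key <- unique(paste(significant_assignments$tumour_id,
                      significant_assignments$deg, sep = "\r"))
  deg <- vapply(strsplit(key, "\r", fixed = TRUE), `[`, "", 2L)
  counts <- table(deg)
  sort(names(counts)[as.integer(counts) > min_fraction * n_tumours])
}

#' Enumerate co-regulation instances
#'
#' A co-regulation instance is a (tumour, SGA, DEG pair) triple in which
#' both DEGs are assigned to the same SGA in the same tumour. An SGA causing
#' m retained DEGs in a tumour contributes choose(m, 2) instances.
#'
#' @param significant_assignments Assignment table after filtering.
#' @param kept_nodes DEG symbols retained by [filter_network_nodes()].
#' @return Data frame with columns `tumour_id`, `sga`, `deg_a`, `deg_b`
#'   (`deg_a` < `deg_b` lexicographically), one row per instance.
#' @export
enumerate_coregulation <- function(significant_assignments, kept_nodes) {
  validate_assignments(significant_assignments)
  a <- significant_assignments[significant_assignments$deg %in% kept_nodes, ,
                               drop = FALSE]
  empty <- data.frame(tumour_id = character(), sga = character(),
                      deg_a = character(), deg_b = character(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0L) {
    return(empty)
  }
  groups <- split(a$deg, paste(a$tumour_id, a$sga, sep = "\r"))
  pieces <- lapply(names(groups), function(k) {
    degs <- sort(unique(groups[[k]]))
    m <- length(degs)
    if (m < 2L) return(NULL)
    idx <- utils::combn(m, 2L)
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    data.frame(tumour_id = parts[1L], sga = parts[2L],
               deg_a = degs[idx[1L, ]], deg_b = degs[idx[2L, ]],
               stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, TRUE)]
  if (length(pieces) == 0L) {
    return(empty)
  }
  out <- do.call(rbind, pieces)
  out <- out[order(out$tumour_id, out$sga, out$deg_a, out$deg_b), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the weighted DEG co-regulation network
#'
#' Edge weight between two DEGs is the number of distinct tumours in which
#' the pair was co-regulated by a common SGA. The instance list is retained
#' as per-edge provenance so module co-regulation can later be attributed to
#' individual SGAs.
#'
#' @param instances Output of [enumerate_coregulation()].
#' @param kept_nodes DEG symbols defining the node set (isolated nodes are
#'   kept with zero-weight rows/columns).
#' @param min_edge_weight Optional minimum tumour count for an edge; weights
#'   below it are zeroed (default 1, i.e. any co-regulation adds an edge).
#' @return A `deg_network` object: list with `nodes`, symmetric integer
#'   weight matrix `W` (zero diagonal) and the `provenance` data frame.
#' @export
build_deg_network <- function(instances, kept_nodes, min_edge_weight = 1L) {
  nodes <- sort(unique(as.character(kept_nodes)))
  n <- length(nodes)
  W <- matrix(0L, n, n, dimnames = list(nodes, nodes))
  if (nrow(instances) > 0L) {
    pair_key <- paste(instances$deg_a, instances$deg_b, sep = "\r")
    w <- tapply(instances$tumour_id, pair_key, function(t) length(unique(t)))
    parts <- strsplit(names(w), "\r", fixed = TRUE)
    ia <- match(vapply(parts, `[`, "", 1L), nodes)
    ib <- match(vapply(parts, `[`, "", 2L), nodes)
    if (anyNA(ia) || anyNA(ib)) {
      stop("instances reference DEGs outside the node set", call. = FALSE)
    }
    w <- as.integer(w)
    w[w < min_edge_weight] <- 0L
    W[cbind(ia, ib)] <- w
    W[cbind(ib, ia)] <- w
  }
  structure(list(nodes = nodes, W = W, provenance = instances),
            class = "deg_network")
}

#' @export
print.deg_network <- function(x, ...) {
  n_edges <- sum(x$W[upper.tri(x$W)] > 0)
  cat(sprintf("DEG co-regulation network: %d nodes, %d edges, %d co-regulation instances\n",
              length(x$nodes), n_edges, nrow(x$provenance)))
  invisible(x)
}

#' Write a DEG network to tab-separated files
#'
#' Writes `edges.tsv` (`deg_a`, `deg_b`, `weight`), `nodes.tsv` and
#' `provenance.tsv` (`deg_a`, `deg_b`, `tumour_id`, `sga`) into `dir`.
#'
#' @param network A `deg_network` object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_deg_network <- function(network, dir) {
  stopifnot(inherits(network, "deg_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ut <- upper.tri(network$W)
  idx <- which(ut & network$W > 0, arr.ind = TRUE)
  edges <- data.frame(deg_a = network$nodes[idx[, 1L]],
                      deg_b = network$nodes[idx[, 2L]],
                      weight = network$W[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$deg_a, edges$deg_b), , drop = FALSE]
  utils::write.table(edges, file.path(dir, "edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(deg = network$nodes), file.path(dir, "nodes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- network$provenance[, c("deg_a", "deg_b", "tumour_id", "sga")]
  utils::write.table(prov, file.path(dir, "provenance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a DEG network written by [write_deg_network()]
#'
#' @param dir Directory containing `edges.tsv`, `nodes.tsv`,
#'   `provenance.tsv`.
#' @return A `deg_network` object.
#' @export
read_deg_network <- function(dir) {
  nodes <- utils::read.table(file.path(dir, "nodes.tsv"), header = TRUE,
                             sep = "\t", stringsAsFactors = FALSE)$deg
  prov <- utils::read.table(file.path(dir, "provenance.tsv"), header = TRUE,
                            sep = "\t", stringsAsFactors = FALSE,
                            colClasses = "character")
  prov <- prov[, c("tumour_id", "sga", "deg_a", "deg_b")]
  prov <- prov[order(prov$tumour_id, prov$sga, prov$deg_a, prov$deg_b), ,
               drop = FALSE]
  rownames(prov) <- NULL
  build_deg_network(prov, nodes)
}
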