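make_provenance <- function(counts_by_sga, module_genes) {
  # counts_by_sga: named integer vector of instance counts inside one
  # module whose genes are module_genes (pairs drawn cyclically).
  rows <- list()
  pairs <- t(combn(module_genes, 2))
  i <- 0L
  for (s in names(counts_by_sga)) {
    for (r in seq_len(counts_by_sga[[s]])) {
      i <- i + 1L
      p <- pairs[(i - 1L) %% nrow(pairs) + 1L, ]
      rows[[i]] <- data.frame(tumour_id = paste0("t", i), sga = s,
                              deg_a = p[1], deg_b = p[2])
    }
  }
  do.call(rbind, rows)
}

test_that("dominance uses a strict threshold and proportions sum to one", {
  genes <- paste0("g", 1:6)
  partition <- setNames(rep(1L, 6), genes)
  prov <- make_provenance(c(big = 89, edge = 10, tiny = 1), genes)
  rep1 <- dominant_sgas(partition, prov, threshold = 0.10)
  expect_equal(sum(rep1$proportion), 1, tolerance = 1e-9)
  expect_true(rep1$dominant[rep1$sga == "big"])
  expect_false(rep1$dominant[rep1$sga == "edge"])   # exactly 10%: not dominant
  expect_false(rep1$dominant[rep1$sga == "tiny"])
  # 11 of 100 is dominant
  prov2 <- make_provenance(c(big = 89, over = 11), genes)
  rep2 <- dominant_sgas(partition, prov2)
  expect_true(rep2$dominant[rep2$sga == "over"])
})

test_that("only instances wholly inside a module count towards it", {
  partition <- setNames(c(1L, 1L, 2L, 2L), c("a", "b", "c", "d"))
  prov <- data.frame(tumour_id = c("t1", "t2", "t3"),
                     sga = c("s1", "s1", "s2"),
                     deg_a = c("a", "a", "c"),
                     deg_b = c("b", "c", "d"))
  rep_ <- dominant_sgas(partition, prov)
  # the (a, c) instance straddles modules and is attributed to neither
  expect_equal(rep_$n_instances[rep_$module == 1], 1L)
  expect_equal(rep_$n_instances[rep_$module == 2], 1L)
  expect_equal(sum(rep_$n_instances), 2L)
})

test_that("hypergeometric overlap matches exhaustive enumeration", {
  # canonical case: universe 10, set 5, module 4, overlap 4
  h <- hypergeom_overlap(paste0("g", 1:4), paste0("g", 1:5), paste0("g", 1:10))
  expect_equal(h$overlap, 4L)
  expect_equal(h$p_value, 5 / 210, tolerance = 1e-12)
  # sweep of small configurations against the combinatorial oracle
  set.seed(12)
  for (rep in 1:20) {
    n_u <- sample(4:12, 1)
    universe <- paste0("u", seq_len(n_u))
    gene_set <- sample(universe, sample.int(n_u, 1))
    module <- sample(universe, sample.int(n_u, 1))
    h <- hypergeom_overlap(module, gene_set, universe)
    expect_equal(h$p_value,
                 oracle_hypergeom(h$overlap, length(gene_set), n_u,
                                  length(module)),
                 tolerance = 1e-12)
  }
  # degenerate tails
  expect_equal(hypergeom_overlap(character(), "g1", paste0("g", 1:5))$p_value, 1)
  expect_equal(hypergeom_overlap(paste0("g", 1:5), paste0("g", 1:5),
                                 paste0("g", 1:5))$p_value, 1)
  expect_error(hypergeom_overlap("g1", "g1", character()), "non-empty")
})

test_that("gene-set ranking puts a planted signature first, order-independent", {
  set.seed(14)
  universe <- paste0("g", 1:100)
  signature <- universe[1:20]
  module <- c(signature[1:18], "g90", "g91")
  decoys <- lapply(1:10, function(i) sample(universe, 20))
  names(decoys) <- paste0("decoy", 1:10)
  coll <- c(list(planted = signature), decoys)
  ranked <- rank_gene_sets(module, coll, universe, top_n = 5)
  expect_equal(ranked$set[1], "planted")
  expect_true(all(diff(ranked$p_value) >= 0))
  shuffled <- coll[sample(length(coll))]
  ranked2 <- rank_gene_sets(module, shuffled, universe, top_n = 5)
  expect_equal(ranked, ranked2)
  # single-set collection returns that set
  one <- rank_gene_sets(module, coll["planted"], universe)
  expect_equal(nrow(one), 1L)
})

test_that("module report summarises sizes, effective DEGs and dominant SGAs", {
  partition <- setNames(c(1L, 1L, 2L), c("a", "b", "c"))
  prov <- data.frame(tumour_id = "t1", sga = "s1", deg_a = "a", deg_b = "b")
  rep_ <- module_report(partition, dominant_sgas(partition, prov),
                        expression_genes = c("a", "c"))
  expect_equal(rep_$n_deg, c(2L, 1L))
  expect_equal(rep_$n_effective_deg, c(1L, 1L))
  expect_match(rep_$dominant_sgas[1], "s1 \\(100.0%\\)")
})
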