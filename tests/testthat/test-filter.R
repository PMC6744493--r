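test_that("posterior floor is strict and order-preserving", {
  a <- data.frame(tumour_id = c("t1", "t1", "t2"),
                  sga = "s", deg = c("d1", "d2", "d1"),
                  posterior = c(0.9, 0.5, 0.51))
  out <- filter_valid_assignments(a, 0.5)
  expect_equal(out$posterior, c(0.9, 0.51))
  expect_equal(out$tumour_id, c("t1", "t2"))

  set.seed(4)
  inst <- random_instance(10, 5, 12)
  out <- filter_valid_assignments(inst$assignments, 0.3)
  expect_equal(out, inst$assignments[inst$assignments$posterior > 0.3, ],
               ignore_attr = TRUE)
})

test_that("duplicate assignment rows collapse to the maximum posterior", {
  a <- data.frame(tumour_id = "t1", sga = "s", deg = "d",
                  posterior = c(0.2, 0.8, 0.5))
  expect_warning(out <- filter_valid_assignments(a, 0), "duplicate")
  expect_equal(nrow(out), 1L)
  expect_equal(out$posterior, 0.8)
})

test_that("driver calls require the DEG count threshold within one tumour", {
  five <- data.frame(tumour_id = "t1", sga = "s",
                     deg = paste0("d", 1:5), posterior = 0.9)
  four <- data.frame(tumour_id = "t2", sga = "s",
                     deg = paste0("d", 1:4), posterior = 0.9)
  calls <- call_tumour_drivers(rbind(five, four))
  expect_equal(calls$tumour_id, "t1")
  expect_equal(calls$n_degs, 5L)
})

test_that("driver significance is a conjunction of count and fraction", {
  th <- filter_thresholds()
  obs <- function(s, n) data.frame(tumour_id = paste0("o", seq_len(n)), sga = s)
  calls <- function(s, n) data.frame(tumour_id = paste0("o", seq_len(n)), sga = s)
  # 30 of 120 observed = exactly 25%: significant
  out <- call_significant_drivers(calls("s1", 30), obs("s1", 120), th)
  expect_equal(out$sga, "s1")
  # 29 driver tumours: count fails
  out <- call_significant_drivers(calls("s2", 29), obs("s2", 40), th)
  expect_equal(nrow(out), 0L)
  # 30 of 121 observed = 24.8%: fraction fails
  out <- call_significant_drivers(calls("s3", 30), obs("s3", 121), th)
  expect_equal(nrow(out), 0L)
})

test_that("relationship significance is a disjunction of count and fraction", {
  th <- filter_thresholds()
  mk <- function(s, d, n) data.frame(tumour_id = paste0("t", seq_len(n)),
                                     sga = s, deg = d, posterior = 0.9)
  drv <- function(s, n) data.frame(tumour_id = paste0("t", seq_len(n)), sga = s)
  # 50 tumours but only 17% of driver tumours: count branch alone suffices
  out <- call_significant_relationships(mk("s", "d", 50), "s", drv("s", 300), th)
  expect_equal(out$deg, "d")
  # 10 of 50 driver tumours = 20%: fraction branch
  out <- call_significant_relationships(mk("s", "d", 10), "s", drv("s", 50), th)
  expect_equal(out$deg, "d")
  # 9 of 50 = 18%: neither branch
  out <- call_significant_relationships(mk("s", "d", 9), "s", drv("s", 50), th)
  expect_equal(nrow(out), 0L)
})

test_that("projection to significant pairs is a set-membership filter", {
  set.seed(11)
  inst <- random_instance()
  a <- inst$assignments
  expect_equal(nrow(project_to_significant(
    a, data.frame(sga = character(), deg = character()))), 0L)
  all_pairs <- unique(a[, c("sga", "deg")])
  expect_equal(project_to_significant(a, all_pairs), a, ignore_attr = TRUE)
  some <- all_pairs[seq_len(floor(nrow(all_pairs) / 2)), , drop = FALSE]
  got <- project_to_significant(a, some)
  want <- a[paste(a$sga, a$deg) %in% paste(some$sga, some$deg), ]
  expect_equal(got, want, ignore_attr = TRUE)
})

test_that("all standards match the brute-force oracle on random instances", {
  set.seed(21)
  th <- small_thresholds()
  for (rep in 1:10) {
    inst <- random_instance(n_tumours = sample(5:25, 1),
                            n_sgas = sample(3:8, 1),
                            n_degs = sample(6:20, 1))
    got <- apply_filter_standards(inst$assignments, inst$observations, th)
    want <- oracle_filter(inst$assignments, inst$observations, th)
    expect_equal(sort(got$significant_drivers$sga), want$significant_drivers)
    expect_setequal(paste(got$driver_calls$tumour_id, got$driver_calls$sga),
                    paste(want$driver_calls[, 1], want$driver_calls[, 2]))
    expect_setequal(paste(got$significant_relationships$sga,
                          got$significant_relationships$deg),
                    paste(want$significant_relationships[, 1],
                          want$significant_relationships[, 2]))
    expect_equal(got$significant_assignments, want$significant_assignments,
                 ignore_attr = TRUE)
  }
})

test_that("raising thresholds never adds drivers, nor relationships when the
           driver-call denominator is unchanged", {
  # Drivers are monotone in every threshold. Relationships are monotone in
  # the driver- and relationship-level thresholds; the posterior floor and
  # the per-tumour DEG count also shrink the driver-call denominator of the
  # relationship fraction, so monotonicity is only claimed for the rest.
  set.seed(31)
  base <- small_thresholds()
  driver_fields <- c("posterior_floor", "min_degs_per_driver",
                     "min_driver_tumours", "min_driver_fraction",
                     "min_relationship_tumours", "min_relationship_fraction")
  rel_fields <- c("min_driver_tumours", "min_driver_fraction",
                  "min_relationship_tumours", "min_relationship_fraction")
  for (rep in 1:5) {
    inst <- random_instance(15, 6, 12)
    ref <- apply_filter_standards(inst$assignments, inst$observations, base)
    for (field in driver_fields) {
      harder <- base
      harder[[field]] <- if (field %in% c("posterior_floor", "min_driver_fraction",
                                          "min_relationship_fraction")) {
        min(1, base[[field]] + 0.2)
      } else {
        base[[field]] + 2L
      }
      out <- apply_filter_standards(inst$assignments, inst$observations, harder)
      expect_true(all(out$significant_drivers$sga %in% ref$significant_drivers$sga))
      if (field %in% rel_fields) {
        expect_true(all(paste(out$significant_relationships$sga,
                              out$significant_relationships$deg) %in%
                          paste(ref$significant_relationships$sga,
                                ref$significant_relationships$deg)))
      }
    }
  }
})

test_that("filtering is invariant to assignment row order", {
  set.seed(41)
  inst <- random_instance()
  th <- small_thresholds()
  ref <- apply_filter_standards(inst$assignments, inst$observations, th)
  perm <- inst$assignments[sample(nrow(inst$assignments)), ]
  out <- apply_filter_standards(perm, inst$observations, th)
  expect_equal(out$significant_drivers, ref$significant_drivers)
  expect_equal(out$significant_relationships, ref$significant_relationships)
  expect_setequal(paste(out$significant_assignments$tumour_id,
                        out$significant_assignments$deg),
                  paste(ref$significant_assignments$tumour_id,
                        ref$significant_assignments$deg))
})
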