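test_that("overlap statistics report exact intersections and coverages", {
  ov <- overlap_stats(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(ov$n_intersection, 2L)
  expect_equal(ov$coverage_of_reference, 100 * 2 / 3)
  expect_equal(ov$coverage_of_query, 100 * 2 / 3)
  expect_equal(overlap_stats(c("a"), c("b"))$coverage_of_reference, 0)
  expect_error(overlap_stats(c("a"), character(0)), "empty")
  # refset objects carry their names through
  ov2 <- overlap_stats(reference_set("core", c("a", "b")),
                       reference_set("ip", c("b"), role = "ip_dataset"))
  expect_equal(ov2$query, "core")
  expect_equal(ov2$n_intersection, 1L)
})

test_that("the intersection FDR estimator matches the closed form", {
  mk_ids <- function(n, prefix) sprintf("%s%04d", prefix, seq_len(n))
  # |A| = 100, |A n B| = 80, |R| = 50, |B n R| = 40 -> FDR 0
  A <- mk_ids(100, "a")
  B <- c(A[1:80], mk_ids(40, "b"))
  R <- c(A[81:90], B[81:120])  # 50 ids, exactly 40 of them in B
  est <- estimate_interaction_fdr(A, B, R)
  expect_equal(est$n_AB, 80L)
  expect_equal(est$n_BR, 40L)
  expect_equal(est$fdr, 0)
  # |A n B| = 60 with the same margins -> FDR 0.25
  B2 <- c(A[1:60], mk_ids(60, "b"))
  R2 <- c(A[61:70], B2[61:100])
  est2 <- estimate_interaction_fdr(A, B2, R2)
  expect_equal(est2$fdr, 1 - 60 * 50 / (100 * 40))
  expect_equal(est2$fdr, 0.25)
  # perfect replication limit: A = B and R inside A gives FDR 0
  est3 <- estimate_interaction_fdr(A, A, A[1:20])
  expect_equal(est3$fdr, 0)
  # no recapture: not evaluable
  est4 <- estimate_interaction_fdr(A, B, mk_ids(5, "z"))
  expect_true(is.na(est4$fdr))
  expect_match(est4$note, "not evaluable")
})

test_that("the estimator recovers a planted FDR in simulation", {
  bench <- simulate_fdr_benchmark(0.15, n_sims = 10L, seed = 99L)
  expect_equal(nrow(bench), 10L)
  expect_lt(abs(mean(bench$estimate) - 0.15), 0.03)
})

test_that("hypergeometric upper tails equal subset enumeration", {
  expect_equal(hypergeometric_test(4, 4, 4, 10), 1 / 210)
  expect_equal(hypergeometric_test(0, 0, 3, 10), 1)
  expect_equal(hypergeometric_test(0, 3, 0, 10), 1)
  expect_error(hypergeometric_test(5, 4, 4, 10), "inconsistent")
  expect_error(hypergeometric_test(1, 11, 4, 10), "inconsistent")
  # exhaustive check on a lattice of small configurations
  for (N in c(5L, 8L)) {
    for (n in 0:N) {
      for (K in 0:N) {
        for (k in 0:min(n, K)) {
          expect_equal(hypergeometric_test(k, n, K, N),
                       brute_force_hyper(k, n, K, N),
                       tolerance = 1e-12,
                       label = sprintf("N=%d n=%d K=%d k=%d", N, n, K, k))
        }
      }
    }
  }
})

test_that("Benjamini-Hochberg adjustment matches an independent step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(7)
  for (i in 1:20) {
    p <- stats::runif(sample(1:30, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, step_up_bh(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    # order-equivariant
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), adj[perm])
  }
})

test_that("annotation enrichment tests each term against the background", {
  background <- sprintf("P%02d", 1:10)
  query <- background[1:4]
  ann <- data.frame(
    term_id = c(rep("T1", 4), rep("T2", 3), "T1"),
    term_name = c(rep("whole query", 4), rep("other", 3), "whole query"),
    uniprot_id = c(background[1:4], background[8:10], background[1])
  )
  res <- annotation_enrichment(query, ann, background)
  t1 <- res[res$term_id == "T1", ]
  expect_equal(t1$p_value, 1 / 210)  # all four query proteins in the term
  expect_true(t1$significant)
  t2 <- res[res$term_id == "T2", ]
  expect_equal(t2$count, 0L)
  expect_equal(t2$p_value, 1)
  # duplicated membership rows are removed before testing
  expect_equal(t1$term_size, 4L)
  # empty query: every p-value is 1
  res0 <- annotation_enrichment(character(0), ann, background)
  expect_true(all(res0$p_value == 1))
  expect_false(any(res0$significant))
  expect_error(annotation_enrichment("absent", ann, background),
               "outside the background")
})

test_that("complex ranking filters, ranks and flags the upper quartile", {
  members <- list(
    "1" = c("A1", "A2", "A3", "A4"),  # fully covered by the screen
    "2" = c("B1", "B2", "B3", "B4"),  # no screen overlap
    "3" = c("A1", "B1", "C1"),        # 2 combined overlaps only
    "4" = c("A1", "A2", "C2", "C3")   # partially covered
  )
  catalog <- prisma:::new_complex_catalog(names(members),
                                          paste("cx", names(members)),
                                          members)
  prisma_set <- c("A1", "A2", "A3", "A4")
  ip_set <- c("B1", "B2", "C2", "C3")
  rk <- rank_complexes(prisma_set, ip_set, catalog)
  expect_false(rk$retained[rk$complex_id == "2"])  # no screen overlap
  expect_false(rk$retained[rk$complex_id == "3"])  # below min_combined = 3
  # retained ranks form a permutation of 1..n
  expect_setequal(rk$rank[rk$retained], seq_len(sum(rk$retained)))
  expect_true(all(is.na(rk$rank[!rk$retained])))
  # full coverage outranks partial coverage at equal size
  expect_lt(rk$rank[rk$complex_id == "1"], rk$rank[rk$complex_id == "4"])

  # growing a complex's screen overlap never worsens its coverage rank
  members2 <- members
  members2[["4"]] <- c("A1", "A2", "A3", "C3")
  catalog2 <- prisma:::new_complex_catalog(names(members2),
                                           paste("cx", names(members2)),
                                           members2)
  rk2 <- rank_complexes(prisma_set, ip_set, catalog2)
  expect_lte(rk2$rank[rk2$complex_id == "4"],
             rk$rank[rk$complex_id == "4"])
  expect_error(rank_complexes(prisma_set, ip_set,
                              prisma:::new_complex_catalog(character(0),
                                                           character(0),
                                                           list())),
               "empty")
})

test_that("the upper quartile boundary is floor(n/4)", {
  set.seed(11)
  pool <- sprintf("P%03d", 1:300)
  pr <- pool[1:150]
  ip <- pool[120:220]
  n_pass <- 417L
  members <- lapply(seq_len(n_pass), function(i) {
    sample(pr, sample(3:6, 1))  # >= 3 screen members: passes both filters
  })
  ## plus some complexes that fail the combined-overlap filter
  members <- c(members, lapply(1:10, function(i) sample(pool[250:300], 4)))
  ids <- sprintf("c%03d", seq_along(members))
  catalog <- prisma:::new_complex_catalog(ids, ids, members)
  rk <- rank_complexes(pr, ip, catalog)
  expect_equal(sum(rk$retained), n_pass)
  expect_equal(sum(rk$upper_quartile), 104L)  # floor(417 / 4)
  expect_equal(max(rk$rank[rk$upper_quartile]), 104L)
})
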