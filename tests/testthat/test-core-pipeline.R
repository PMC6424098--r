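mk <- function(...) {
  rows <- list(...)
  mat <- do.call(rbind, lapply(rows, function(r) r$v))
  colnames(mat) <- sprintf("t%03d", seq_len(ncol(mat)))
  make_table(rows[[1]]$rep %||% "r", vapply(rows, `[[`, "", "id"), mat)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("replicate integration averages detected values and labels confidence", {
  r1 <- mk(list(id = "P1", v = c(10, 10, 0)))
  r2 <- mk(list(id = "P1", v = c(20, 0, 0)))
  prof <- integrate_replicates(r1, r2)
  expect_equal(unname(prof$values["P1", ]), c(15, 10, 0))
  expect_equal(unname(prof$confidence["P1", ]),
               c("double", "single", "absent"))
  # proteins appearing in either replicate appear in the output
  r3 <- mk(list(id = "P2", v = c(0, 0, 5)))
  prof2 <- integrate_replicates(r1, r3)
  expect_setequal(rownames(prof2$values), c("P1", "P2"))
  expect_equal(unname(prof2$values["P2", ]), c(0, 0, 5))
  # mismatched spot sets are rejected
  r4 <- make_table("r4", "P1", matrix(1, 1, 2,
                                      dimnames = list(NULL, c("x1", "x2"))))
  expect_error(integrate_replicates(r1, r4), "different spot sets")
})

test_that("normalization scales each profile to a unit maximum", {
  m <- rbind(P1 = c(0, 5, 10), P2 = c(0, 0, 0), P3 = c(0, 0, 4))
  colnames(m) <- sprintf("t%03d", 1:3)
  prof <- normalize_profiles(profiles_from_matrix(m))
  expect_equal(unname(prof$values["P1", ]), c(0, 0.5, 1))
  expect_equal(unname(prof$values["P2", ]), c(0, 0, 0))
  expect_equal(unname(prof$values["P3", ]), c(0, 0, 1))
  expect_identical(attr(prof, "undetected"), "P2")
  # idempotent
  expect_equal(normalize_profiles(prof)$values, prof$values)
  # negative input rejected
  bad <- profiles_from_matrix(rbind(P1 = c(-1, 0, 0)))
  expect_error(normalize_profiles(bad), "negative")
})

test_that("outlier filtering keeps the nearest-rank upper tail", {
  base <- function(v) {
    m <- matrix(v, nrow = 1, dimnames = list("P", sprintf("t%03d",
                                                          seq_along(v))))
    normalize_profiles(profiles_from_matrix(m))
  }
  # ten detected values: ceiling(0.9 * 10) = 9, so the top two survive
  f <- outlier_filter(base(1:10))
  expect_equal(sum(f$values > 0), 2L)
  expect_equal(unname(f$values[1, 9:10]), c(0.9, 1))
  # constant detected values: threshold equals the common value, all kept
  f2 <- outlier_filter(base(c(rep(4, 6), 0, 0)))
  expect_equal(sum(f2$values > 0), 6L)
  # two detected values: ceiling(0.9 * 2) = 2, only the larger survives
  f3 <- outlier_filter(base(c(3, 7, 0)))
  expect_equal(unname(f3$values[1, ]), c(0, 1, 0))
  # all-zero profile passes through
  f4 <- outlier_filter(base(rep(0, 5)))
  expect_true(all(f4$values == 0))
  # filtering an already-filtered profile is a no-op
  expect_equal(outlier_filter(f)$values, f$values)
})

test_that("filters shrink monotonically and respect the retention bound", {
  set.seed(101)
  for (i in 1:50) {
    k_spots <- sample(5:40, 1)
    v <- ifelse(stats::runif(k_spots) < 0.6,
                stats::rlnorm(k_spots, 0, 2), 0)
    m <- matrix(v, nrow = 1,
                dimnames = list("P", sprintf("t%03d", seq_len(k_spots))))
    norm <- normalize_profiles(profiles_from_matrix(m))
    filt <- outlier_filter(norm)
    # never creates signal; per-spot values never increase
    expect_true(all(filt$values <= norm$values + 1e-12))
    expect_true(all(filt$values[norm$values == 0] == 0))
    det <- norm$values[norm$values > 0]
    if (length(det)) {
      thr <- sort(det)[ceiling(0.9 * length(det))]
      ties <- sum(det == thr)
      expect_lte(sum(filt$values > 0), ceiling(0.1 * length(det)) + ties)
    }
  }
})

test_that("the consecutive criterion requires adjacent tiles and collapses variants", {
  design <- make_design(50L)
  v <- stats::setNames(rep(0, 50), design$spot_id)
  v[c("t011", "t012")] <- 1  # tile_index 10 and 11
  res <- consecutive_filter(v, design)
  expect_true(res$passes)
  expect_equal(res$runs[res$runs$length >= 2, ]$start_tile, 10L)
  v2 <- stats::setNames(rep(0, 50), design$spot_id)
  v2[c("t011", "t013")] <- 1  # non-adjacent tiles fail
  expect_false(consecutive_filter(v2, design)$passes)

  # a variant's surviving signal marks its parent tile, not a new one
  vd <- design[41, ]
  vd$spot_id <- "t041+phospho_S5"
  vd$ptms <- "phospho_S:5"
  vd$parent_spot_id <- "t041"
  design_v <- rbind(design, vd)
  v3 <- stats::setNames(rep(0, 51), design_v$spot_id)
  v3[c("t041", "t041+phospho_S5")] <- 1
  res3 <- consecutive_filter(v3, design_v)
  expect_false(res3$passes)  # one marked tile only
  expect_equal(nrow(res3$runs), 1L)
  v3["t042"] <- 1
  expect_true(consecutive_filter(v3, design_v)$passes)

  expect_error(consecutive_filter(v[-1], design), "match the design")
})

test_that("interactor sets nest and follow set algebra", {
  spots <- sprintf("t%03d", 1:6)
  m1 <- rbind(A = c(5, 6, 0, 0, 0, 0), B = c(1, 2, 3, 4, 0, 0))
  m2 <- rbind(B = c(2, 3, 4, 5, 0, 0), C = c(0, 0, 0, 0, 7, 0))
  colnames(m1) <- colnames(m2) <- spots
  r1 <- make_table("r1", rownames(m1), m1)
  r2 <- make_table("r2", rownames(m2), m2)
  sets <- derive_interactor_sets(r1, r2, make_design(6L))
  expect_equal(sets$set1, c("A", "B"))
  expect_equal(sets$set2, c("B", "C"))
  expect_equal(sets$both, "B")
  expect_true(all(sets$core %in% sets$both))
  expect_equal(length(sets$union),
               length(sets$set1) + length(sets$set2) - length(sets$both))

  # on random screens: core subset both subset set1/set2, every run >= min_run
  spec <- truth_spec(n_true_binders = 30L, n_background_binders = 60L,
                     seed = 5L)
  sc <- generate_screen(spec)
  s <- derive_interactor_sets(sc$rep1, sc$rep2, sc$design)
  expect_true(all(s$core %in% s$both))
  expect_true(all(s$both %in% s$set1) && all(s$both %in% s$set2))
  expect_true(all(s$runs$length >= 2))
  expect_setequal(unique(s$runs$uniprot_id), s$core)
})

test_that("the physicochemical bias check reports span and correlations", {
  # abundance span: accumulated values 1 and 1e6 are six decades apart
  seqs <- c(strrep("I", 14), strrep("G", 14), strrep("L", 14))
  design <- make_design(3L, sequences = seqs)
  m <- rbind(P1 = c(1, 1e6, 0.5))
  colnames(m) <- design$spot_id
  prof <- profiles_from_matrix(m, normalized = TRUE)
  bc <- bias_check(prof, design)
  expect_equal(bc$abundance_span, log10(1e6 / 0.5))

  # constant covariate: correlation is not applicable, not zero
  design_const <- make_design(3L)
  bc2 <- bias_check(prof, design_const)
  expect_true(is.na(bc2$gravy_cor$rho))
  expect_match(bc2$gravy_cor$note, "not applicable")

  # a planted monotone gravy -> intensity relationship is detected
  letters_by_gravy <- c("R", "G", "A", "C", "I")  # increasing hydropathy
  design_mono <- make_design(5L,
                             sequences = strrep(letters_by_gravy, 14))
  mm <- rbind(P1 = c(0.1, 0.3, 0.5, 0.8, 1.0))
  colnames(mm) <- design_mono$spot_id
  bc3 <- bias_check(profiles_from_matrix(mm, normalized = TRUE), design_mono)
  expect_equal(bc3$gravy_cor$rho, 1)
  expect_error(bias_check(profiles_from_matrix(
    matrix(1, 1, 2, dimnames = list("P", c("a", "b"))), normalized = TRUE),
    design), "3 spots")
})
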