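test_that("tiling covers the protein with the expected starts and overlaps", {
  # degenerate: protein length equals peptide length
  p14 <- protein_sequence("p14", strrep("ACDEFGHIKLMNPQ", 1))
  d <- tile_sequence(p14)
  expect_equal(nrow(d), 1L)
  expect_equal(c(d$start, d$end), c(1L, 14L))

  # one offset step reaches the terminus exactly
  p18 <- protein_sequence("p18", strrep("AC", 9))
  d <- tile_sequence(p18)
  expect_equal(d$start, c(1L, 5L))
  expect_equal(d$end, c(14L, 18L))

  # 297-residue protein: 71 regular tiles plus a C-anchored tail
  p297 <- default_design()$protein
  d <- tile_sequence(p297)
  expect_equal(nrow(d), 72L)
  expect_equal(d$start, c(seq(1L, 281L, by = 4L), 284L))
  expect_equal(d$end[nrow(d)], 297L)

  # coverage: the union of tile intervals is [1, 297]
  covered <- rep(FALSE, 297)
  for (i in seq_len(nrow(d))) covered[d$start[i]:d$end[i]] <- TRUE
  expect_true(all(covered))

  # regular neighbors share exactly length - offset residues
  reg <- d[-nrow(d), ]
  overlaps <- reg$end[-nrow(reg)] - reg$start[-1] + 1L
  expect_true(all(overlaps == 10L))

  # tile sequences equal the protein subsequence at [start, end]
  expect_equal(d$sequence,
               substring(p297$residues, d$start, d$end))
})

test_that("tiling rejects proteins shorter than the peptide and drop policy skips the tail", {
  p10 <- protein_sequence("p10", strrep("A", 10))
  expect_error(tile_sequence(p10), "shorter than the peptide length")

  p20 <- protein_sequence("p20", strrep("A", 20))
  d <- tile_sequence(p20, tail_policy = "drop")
  expect_equal(max(d$end), 18L)  # residues 19-20 uncovered under drop
})

test_that("PTM expansion creates one variant per covering tile with stable ids", {
  dd <- default_design()
  tiles <- tile_sequence(dd$protein)
  ptm <- data.frame(position = 60L, residue = "K", mod_type = "acetyl_K",
                    stringsAsFactors = FALSE)
  out <- expand_ptm_variants(tiles, ptm, dd$protein)
  variants <- out[out$ptms != "", ]
  covering <- tiles[tiles$start <= 60 & tiles$end >= 60, ]
  expect_equal(nrow(variants), nrow(covering))
  expect_setequal(variants$parent_spot_id, covering$spot_id)
  expect_true(all(variants$spot_id ==
                    paste0(variants$parent_spot_id, "+acetyl_K60")))
  # variants inherit coordinates and tile_index from their parents
  parent_rows <- out[match(variants$parent_spot_id, out$spot_id), ]
  expect_equal(variants$start, parent_rows$start)
  expect_equal(variants$end, parent_rows$end)
  expect_equal(variants$tile_index, parent_rows$tile_index)
})

test_that("PTM expansion validates residues and handles uncovered positions", {
  p20 <- protein_sequence("p20", paste0(strrep("A", 18), "KA"))
  tiles <- tile_sequence(p20, tail_policy = "drop")  # covers [1, 18] only
  # residue mismatch is rejected
  bad <- data.frame(position = 2L, residue = "K", mod_type = "acetyl_K")
  expect_error(expand_ptm_variants(tiles, bad, p20), "expects residue")
  # chemically incompatible mod_type is rejected
  bad2 <- data.frame(position = 19L, residue = "K", mod_type = "phospho_S")
  expect_error(expand_ptm_variants(tiles, bad2, p20), "not compatible")
  # a PTM covered by no tile yields zero variants
  ptm <- data.frame(position = 19L, residue = "K", mod_type = "acetyl_K")
  out <- expand_ptm_variants(tiles, ptm, p20)
  expect_equal(sum(out$ptms != ""), 0L)
})

test_that("combinations policy emits every non-empty PTM subset per tile", {
  p14 <- protein_sequence("p", "ASKAAAAAAAAAAA")
  tiles <- tile_sequence(p14)
  ptms <- data.frame(position = c(2L, 3L), residue = c("S", "K"),
                     mod_type = c("phospho_S", "acetyl_K"))
  single <- expand_ptm_variants(tiles, ptms, p14, policy = "single_ptm")
  expect_equal(sum(single$ptms != ""), 2L)
  combo <- expand_ptm_variants(tiles, ptms, p14, policy = "combinations")
  expect_equal(sum(combo$ptms != ""), 3L)  # 2 singles + 1 pair
})

test_that("region annotation returns every intersecting region", {
  regions <- data.frame(name = c("CR1", "CR2"), start = c(1L, 20L),
                        end = c(15L, 40L))
  tile_in <- list(start = 2L, end = 10L)
  tile_span <- list(start = 10L, end = 25L)
  tile_out <- list(start = 16L, end = 19L)
  expect_equal(annotate_regions(tile_in, regions), "CR1")
  expect_setequal(annotate_regions(tile_span, regions), c("CR1", "CR2"))
  expect_length(annotate_regions(tile_out, regions), 0L)
  expect_error(annotate_regions(tile_in,
                                data.frame(name = c("A", "A"),
                                           start = c(1L, 2L),
                                           end = c(3L, 4L))),
               "unique")
})

test_that("GRAVY equals the per-residue table average", {
  expect_equal(peptide_gravy("AAAA"), 1.8)
  expect_equal(peptide_gravy(strrep("G", 14)), -0.4)
  expect_error(peptide_gravy("AXB"), "non-standard")
  set.seed(42)
  for (i in 1:25) {
    pep <- random_peptide(sample(5:20, 1))
    expect_equal(peptide_gravy(pep), oracle_gravy(pep))
    shuffled <- paste(sample(strsplit(pep, "")[[1]]), collapse = "")
    expect_equal(peptide_gravy(shuffled), peptide_gravy(pep))
  }
})

test_that("isoelectric point matches a grid-scan oracle and orders as expected", {
  set.seed(43)
  for (i in 1:20) {
    pep <- random_peptide(sample(5:20, 1))
    expect_equal(as.numeric(peptide_isoelectric_point(pep)),
                 oracle_pi(pep), tolerance = 0.01)
  }
  expect_lt(peptide_isoelectric_point("DDDD"),
            peptide_isoelectric_point("KKKK"))
  expect_lt(as.numeric(peptide_isoelectric_point("DDDD", "lehninger")),
            as.numeric(peptide_isoelectric_point("KKKK", "lehninger")))
  # appending a lysine never lowers the pI
  for (pep in c("ACDE", "GGGG", "KRKR", "STYW")) {
    expect_gte(peptide_isoelectric_point(paste0(pep, "K")),
               peptide_isoelectric_point(pep))
  }
  # composition-based: permutation leaves the pI unchanged exactly
  expect_equal(as.numeric(peptide_isoelectric_point("KDEH")),
               as.numeric(peptide_isoelectric_point("HEDK")))
  # the pKa set used is recorded
  expect_identical(attr(peptide_isoelectric_point("ACDK"), "pka_table"),
                   "emboss")
  expect_error(peptide_isoelectric_point("ACDK", "nonsense"), "unknown pKa")
})

test_that("the default design has 203 spots over 72 tiles", {
  dd <- default_design()
  expect_equal(nrow(dd$design), 203L)
  expect_equal(sum(dd$design$ptms == ""), 72L)
  expect_equal(sum(dd$design$ptms != ""), 131L)
  # every variant resolves to an unmodified parent with identical coordinates
  variants <- dd$design[dd$design$ptms != "", ]
  parents <- dd$design[match(variants$parent_spot_id, dd$design$spot_id), ]
  expect_true(all(parents$ptms == ""))
  expect_equal(variants$start, parents$start)
  expect_equal(variants$tile_index, parents$tile_index)
})
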