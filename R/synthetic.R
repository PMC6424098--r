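#' Specification of a synthetic screen with planted truth
#'
#' Describes a screen the pipeline can be benchmarked on: true binders carry
#' a contiguous plateau of peak intensity over `run_length_range` adjacent
#' tiles with triangular flank attenuation (0.5x one tile out, 0.2x two
#' tiles out), plus low-level promiscuous binding scattered over the matrix;
#' background binders occupy one isolated spot at low intensity. Peak
#' intensities are log-normal, spanning roughly six orders of magnitude
#' across proteins. Replicate tables apply multiplicative log-normal noise
#' (`noise_cv`) and per-value dropout. Selected (binder, peptide-group)
#' pairs get a planted PTM response: every variant of the group is set to
#' the parent value times a category multiplier (repressed 0.1, independent
#' 1, enhanced 8; regulated puts one variant at 8 and the rest at 1).
#'
#' @param n_true_binders Number of footprint-carrying binders (default 500).
#' @param n_background_binders Number of isolated single-spot binders
#'   (default 1500).
#' @param dropout Probability a detected value is missed in one replicate
#'   (default 0.1).
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal replicate noise (default 0.3).
#' @param run_length_range Inclusive range of footprint run lengths in
#'   tiles (default `c(2, 5)`).
#' @param peak_meanlog,peak_sdlog Log-normal parameters of the peak
#'   intensities (defaults `log(1e6)` and 2.3).
#' @param background_meanlog,background_sdlog Log-normal parameters of the
#'   isolated background binders (defaults `log(1e3)` and 1).
#' @param n_promiscuous_spots Number of extra low-level spots each true
#'   binder touches (default 30).
#' @param ptm_per_category Planted (binder, group) pairs per response
#'   category (default 20 each).
#' @param ptm_max_variants Only groups with at most this many variants are
#'   eligible for planting (default 3).
#' @param design Design list as returned by [default_design()].
#' @param seed Seed fixing all randomness.
#' @return A `prisma_truth_spec` list.
#' @export
truth_spec <- function(n_true_binders = 500L, n_background_binders = 1500L,
                       dropout = 0.1, noise_cv = 0.3,
                       run_length_range = c(2L, 5L),
                       peak_meanlog = log(1e6), peak_sdlog = 2.3,
                       background_meanlog = log(1e3), background_sdlog = 1,
                       n_promiscuous_spots = 30L,
                       ptm_per_category = 20L, ptm_max_variants = 3L,
                       design = default_design(), seed = 1L) {
  stopifnot(dropout >= 0, dropout <= 1, noise_cv >= 0,
            run_length_range[1] >= 1,
            run_length_range[2] >= run_length_range[1])
  n_tiles <- length(unique(design$design$tile_index))
  if (run_length_range[2] > n_tiles) {
    stop("footprint span exceeds the number of tiles (", n_tiles, ")")
  }
  structure(
    list(n_true_binders = as.integer(n_true_binders),
         n_background_binders = as.integer(n_background_binders),
         dropout = dropout, noise_cv = noise_cv,
         run_length_range = as.integer(run_length_range),
         peak_meanlog = peak_meanlog, peak_sdlog = peak_sdlog,
         background_meanlog = background_meanlog,
         background_sdlog = background_sdlog,
         n_promiscuous_spots = as.integer(n_promiscuous_spots),
         ptm_per_category = as.integer(ptm_per_category),
         ptm_max_variants = as.integer(ptm_max_variants),
         design = design, seed = as.integer(seed)),
    class = "prisma_truth_spec"
  )
}

PTM_CATEGORY_MULTIPLIERS <- list(
  repressed = 0.1, independent = 1, enhanced = 8
)

#' Generate a synthetic replicate pair with known ground truth
#'
#' @param spec A [truth_spec()].
#' @return A list with `rep1`, `rep2` (`prisma_intensities`), `truth`
#'   (binder table: `uniprot_id`, `type`, `run_start_tile`, `run_length`,
#'   `peak`), `ptm_truth` (planted categories per (binder, group)) and
#'   `design`.
#' @export
generate_screen <- function(spec = truth_spec()) {
  stopifnot(inherits(spec, "prisma_truth_spec"))
  set.seed(spec$seed)
  design <- spec$design$design
  spots <- design$spot_id
  unmod <- design[design$ptms == "", , drop = FALSE]
  unmod <- unmod[order(unmod$tile_index), , drop = FALSE]
  n_tiles <- nrow(unmod)
  groups <- ptm_groups(design)
  group_tile <- design$tile_index[match(names(groups), design$spot_id)]

  n_true <- spec$n_true_binders
  n_bg <- spec$n_background_binders
  ids <- c(sprintf("SYNT%05d", seq_len(n_true)),
           sprintf("SYNB%05d", seq_len(n_bg)))
  truth_values <- matrix(0, nrow = length(ids), ncol = length(spots),
                         dimnames = list(ids, spots))

  run_len <- sample(seq.int(spec$run_length_range[1],
                            spec$run_length_range[2]),
                    n_true, replace = TRUE)
  run_start <- vapply(run_len, function(L) {
    sample.int(n_tiles - L + 1L, 1L) - 1L
  }, integer(1))
  peak <- stats::rlnorm(n_true, spec$peak_meanlog, spec$peak_sdlog)

  for (i in seq_len(n_true)) {
    tiles_in_run <- run_start[i]:(run_start[i] + run_len[i] - 1L)
    flank1 <- setdiff(c(run_start[i] - 1L, run_start[i] + run_len[i]),
                      tiles_in_run)
    flank2 <- setdiff(c(run_start[i] - 2L, run_start[i] + run_len[i] + 1L),
                      c(tiles_in_run, flank1))
    set_tiles <- function(tt, value) {
      tt <- tt[tt >= 0 & tt < n_tiles]
      truth_values[i, unmod$spot_id[tt + 1L]] <<- value
    }
    set_tiles(tiles_in_run, peak[i])
    set_tiles(flank1, 0.5 * peak[i])
    set_tiles(flank2, 0.2 * peak[i])
    ## promiscuous low-level binding on parent spots away from the footprint
    away <- unmod$spot_id[!(unmod$tile_index %in%
                              c(tiles_in_run, flank1, flank2))]
    n_prom <- min(spec$n_promiscuous_spots, length(away))
    if (n_prom > 0) {
      prom_spots <- sample(away, n_prom)
      truth_values[i, prom_spots] <-
        peak[i] * stats::runif(n_prom, 1e-4, 0.05)
    }
  }

  ## isolated background binders: one spot each (any spot of the matrix)
  bg_spot <- sample(spots, n_bg, replace = TRUE)
  bg_intensity <- stats::rlnorm(n_bg, spec$background_meanlog,
                                spec$background_sdlog)
  for (j in seq_len(n_bg)) {
    truth_values[n_true + j, bg_spot[j]] <- bg_intensity[j]
  }

  ## planted PTM responses on eligible (true binder, group) pairs
  ptm_truth <- data.frame(uniprot_id = character(0),
                          parent_spot_id = character(0),
                          category = character(0),
                          regulated_variant = character(0),
                          stringsAsFactors = FALSE)
  if (length(groups) && spec$ptm_per_category > 0 && n_true > 0) {
    eligible_groups <- names(groups)[lengths(groups) <= spec$ptm_max_variants]
    pairs <- list()
    for (i in seq_len(n_true)) {
      tiles_in_run <- run_start[i]:(run_start[i] + run_len[i] - 1L)
      gg <- eligible_groups[group_tile[match(eligible_groups,
                                             names(groups))] %in%
                              tiles_in_run]
      if (length(gg)) {
        pairs[[length(pairs) + 1L]] <-
          data.frame(binder = i, parent = gg, stringsAsFactors = FALSE)
      }
    }
    pairs <- do.call(rbind, pairs)
    ## one planted group per binder, so footprints stay dominant
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    pairs <- pairs[!duplicated(pairs$binder), , drop = FALSE]
    ## regulated needs >= 2 variants (one in, one out of the band)
    n_variants <- lengths(groups)[pairs$parent]
    reg_pool <- which(n_variants >= 2L)
    reg_idx <- reg_pool[seq_len(min(spec$ptm_per_category,
                                    length(reg_pool)))]
    rest <- setdiff(seq_len(nrow(pairs)), reg_idx)
    other <- rep_len(c("repressed", "independent", "enhanced"),
                     min(3L * spec$ptm_per_category, length(rest)))
    sel <- pairs[c(reg_idx, rest[seq_along(other)]), , drop = FALSE]
    categories <- c(rep("regulated", length(reg_idx)), other)
    take <- nrow(sel)
    reg_var <- character(take)
    for (s in seq_len(take)) {
      i <- sel$binder[s]
      parent <- sel$parent[s]
      variants <- groups[[parent]]
      parent_value <- truth_values[i, parent]
      cat_s <- categories[s]
      if (cat_s == "regulated") {
        mult <- rep(1, length(variants))
        pick <- sample.int(length(variants), 1L)
        mult[pick] <- 8
        reg_var[s] <- variants[pick]
      } else {
        mult <- rep(PTM_CATEGORY_MULTIPLIERS[[cat_s]], length(variants))
        reg_var[s] <- ""
      }
      truth_values[i, variants] <- parent_value * mult
    }
    ptm_truth <- data.frame(uniprot_id = ids[sel$binder],
                            parent_spot_id = sel$parent,
                            category = categories,
                            regulated_variant = reg_var,
                            stringsAsFactors = FALSE)
  }

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  make_rep <- function(label) {
    v <- truth_values
    nz <- which(v > 0)
    if (spec$noise_cv > 0) {
      v[nz] <- v[nz] * stats::rlnorm(length(nz), -sdlog^2 / 2, sdlog)
    }
    if (spec$dropout > 0) {
      drop <- nz[stats::runif(length(nz)) < spec$dropout]
      v[drop] <- 0
    }
    new_intensity_table(
      label, v,
      data.frame(uniprot_id = ids, gene_name = ids, stringsAsFactors = FALSE)
    )
  }
  rep1 <- make_rep("rep1")
  rep2 <- make_rep("rep2")

  truth <- data.frame(
    uniprot_id = ids,
    type = c(rep("true", n_true), rep("background", n_bg)),
    run_start_tile = c(run_start, rep(NA_integer_, n_bg)),
    run_length = c(run_len, rep(NA_integer_, n_bg)),
    peak = c(peak, bg_intensity),
    spot = c(rep(NA_character_, n_true), bg_spot),
    stringsAsFactors = FALSE
  )
  list(rep1 = rep1, rep2 = rep2, truth = truth, ptm_truth = ptm_truth,
       design = design)
}

#' Score pipeline output against planted truth
#'
#' Core-set precision and recall are computed against the planted true
#' binders that were detected in both replicates (the only ones the core
#' filter can recover). When a PTM classification table is supplied, the
#' planted-versus-assigned category confusion matrix and the recovery rate
#' over planted pairs are added.
#'
#' @param sets A `prisma_sets` from [derive_interactor_sets()].
#' @param screen The list returned by [generate_screen()].
#' @param ptm_result Optional result of [ptm_response_matrix()] on the same
#'   screen.
#' @return A list with `precision`, `recall` (NA when not evaluable),
#'   `n_eligible`, `n_core`, and optionally `ptm_confusion`,
#'   `ptm_recovery`.
#' @export
score_recovery <- function(sets, screen, ptm_result = NULL) {
  stopifnot(inherits(sets, "prisma_sets"))
  truth <- screen$truth
  if (!all(sets$core %in% truth$uniprot_id)) {
    stop("core set contains proteins unknown to the truth report")
  }
  true_ids <- truth$uniprot_id[truth$type == "true"]
  eligible <- intersect(true_ids, sets$both)
  tp <- length(intersect(sets$core, eligible))
  precision <- if (length(sets$core)) {
    length(intersect(sets$core, true_ids)) / length(sets$core)
  } else NA_real_
  recall <- if (length(eligible)) tp / length(eligible) else NA_real_
  out <- list(precision = precision, recall = recall,
              n_eligible = length(eligible), n_core = length(sets$core))
  if (!is.null(ptm_result) && nrow(screen$ptm_truth)) {
    planted <- screen$ptm_truth
    cls <- ptm_result$classifications
    key <- paste(cls$uniprot_id, cls$parent_spot_id)
    assigned <- cls$category[match(paste(planted$uniprot_id,
                                         planted$parent_spot_id), key)]
    assigned[is.na(assigned)] <- "not_evaluable"
    levels <- c("repressed", "independent", "regulated", "enhanced",
                "not_evaluable")
    out$ptm_confusion <- table(
      planted = factor(planted$category, levels = levels),
      assigned = factor(assigned, levels = levels)
    )
    out$ptm_recovery <- mean(assigned == planted$category)
  }
  out
}
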