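#' PTM-response configuration
#'
#' @param fold_threshold Fold change delta separating the response bands
#'   (default 2: ratios at or below 1/2 count as reduced, at or above 2 as
#'   enhanced).
#' @param cap_value Finite stand-in ratio when the unmodified spot carries
#'   no signal but a variant does (default 64); always flagged.
#' @param min_detected_variants Minimum detected variants for a
#'   classification (default 1).
#' @return A `prisma_ptm_config` list.
#' @export
ptm_config <- function(fold_threshold = 2, cap_value = 64,
                       min_detected_variants = 1L) {
  stopifnot(fold_threshold > 1, cap_value > fold_threshold,
            min_detected_variants >= 1)
  structure(
    list(fold_threshold = fold_threshold, cap_value = cap_value,
         min_detected_variants = as.integer(min_detected_variants)),
    class = "prisma_ptm_config"
  )
}

#' Peptide groups of a design
#'
#' A group is an unmodified spot together with all its PTM-variant spots
#' (identical coordinates). Only parents with at least one variant are
#' returned.
#'
#' @param design The matrix design.
#' @return Named list (by parent spot id) of character vectors of variant
#'   spot ids.
#' @export
ptm_groups <- function(design) {
  variants <- design[design$ptms != "", , drop = FALSE]
  if (!nrow(variants)) return(list())
  split(variants$spot_id, variants$parent_spot_id)
}

#' Modified-to-unmodified binding ratios for one group
#'
#' Ratios are computed on integrated raw intensities (before 0-1
#' normalization, which would distort within-group ratios). A variant with
#' signal but a silent parent gets the finite `cap_value` with a `capped`
#' flag; a variant silent together with its parent is marked not detected.
#'
#' @param values Named per-spot raw intensity vector for one protein.
#' @param parent_spot_id The unmodified spot of the group.
#' @param variant_spot_ids Its PTM-variant spots.
#' @param cfg A [ptm_config()].
#' @return Data frame with `variant_spot_id`, `ratio`, `capped`, `detected`.
#' @export
ptm_ratio <- function(values, parent_spot_id, variant_spot_ids,
                      cfg = ptm_config()) {
  missing_spots <- setdiff(c(parent_spot_id, variant_spot_ids), names(values))
  if (length(missing_spots)) {
    stop("spot(s) not in the profile: ", paste(missing_spots, collapse = ", "))
  }
  ip <- values[[parent_spot_id]]
  iv <- values[variant_spot_ids]
  detected <- iv > 0 | ip > 0
  ratio <- rep(NA_real_, length(iv))
  capped <- rep(FALSE, length(iv))
  for (j in seq_along(iv)) {
    if (!detected[j]) next
    if (ip > 0) {
      ratio[j] <- iv[[j]] / ip
    } else {
      ratio[j] <- cfg$cap_value
      capped[j] <- TRUE
    }
  }
  data.frame(variant_spot_id = variant_spot_ids, ratio = ratio,
             capped = capped, detected = unname(detected),
             stringsAsFactors = FALSE)
}

#' Classify a group's PTM response
#'
#' Four-category rule over the detected variant ratios with band
#' `(1/delta, delta)`: `repressed` when every ratio is at or below
#' `1/delta`, `enhanced` when every ratio is at or above `delta`,
#' `independent` when every ratio lies strictly inside the band, and
#' `regulated` (PTM-specific) otherwise -- at least one variant outside the
#' band while the rest are not on the same side. Scale-invariant: rescaling
#' the whole group's raw signals leaves the category unchanged.
#'
#' @param ratios Data frame from [ptm_ratio()] (or a numeric ratio vector).
#' @param cfg A [ptm_config()].
#' @return One of `"repressed"`, `"independent"`, `"regulated"`,
#'   `"enhanced"`, or `"not_evaluable"` when fewer than
#'   `min_detected_variants` variants are detected.
#' @export
classify_response <- function(ratios, cfg = ptm_config()) {
  r <- if (is.data.frame(ratios)) ratios$ratio[ratios$detected] else
    ratios[!is.na(ratios)]
  if (length(r) < cfg$min_detected_variants) return("not_evaluable")
  d <- cfg$fold_threshold
  if (all(r <= 1 / d)) return("repressed")
  if (all(r >= d)) return("enhanced")
  if (all(r > 1 / d & r < d)) return("independent")
  "regulated"
}

#' PTM-response table over all proteins and peptide groups
#'
#' For every protein detected on at least one spot of a group, computes the
#' modified/unmodified ratios and the four-category response. Ratios are
#' taken from raw (integrated, un-normalized) profiles.
#'
#' @param profiles Raw `prisma_profiles` from [integrate_replicates()].
#' @param design The matrix design (must contain PTM variant spots).
#' @param cfg A [ptm_config()].
#' @return A list with `table` (long data frame `uniprot_id`,
#'   `parent_spot_id`, `variant_spot_id`, `ratio`, `capped`, `category`),
#'   `classifications` (one row per evaluable (protein, group) pair),
#'   `counts` (category tally) and `cluster_order` (deterministic
#'   hierarchical-cluster order of the per-protein log-ratio vectors).
#' @export
ptm_response_matrix <- function(profiles, design, cfg = ptm_config()) {
  stopifnot(inherits(profiles, "prisma_profiles"))
  if (profiles$normalized) {
    stop("ptm_response_matrix expects raw (un-normalized) profiles")
  }
  groups <- ptm_groups(design)
  empty <- list(
    table = data.frame(uniprot_id = character(0),
                       parent_spot_id = character(0),
                       variant_spot_id = character(0), ratio = numeric(0),
                       capped = logical(0), category = character(0)),
    classifications = data.frame(uniprot_id = character(0),
                                 parent_spot_id = character(0),
                                 category = character(0)),
    counts = c(repressed = 0L, independent = 0L, regulated = 0L,
               enhanced = 0L),
    cluster_order = character(0)
  )
  if (!length(groups)) return(empty)
  ids <- rownames(profiles$values)
  rows <- list()
  cls <- list()
  for (id in ids) {
    v <- profiles$values[id, ]
    for (parent in names(groups)) {
      spots <- c(parent, groups[[parent]])
      if (all(v[spots] == 0)) next
      rat <- ptm_ratio(v, parent, groups[[parent]], cfg)
      category <- classify_response(rat, cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        uniprot_id = id, parent_spot_id = parent,
        variant_spot_id = rat$variant_spot_id, ratio = rat$ratio,
        capped = rat$capped, category = category, stringsAsFactors = FALSE
      )
      cls[[length(cls) + 1L]] <- data.frame(
        uniprot_id = id, parent_spot_id = parent, category = category,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) return(empty)
  table <- do.call(rbind, c(rows, make.row.names = FALSE))
  classifications <- do.call(rbind, c(cls, make.row.names = FALSE))
  evaluable <- classifications[classifications$category != "not_evaluable", ]
  counts <- c(repressed = 0L, independent = 0L, regulated = 0L,
              enhanced = 0L)
  tab <- table(evaluable$category)
  counts[names(tab)] <- as.integer(tab)
  ## deterministic cluster order of per-protein log2-ratio vectors
  variant_ids <- unlist(groups, use.names = FALSE)
  prot <- sort(unique(table$uniprot_id))
  m <- matrix(0, nrow = length(prot), ncol = length(variant_ids),
              dimnames = list(prot, variant_ids))
  fin <- !is.na(table$ratio)
  m[cbind(table$uniprot_id[fin], table$variant_spot_id[fin])] <-
    log2(pmax(table$ratio[fin], 1 / cfg$cap_value))
  cluster_order <- if (nrow(m) >= 2L) {
    hc <- stats::hclust(stats::dist(m), method = "average")
    rownames(m)[hc$order]
  } else rownames(m)
  list(table = table, classifications = classifications, counts = counts,
       cluster_order = cluster_order)
}
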