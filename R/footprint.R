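#' Accumulated binding intensity per matrix spot
#'
#' Sums the normalized (optionally filtered) intensities over a set of
#' proteins for every spot, and counts the proteins with nonzero signal per
#' spot. Accumulation is linear in the contributing protein set.
#'
#' @param profiles A normalized `prisma_profiles`.
#' @return A data frame with `spot_id`, `accumulated` and `protein_count`.
#' @export
accumulated_spot_intensity <- function(profiles) {
  stopifnot(inherits(profiles, "prisma_profiles"))
  if (!profiles$normalized) {
    stop("accumulated_spot_intensity expects normalized profiles")
  }
  data.frame(
    spot_id = colnames(profiles$values),
    accumulated = unname(colSums(profiles$values)),
    protein_count = unname(colSums(profiles$values > 0)),
    stringsAsFactors = FALSE
  )
}

#' Interaction footprint of one protein
#'
#' Maps the maximal runs of surviving tiles to merged residue intervals in
#' parent-protein coordinates: each interval spans from the first residue of
#' its run's first tile to the last residue of its last tile. Footprints are
#' defined on the unmodified tiling; variant spots mark their parent tile.
#'
#' @param values Named per-spot value vector (one row of filtered profiles).
#' @param design The matrix design.
#' @param min_run Minimum run length to report (default 1: every surviving
#'   tile contributes).
#' @return A data frame with `start`, `end` (1-based inclusive),
#'   `start_tile`, `end_tile`; zero rows when nothing survives.
#' @export
protein_footprint <- function(values, design, min_run = 1L) {
  present <- tile_signal(values, design)
  runs <- maximal_runs(present)
  runs <- runs[runs$length >= min_run, , drop = FALSE]
  unmod <- design[design$ptms == "", , drop = FALSE]
  start <- unmod$start[match(runs$start_tile, unmod$tile_index)]
  end <- unmod$end[match(runs$end_tile, unmod$tile_index)]
  out <- data.frame(start = start, end = end,
                    start_tile = runs$start_tile, end_tile = runs$end_tile)
  out[order(out$start), , drop = FALSE]
}

#' Footprint intervals for a set of proteins
#'
#' @param profiles Filtered `prisma_profiles`.
#' @param design The matrix design.
#' @param ids Protein ids (default: all rows).
#' @param min_run Minimum run length to report.
#' @return BED-like data frame `uniprot_id start end` (1-based inclusive).
#' @export
footprint_table <- function(profiles, design, ids = rownames(profiles$values),
                            min_run = 1L) {
  out <- lapply(ids, function(id) {
    fp <- protein_footprint(profiles$values[id, ], design, min_run)
    if (!nrow(fp)) return(NULL)
    data.frame(uniprot_id = id, fp[, c("start", "end")],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(out, make.row.names = FALSE))
  if (is.null(out)) {
    out <- data.frame(uniprot_id = character(0), start = integer(0),
                      end = integer(0))
  }
  out
}

#' Accumulated footprint of a protein complex
#'
#' Sums the normalized per-spot intensities over the complex members found
#' in the screen; members missing from the profiles contribute zero and are
#' reported.
#'
#' @param member_ids UniProt ids of the complex members.
#' @param profiles A normalized `prisma_profiles`.
#' @return A data frame as in [accumulated_spot_intensity()], with
#'   attributes `n_found` and `missing`.
#' @export
complex_footprint <- function(member_ids, profiles) {
  stopifnot(inherits(profiles, "prisma_profiles"))
  member_ids <- unique(normalize_uniprot_ids(member_ids))
  found <- intersect(member_ids, rownames(profiles$values))
  missing <- setdiff(member_ids, found)
  if (!length(found)) {
    warning("no complex member found in the screen")
  }
  sub <- profiles$values[found, , drop = FALSE]
  out <- data.frame(
    spot_id = colnames(profiles$values),
    accumulated = unname(colSums(sub)),
    protein_count = unname(colSums(sub > 0)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_found") <- length(found)
  attr(out, "missing") <- missing
  out
}

#' Row ordering for a clustered binding heatmap
#'
#' Agglomerative hierarchical clustering of the normalized profiles
#' (Euclidean distance, average linkage by default). Rows are pre-sorted by
#' protein id before clustering so the leaf order is deterministic and
#' invariant to the input row order.
#'
#' @param profiles A normalized `prisma_profiles` with at least one protein.
#' @param method Linkage passed to [stats::hclust()]; default `"average"`.
#' @param distance Distance measure passed to [stats::dist()]; default
#'   `"euclidean"`.
#' @return A list with `order` (protein ids in leaf order), `matrix` (the
#'   reordered value matrix) and `hclust` (the tree, `NULL` for a single
#'   protein).
#' @export
cluster_heatmap_matrix <- function(profiles, method = "average",
                                   distance = "euclidean") {
  stopifnot(inherits(profiles, "prisma_profiles"))
  v <- profiles$values[order(rownames(profiles$values)), , drop = FALSE]
  if (nrow(v) < 2L) {
    return(list(order = rownames(v), matrix = v, hclust = NULL))
  }
  hc <- stats::hclust(stats::dist(v, method = distance), method = method)
  ord <- rownames(v)[hc$order]
  list(order = ord, matrix = v[ord, , drop = FALSE], hclust = hc)
}
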