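#' Pipeline configuration
#'
#' Houses the filter parameters of the interaction pipeline: the outlier
#' quantile (signals below this quantile of each protein's detected signal
#' distribution are removed; default 0.90), and the minimum number of
#' adjacent tiles a surviving signal must span (consecutive-binding
#' criterion; default 2).
#'
#' @param outlier_quantile Fraction in (0, 1); default 0.90.
#' @param min_run Minimum run of adjacent tiles; default 2.
#' @param quantile_method Only `"nearest_rank"` is implemented.
#' @param keep_rule Only `"geq_threshold"` (values equal to the threshold
#'   survive) is implemented.
#' @param integration Only `"mean_of_detected"` is implemented.
#' @return A `prisma_config` list.
#' @export
pipeline_config <- function(outlier_quantile = 0.90, min_run = 2L,
                            quantile_method = "nearest_rank",
                            keep_rule = "geq_threshold",
                            integration = "mean_of_detected") {
  stopifnot(outlier_quantile > 0, outlier_quantile < 1, min_run >= 1)
  quantile_method <- match.arg(quantile_method, "nearest_rank")
  keep_rule <- match.arg(keep_rule, "geq_threshold")
  integration <- match.arg(integration, "mean_of_detected")
  structure(
    list(outlier_quantile = outlier_quantile, min_run = as.integer(min_run),
         quantile_method = quantile_method, keep_rule = keep_rule,
         integration = integration),
    class = "prisma_config"
  )
}

new_profiles <- function(values, confidence, replicate_ids,
                         normalized = FALSE, outlier_filtered = FALSE) {
  structure(
    list(values = values, confidence = confidence,
         replicate_ids = replicate_ids, normalized = normalized,
         outlier_filtered = outlier_filtered),
    class = "prisma_profiles"
  )
}

#' @export
print.prisma_profiles <- function(x, ...) {
  state <- c(if (x$normalized) "normalized" else "raw",
             if (x$outlier_filtered) "outlier-filtered")
  cat("<prisma_profiles> ", nrow(x$values), " proteins x ", ncol(x$values),
      " spots (", paste(state, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Integrate two replicate intensity tables
#'
#' Per (protein, spot), the integrated value is the mean of the detected
#' (nonzero) replicate values; detection in both replicates is labelled
#' `double` (high confidence), in one `single` (low confidence), in neither
#' `absent`. Proteins appearing in either replicate appear in the output.
#'
#' @param rep1,rep2 `prisma_intensities` objects over the same design.
#' @return A raw `prisma_profiles` object: per-protein intensity matrix
#'   (rownames = uniprot ids) plus a parallel confidence matrix.
#' @export
integrate_replicates <- function(rep1, rep2) {
  stopifnot(inherits(rep1, "prisma_intensities"),
            inherits(rep2, "prisma_intensities"))
  if (!identical(colnames(rep1$intensities), colnames(rep2$intensities))) {
    stop("replicates cover different spot sets; align them to one design")
  }
  if (anyDuplicated(rep1$proteins$uniprot_id) ||
      anyDuplicated(rep2$proteins$uniprot_id)) {
    stop("duplicate protein ids; run merge_protein_ids() first")
  }
  ids <- sort(union(rep1$proteins$uniprot_id, rep2$proteins$uniprot_id))
  spots <- colnames(rep1$intensities)
  expand <- function(tab) {
    m <- matrix(0, nrow = length(ids), ncol = length(spots),
                dimnames = list(ids, spots))
    m[tab$proteins$uniprot_id, ] <- tab$intensities
    m
  }
  v1 <- expand(rep1)
  v2 <- expand(rep2)
  ndet <- (v1 > 0) + (v2 > 0)
  values <- (v1 + v2) / pmax(ndet, 1L)
  confidence <- matrix(c("absent", "single", "double")[ndet + 1L],
                       nrow = length(ids), dimnames = list(ids, spots))
  new_profiles(values, confidence,
               c(rep1$replicate_id, rep2$replicate_id))
}

#' Normalize each profile between 0 and 1
#'
#' Divides each protein's intensities by that protein's maximum across all
#' matrix spots, so every detected profile has maximum exactly 1. All-zero
#' profiles stay all-zero and are flagged in the `undetected` attribute.
#'
#' @param profiles A raw `prisma_profiles`.
#' @return The normalized `prisma_profiles`.
#' @export
normalize_profiles <- function(profiles) {
  stopifnot(inherits(profiles, "prisma_profiles"))
  if (any(profiles$values < 0)) stop("negative intensities are not allowed")
  rowmax <- apply(profiles$values, 1, max)
  scale <- ifelse(rowmax > 0, rowmax, 1)
  out <- profiles
  out$values <- profiles$values / scale
  out$normalized <- TRUE
  attr(out, "undetected") <- rownames(profiles$values)[rowmax == 0]
  out
}

nearest_rank_threshold <- function(detected, q) {
  sort(detected)[ceiling(q * length(detected))]
}

#' Remove signals below each protein's outlier threshold
#'
#' For each protein the threshold is the nearest-rank `outlier_quantile`
#' percentile of its detected (nonzero) values; values below the threshold
#' are set to zero and values at or above it are kept. A profile set that
#' has already been outlier-filtered is returned unchanged, so the filter is
#' idempotent.
#'
#' @param profiles A normalized `prisma_profiles`.
#' @param cfg A [pipeline_config()].
#' @return The filtered `prisma_profiles`.
#' @export
outlier_filter <- function(profiles, cfg = pipeline_config()) {
  stopifnot(inherits(profiles, "prisma_profiles"))
  if (!profiles$normalized) stop("outlier_filter expects normalized profiles")
  if (profiles$outlier_filtered) return(profiles)
  v <- profiles$values
  for (i in seq_len(nrow(v))) {
    det <- v[i, ] > 0
    if (!any(det)) next
    thr <- nearest_rank_threshold(v[i, det], cfg$outlier_quantile)
    v[i, v[i, ] < thr] <- 0
  }
  out <- profiles
  out$values <- v
  out$outlier_filtered <- TRUE
  out
}

tile_signal <- function(values, design) {
  ## collapse spots to the unmodified tile order: a variant's surviving
  ## signal marks its parent tile
  if (!identical(sort(names(values)), sort(design$spot_id))) {
    stop("profile spots do not match the design")
  }
  idx <- design$tile_index[match(names(values), design$spot_id)]
  tiles <- sort(unique(design$tile_index))
  present <- vapply(tiles, function(t) any(values[idx == t] > 0), logical(1))
  names(present) <- tiles
  present
}

maximal_runs <- function(present) {
  r <- rle(present)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(
    start_tile = as.integer(names(present))[starts[keep]],
    end_tile = as.integer(names(present))[ends[keep]],
    length = r$lengths[keep]
  )
}

#' Apply the consecutive-binding criterion to one profile
#'
#' Surviving spot signals are collapsed to unmodified tile indices (a PTM
#' variant marks its parent tile, since both occupy identical coordinates).
#' The protein passes when some run of at least `min_run` adjacent tiles all
#' carry surviving signal, exploiting the overlap between neighboring tiling
#' peptides.
#'
#' @param values Named per-spot value vector (one row of filtered profiles).
#' @param design The matrix design.
#' @param cfg A [pipeline_config()].
#' @return A list with `passes` (logical) and `runs` (data frame of all
#'   maximal runs: `start_tile`, `end_tile`, `length`).
#' @export
consecutive_filter <- function(values, design, cfg = pipeline_config()) {
  present <- tile_signal(values, design)
  runs <- maximal_runs(present)
  list(passes = any(runs$length >= cfg$min_run), runs = runs)
}

#' Derive replicate, intersection and core interactor sets
#'
#' Applies the full filter chain: identifier merging, raw per-replicate
#' detection (SET1/SET2), replicate integration, 0-1 normalization, outlier
#' filtering and the consecutive-binding criterion. The core set contains
#' the proteins detected in both replicates whose filtered, integrated
#' profile spans at least `min_run` adjacent tiles.
#'
#' @param rep1,rep2 `prisma_intensities` objects over `design`.
#' @param design The matrix design.
#' @param cfg A [pipeline_config()].
#' @return A `prisma_sets` object: list with `set1`, `set2`, `both`,
#'   `union`, `core` (character vectors of uniprot ids), `profiles` (the
#'   filtered normalized profiles), `raw_profiles` (integrated, unfiltered),
#'   `runs` (per-core-protein surviving runs) and `provenance` (the config).
#' @export
derive_interactor_sets <- function(rep1, rep2, design,
                                   cfg = pipeline_config()) {
  rep1 <- merge_protein_ids(rep1)
  rep2 <- merge_protein_ids(rep2)
  detected <- function(tab) {
    tab$proteins$uniprot_id[rowSums(tab$intensities > 0) > 0]
  }
  set1 <- sort(detected(rep1))
  set2 <- sort(detected(rep2))
  both <- intersect(set1, set2)
  raw <- integrate_replicates(rep1, rep2)
  filtered <- outlier_filter(normalize_profiles(raw), cfg)
  core <- character(0)
  runs <- list()
  for (id in both) {
    res <- consecutive_filter(filtered$values[id, ], design, cfg)
    ok <- res$runs[res$runs$length >= cfg$min_run, , drop = FALSE]
    if (res$passes) {
      core <- c(core, id)
      runs[[id]] <- data.frame(uniprot_id = id, ok,
                               stringsAsFactors = FALSE)
    }
  }
  structure(
    list(
      set1 = set1, set2 = set2, both = both,
      union = sort(union(set1, set2)), core = sort(core),
      profiles = filtered, raw_profiles = raw,
      runs = if (length(runs)) do.call(rbind, c(runs, make.row.names = FALSE))
             else data.frame(uniprot_id = character(0),
                             start_tile = integer(0), end_tile = integer(0),
                             length = integer(0)),
      provenance = cfg
    ),
    class = "prisma_sets"
  )
}

#' @export
print.prisma_sets <- function(x, ...) {
  cat("<prisma_sets>\n",
      "  union: ", length(x$union), " proteins\n",
      "  SET1:  ", length(x$set1), "  SET2: ", length(x$set2), "\n",
      "  both:  ", length(x$both), "\n",
      "  core:  ", length(x$core),
      " (consecutive binding, min_run = ", x$provenance$min_run, ")\n",
      sep = "")
  invisible(x)
}

#' Physicochemical bias check of accumulated binding
#'
#' Accumulates normalized binding intensity per spot over all proteins and
#' rank-correlates (Spearman) the per-spot totals of the unmodified tiles
#' with peptide hydrophobicity (GRAVY) and isoelectric point. A specific
#' screen should show no strong dependence on either. Also reports the
#' abundance span: log10 of the ratio between the largest and smallest
#' positive accumulated value.
#'
#' @param profiles Normalized `prisma_profiles`.
#' @param design The matrix design.
#' @param pka_table pKa set name for the pI computation.
#' @return A list with `table` (per unmodified spot: accumulated value,
#'   gravy, pI), `gravy_cor`, `pi_cor` (each a list with `rho`, `p_value`,
#'   or `NA` entries with `note = "not applicable"` for a constant
#'   covariate) and `abundance_span`.
#' @export
bias_check <- function(profiles, design, pka_table = "emboss") {
  stopifnot(inherits(profiles, "prisma_profiles"))
  if (ncol(profiles$values) < 3L) stop("need at least 3 spots")
  acc <- colSums(profiles$values)
  unmod <- design[design$ptms == "", , drop = FALSE]
  acc_u <- acc[unmod$spot_id]
  gravy <- vapply(unmod$sequence, peptide_gravy, numeric(1))
  pis <- vapply(unmod$sequence,
                function(s) as.numeric(peptide_isoelectric_point(s, pka_table)),
                numeric(1))
  cor_or_na <- function(x, y) {
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
      return(list(rho = NA_real_, p_value = NA_real_,
                  note = "not applicable (constant input)"))
    }
    ct <- suppressWarnings(
      stats::cor.test(x, y, method = "spearman", exact = FALSE)
    )
    list(rho = unname(ct$estimate), p_value = ct$p.value, note = "")
  }
  pos <- acc[acc > 0]
  span <- if (length(pos)) log10(max(pos) / min(pos)) else NA_real_
  list(
    table = data.frame(spot_id = unmod$spot_id, accumulated = unname(acc_u),
                       gravy = unname(gravy), pi = unname(pis),
                       stringsAsFactors = FALSE),
    gravy_cor = cor_or_na(acc_u, gravy),
    pi_cor = cor_or_na(acc_u, pis),
    abundance_span = span,
    pka_table = pka_table
  )
}
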