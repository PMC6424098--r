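#' Overlap between two protein sets
#'
#' @param query,reference `prisma_refset` objects (or character vectors).
#' @return A data frame with the set sizes, the exact intersection size and
#'   both directional coverages (percent).
#' @export
overlap_stats <- function(query, reference) {
  qname <- if (inherits(query, "prisma_refset")) query$name else "query"
  rname <- if (inherits(reference, "prisma_refset")) reference$name else
    "reference"
  q <- if (inherits(query, "prisma_refset")) query$members else
    unique(query)
  r <- if (inherits(reference, "prisma_refset")) reference$members else
    unique(reference)
  if (!length(r)) stop("reference set is empty")
  k <- length(intersect(q, r))
  data.frame(
    query = qname, reference = rname,
    n_query = length(q), n_reference = length(r), n_intersection = k,
    coverage_of_reference = 100 * k / length(r),
    coverage_of_query = if (length(q)) 100 * k / length(q) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Intersection-based interaction FDR estimate
#'
#' Capture-recapture style estimator under the assumption that false
#' positives do not replicate between independently acquired interaction
#' datasets. The sensitivity of screen B is estimated on a high-precision
#' reference R as `|B n R| / |R|`; the true positives in screen A are then
#' approximately `|A n B|` divided by that sensitivity, giving
#' `FDR_A = 1 - |A n B| * |R| / (|A| * |B n R|)`, clipped to `[0, 1]`.
#'
#' @param A The screen whose FDR is estimated (`prisma_refset` or character
#'   vector).
#' @param B An independent second screen.
#' @param R A high-precision reference interactor set.
#' @return A list with `fdr` (`NA` with a note when `|B n R| = 0`),
#'   `estimator` and the echoed inputs `n_A`, `n_AB`, `n_R`, `n_BR`.
#' @export
estimate_interaction_fdr <- function(A, B, R) {
  members <- function(x) if (inherits(x, "prisma_refset")) x$members else
    unique(x)
  a <- members(A); b <- members(B); r <- members(R)
  n_A <- length(a)
  n_AB <- length(intersect(a, b))
  n_R <- length(r)
  n_BR <- length(intersect(b, r))
  if (n_BR == 0L || n_A == 0L) {
    return(list(fdr = NA_real_, estimator = "intersection_capture_recapture",
                note = "not evaluable: reference recaptures nothing",
                n_A = n_A, n_AB = n_AB, n_R = n_R, n_BR = n_BR))
  }
  fdr <- 1 - n_AB * n_R / (n_A * n_BR)
  list(fdr = min(max(fdr, 0), 1),
       estimator = "intersection_capture_recapture", note = "",
       n_A = n_A, n_AB = n_AB, n_R = n_R, n_BR = n_BR)
}

#' Upper-tail hypergeometric test
#'
#' Probability of drawing at least `k` category members when sampling `n`
#' proteins without replacement from a background of `N` containing `K`
#' category members: `P(X >= k)`, summed termwise from the exact
#' hypergeometric mass.
#'
#' @param k Observed overlap.
#' @param n Query (draw) size.
#' @param K Category size within the background.
#' @param N Background size.
#' @return The upper-tail p-value.
#' @export
hypergeometric_test <- function(k, n, K, N) {
  stopifnot(length(k) == 1, length(n) == 1, length(K) == 1, length(N) == 1)
  if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K)) {
    stop("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  if (k == 0) return(1)
  sum(stats::dhyper(seq.int(k, min(n, K)), K, N - K, n))
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up adjustment controlling the false discovery rate;
#' adjusted values are monotone in the sorted order, never below the raw
#' values and never above 1.
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Hypergeometric annotation enrichment
#'
#' One upper-tail hypergeometric test per annotation term against a
#' user-supplied background, with Benjamini-Hochberg control.
#'
#' @param query Character vector (or `prisma_refset`) of hit proteins; must
#'   be contained in `background`.
#' @param annotations Data frame `term_id`, `term_name`, `uniprot_id` (one
#'   row per membership; duplicates are removed).
#' @param background Character vector of all testable proteins.
#' @param alpha Significance cutoff on the adjusted p-value (default 0.01).
#' @return Data frame per term: counts, `p_value`, `p_adjusted`,
#'   `significant`; sorted by adjusted p then descending count.
#' @export
annotation_enrichment <- function(query, annotations, background,
                                  alpha = 0.01) {
  q <- if (inherits(query, "prisma_refset")) query$members else unique(query)
  background <- unique(background)
  if (!all(q %in% background)) {
    stop("query contains proteins outside the background")
  }
  miss <- setdiff(c("term_id", "term_name", "uniprot_id"),
                  names(annotations))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  ann <- unique(annotations[, c("term_id", "term_name", "uniprot_id")])
  terms <- split(ann, ann$term_id)
  rows <- lapply(terms, function(tt) {
    members <- intersect(unique(tt$uniprot_id), background)
    if (!length(members)) {
      warning("term '", tt$term_id[1], "' has no background members; skipped")
      return(NULL)
    }
    k <- length(intersect(q, members))
    data.frame(
      term_id = tt$term_id[1], term_name = tt$term_name[1],
      count = k, term_size = length(members),
      p_value = hypergeometric_test(k, length(q), length(members),
                                    length(background)),
      stringsAsFactors = FALSE
    )
  })
  rows <- do.call(rbind, c(rows, make.row.names = FALSE))
  if (is.null(rows)) {
    return(data.frame(term_id = character(0), term_name = character(0),
                      count = integer(0), term_size = integer(0),
                      p_value = numeric(0), p_adjusted = numeric(0),
                      significant = logical(0)))
  }
  rows$p_adjusted <- bh_adjust(rows$p_value)
  rows$significant <- rows$p_adjusted <= alpha
  rows <- rows[order(rows$p_adjusted, -rows$count, rows$term_id), ,
               drop = FALSE]
  rownames(rows) <- NULL
  rows
}

fisher_combine <- function(p1, p2) {
  stat <- -2 * (log(pmax(p1, .Machine$double.xmin)) +
                log(pmax(p2, .Machine$double.xmin)))
  stats::pchisq(stat, df = 4, lower.tail = FALSE)
}

#' Rank complexes by coverage and deviation from randomness
#'
#' Complexes are retained when they share at least `min_prisma` proteins
#' with the screen set and at least `min_combined` proteins with the union
#' of the screen and IP sets (both sets are first intersected with the
#' catalog background). Each retained complex gets (1) the percentage of
#' its members covered by the screen and (2) upper-tail hypergeometric
#' p-values for the screen and IP coverages against the catalog background,
#' combined with Fisher's method. The final rank is the mean of the rank by
#' descending coverage and the rank by ascending combined p, with ties
#' broken by descending complex size then complex id; the upper quartile is
#' ranks `1 .. floor(n/4)`.
#'
#' @param prisma_set Screen-derived protein ids (`prisma_refset` or
#'   character).
#' @param ip_set Affinity-purification protein ids.
#' @param catalog A `prisma_complexes` catalog.
#' @param min_prisma Minimum screen overlap (default 1).
#' @param min_combined Minimum overlap with the union of both sets
#'   (default 3).
#' @return A `prisma_ranking` data frame: one row per complex with overlap
#'   counts, coverages, p-values, `retained`, `rank` (`NA` when filtered
#'   out) and `upper_quartile`.
#' @export
rank_complexes <- function(prisma_set, ip_set, catalog, min_prisma = 1L,
                           min_combined = 3L) {
  stopifnot(inherits(catalog, "prisma_complexes"))
  if (!nrow(catalog$complexes)) stop("empty complex catalog")
  members <- function(x) if (inherits(x, "prisma_refset")) x$members else
    unique(x)
  bg <- catalog$background
  pr <- intersect(normalize_uniprot_ids(members(prisma_set)), bg)
  ip <- intersect(normalize_uniprot_ids(members(ip_set)), bg)
  comb <- union(pr, ip)
  df <- catalog$complexes
  df$overlap_prisma <- vapply(
    catalog$members, function(m) length(intersect(m, pr)), integer(1))
  df$overlap_ip <- vapply(
    catalog$members, function(m) length(intersect(m, ip)), integer(1))
  overlap_comb <- vapply(
    catalog$members, function(m) length(intersect(m, comb)), integer(1))
  df$coverage_prisma <- 100 * df$overlap_prisma / df$size
  df$p_prisma <- mapply(hypergeometric_test, df$overlap_prisma,
                        MoreArgs = list(n = length(pr), N = length(bg)),
                        K = df$size)
  df$p_ip <- mapply(hypergeometric_test, df$overlap_ip,
                    MoreArgs = list(n = length(ip), N = length(bg)),
                    K = df$size)
  df$combined_p <- fisher_combine(df$p_prisma, df$p_ip)
  df$retained <- df$overlap_prisma >= min_prisma &
    overlap_comb >= min_combined
  df$rank <- NA_integer_
  df$upper_quartile <- FALSE
  ret <- which(df$retained)
  if (length(ret)) {
    rank_cov <- rank(-df$coverage_prisma[ret], ties.method = "average")
    rank_p <- rank(df$combined_p[ret], ties.method = "average")
    score <- (rank_cov + rank_p) / 2
    ord <- order(score, -df$size[ret], df$complex_id[ret])
    df$rank[ret[ord]] <- seq_along(ret)
    boundary <- floor(length(ret) / 4)
    df$upper_quartile <- !is.na(df$rank) & df$rank <= boundary
  }
  attr(df, "params") <- list(min_prisma = min_prisma,
                             min_combined = min_combined,
                             combination = "mean_of_ranks")
  class(df) <- c("prisma_ranking", "data.frame")
  df
}

#' Monte-Carlo benchmark of the intersection FDR estimator
#'
#' Simulates two screens over a planted interactome: each screen detects
#' every true interactor independently with probability `sensitivity` and
#' adds false positives drawn from a disjoint background pool, sized so the
#' screen's planted FDR equals `true_fdr`. A random subset of true
#' interactors serves as the high-precision reference. Returns the
#' estimator's output for screen A in every simulation.
#'
#' @param true_fdr Planted false-discovery rate of each screen.
#' @param n_true Number of planted true interactors (default 1000).
#' @param sensitivity Per-screen detection probability (default 0.8).
#' @param n_background Size of the false-positive pool (default 5000).
#' @param n_reference Size of the reference set (default 200).
#' @param n_sims Number of simulations (default 20).
#' @param seed Seed fixing all randomness.
#' @return Data frame with one row per simulation: `estimate`, `true_fdr`,
#'   `error`.
#' @export
simulate_fdr_benchmark <- function(true_fdr, n_true = 1000L,
                                   sensitivity = 0.8, n_background = 5000L,
                                   n_reference = 200L, n_sims = 20L,
                                   seed = 1L) {
  stopifnot(true_fdr >= 0, true_fdr < 1)
  set.seed(seed)
  truth <- sprintf("TP%05d", seq_len(n_true))
  pool <- sprintf("BG%05d", seq_len(n_background))
  n_fp <- round(true_fdr * sensitivity * n_true / (1 - true_fdr))
  one <- function() {
    detect <- function() {
      tp <- truth[stats::runif(n_true) < sensitivity]
      c(tp, sample(pool, n_fp))
    }
    A <- detect()
    B <- detect()
    R <- sample(truth, n_reference)
    estimate_interaction_fdr(A, B, R)$fdr
  }
  est <- vapply(seq_len(n_sims), function(i) one(), numeric(1))
  data.frame(estimate = est, true_fdr = true_fdr, error = est - true_fdr)
}
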