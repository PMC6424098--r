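#' @keywords internal
"_PACKAGE"

## Kyte-Doolittle hydropathy values, one per standard residue.
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

AA_STANDARD <- names(KD_HYDROPATHY)

## pKa sets for the composition-based charge model. Keys: Nterm/Cterm plus
## ionizable side chains.
PKA_TABLES <- list(
  emboss = c(
    Nterm = 8.6, Cterm = 3.6,
    C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1
  ),
  lehninger = c(
    Nterm = 9.69, Cterm = 2.34,
    C = 8.33, D = 3.86, E = 4.25, H = 6.0, K = 10.53, R = 12.48, Y = 10.07
  )
)

## Modification types and the residue each one is chemically compatible with.
PTM_RESIDUE <- c(
  phospho_S = "S", phospho_T = "T", phospho_Y = "Y",
  acetyl_K = "K", methyl_K = "K", methyl_R = "R", citrulline_R = "R"
)

#' Construct a validated protein sequence
#'
#' @param id Identifier string.
#' @param residues Amino-acid string using the 20 standard one-letter codes.
#' @return An object of class `protein_sequence` with fields `id`,
#'   `residues` and `length` (1-based residue coordinates throughout).
#' @export
protein_sequence <- function(id, residues) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  chars <- strsplit(residues, "")[[1]]
  if (length(chars) < 1L) {
    stop("protein sequence must contain at least one residue")
  }
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad)) {
    stop("non-standard amino-acid letter(s) in '", id, "': ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(id = id, residues = residues, length = nchar(residues)),
    class = "protein_sequence"
  )
}

#' @export
print.protein_sequence <- function(x, ...) {
  cat("<protein_sequence> ", x$id, " (", x$length, " aa)\n", sep = "")
  invisible(x)
}

protein_residue <- function(protein, position) {
  substring(protein$residues, position, position)
}

#' Tile a protein into overlapping matrix peptides
#'
#' Generates the unmodified spots of a peptide matrix: fixed-length windows
#' shifted by a constant offset so that neighboring spots overlap. With
#' `tail_policy = "anchor_c_terminus"` a final window ending exactly at the
#' C-terminus is appended whenever the last regular window falls short of it,
#' so the tiles always cover the whole protein.
#'
#' @param protein A [protein_sequence()].
#' @param length Peptide length in residues (default 14).
#' @param offset Start-to-start shift between consecutive tiles (default 4).
#' @param tail_policy `"anchor_c_terminus"` (default) or `"drop"`.
#' @return A `prisma_design` data frame with columns `spot_id`, `sequence`,
#'   `start`, `end`, `ptms` (semicolon-separated `mod_type:position`, empty
#'   for unmodified spots), `parent_spot_id` and `tile_index` (0-based).
#' @export
tile_sequence <- function(protein, length = 14L, offset = 4L,
                          tail_policy = c("anchor_c_terminus", "drop")) {
  tail_policy <- match.arg(tail_policy)
  stopifnot(inherits(protein, "protein_sequence"))
  length <- as.integer(length)
  offset <- as.integer(offset)
  if (offset < 1L) stop("offset must be >= 1")
  if (length < 1L) stop("peptide length must be >= 1")
  if (length > protein$length) {
    stop("protein '", protein$id, "' (", protein$length,
         " aa) is shorter than the peptide length (", length, " aa)")
  }
  starts <- seq.int(1L, protein$length - length + 1L, by = offset)
  if (tail_policy == "anchor_c_terminus" &&
      max(starts) + length - 1L < protein$length) {
    starts <- c(starts, protein$length - length + 1L)
  }
  ends <- starts + length - 1L
  spot_id <- sprintf("t%03d", seq_along(starts))
  design <- data.frame(
    spot_id = spot_id,
    sequence = substring(protein$residues, starts, ends),
    start = starts,
    end = ends,
    ptms = "",
    parent_spot_id = spot_id,
    tile_index = seq_along(starts) - 1L,
    stringsAsFactors = FALSE
  )
  class(design) <- c("prisma_design", "data.frame")
  design
}

validate_ptm_annotations <- function(ptms, protein) {
  stopifnot(is.data.frame(ptms),
            all(c("position", "residue", "mod_type") %in% names(ptms)))
  bad_type <- setdiff(ptms$mod_type, names(PTM_RESIDUE))
  if (length(bad_type)) {
    stop("unknown mod_type(s): ", paste(bad_type, collapse = ", "))
  }
  for (i in seq_len(nrow(ptms))) {
    pos <- ptms$position[i]
    if (pos < 1L || pos > protein$length) {
      stop("PTM position ", pos, " outside protein [1, ", protein$length, "]")
    }
    actual <- protein_residue(protein, pos)
    if (actual != ptms$residue[i]) {
      stop("PTM at position ", pos, " expects residue '", ptms$residue[i],
           "' but the protein has '", actual, "'")
    }
    compat <- PTM_RESIDUE[[ptms$mod_type[i]]]
    if (compat != ptms$residue[i]) {
      stop("mod_type '", ptms$mod_type[i], "' is not compatible with residue '",
           ptms$residue[i], "' at position ", pos)
    }
  }
  invisible(TRUE)
}

#' Expand a tiling design with PTM-variant spots
#'
#' For every annotated modification falling inside a tile, a modified copy of
#' that spot is appended. Variants inherit the parent's coordinates, sequence
#' and `tile_index`; their `spot_id` is
#' `<parent_spot_id>+<mod_type><position>`. Under the default `single_ptm`
#' policy each (tile, PTM) pair yields one variant; under `combinations`
#' every non-empty subset of the PTMs inside a tile yields one variant.
#'
#' @param design A `prisma_design` of unmodified tiles.
#' @param ptms Data frame with columns `position`, `residue`, `mod_type`.
#' @param protein The parent [protein_sequence()] (used for validation).
#' @param policy `"single_ptm"` (default) or `"combinations"`.
#' @return The design with variant rows appended, grouped after each parent.
#' @export
expand_ptm_variants <- function(design, ptms, protein,
                                policy = c("single_ptm", "combinations")) {
  policy <- match.arg(policy)
  stopifnot(inherits(design, "prisma_design"))
  validate_ptm_annotations(ptms, protein)
  parents <- design[design$ptms == "", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(parents))) {
    tl <- parents[i, ]
    inside <- ptms[ptms$position >= tl$start & ptms$position <= tl$end, ,
                   drop = FALSE]
    if (!nrow(inside)) next
    inside <- inside[order(inside$position, inside$mod_type), , drop = FALSE]
    combos <- if (policy == "single_ptm") {
      lapply(seq_len(nrow(inside)), function(j) inside[j, , drop = FALSE])
    } else {
      idx <- seq_len(nrow(inside))
      unlist(lapply(idx, function(k) {
        lapply(seq_len(ncol(utils::combn(idx, k))), function(cc) {
          inside[utils::combn(idx, k)[, cc], , drop = FALSE]
        })
      }), recursive = FALSE)
    }
    for (combo in combos) {
      tag <- paste0(combo$mod_type, combo$position, collapse = "+")
      row <- tl
      row$spot_id <- paste0(tl$spot_id, "+", tag)
      row$ptms <- paste0(combo$mod_type, ":", combo$position, collapse = ";")
      row$parent_spot_id <- tl$spot_id
      out[[length(out) + 1L]] <- row
    }
  }
  res <- rbind(design, do.call(rbind, out))
  res <- res[order(res$tile_index, res$ptms != "", res$spot_id), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("prisma_design", "data.frame")
  res
}

#' Region names intersecting a tile
#'
#' @param tile One row of a design (or a list with `start`, `end`).
#' @param regions Data frame with columns `name`, `start`, `end`
#'   (1-based inclusive protein coordinates; names unique).
#' @return Character vector of every region whose interval intersects the
#'   tile's `[start, end]`; empty if none.
#' @export
annotate_regions <- function(tile, regions) {
  stopifnot(all(c("name", "start", "end") %in% names(regions)))
  if (anyDuplicated(regions$name)) stop("region names must be unique")
  if (any(regions$start > regions$end) || any(regions$start < 1L)) {
    stop("invalid region coordinates")
  }
  hit <- regions$start <= tile$end & regions$end >= tile$start
  regions$name[hit]
}

#' GRAVY score of a peptide
#'
#' Grand average of hydropathy: the arithmetic mean of the per-residue
#' Kyte-Doolittle hydropathy values.
#'
#' @param sequence Peptide string (standard residues only).
#' @return Mean hydropathy (dimensionless).
#' @export
peptide_gravy <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad)) {
    stop("non-standard amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  mean(unname(KD_HYDROPATHY[chars]))
}

peptide_net_charge <- function(counts, n_term, c_term, pka, pH) {
  pos <- 0
  for (g in c("K", "R", "H")) {
    n <- counts[[g]] %||% 0
    if (n > 0) pos <- pos + n / (1 + 10^(pH - pka[[g]]))
  }
  if (n_term) pos <- pos + 1 / (1 + 10^(pH - pka[["Nterm"]]))
  neg <- 0
  for (g in c("D", "E", "C", "Y")) {
    n <- counts[[g]] %||% 0
    if (n > 0) neg <- neg + n / (1 + 10^(pka[[g]] - pH))
  }
  if (c_term) neg <- neg + 1 / (1 + 10^(pka[["Cterm"]] - pH))
  pos - neg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Isoelectric point of a peptide
#'
#' Finds the pH at which the Henderson-Hasselbalch net charge of the peptide
#' (free termini plus ionizable side chains) is zero, by bisection on
#' `[0, 14]` to `|charge| < 1e-6`. The charge model is composition-based, so
#' the result is invariant under residue permutation.
#'
#' @param sequence Peptide string (standard residues only).
#' @param pka_table Name of a published pKa set: `"emboss"` (default) or
#'   `"lehninger"`.
#' @return The pI as a numeric value with attribute `pka_table` recording the
#'   set used.
#' @export
peptide_isoelectric_point <- function(sequence, pka_table = "emboss") {
  pka <- PKA_TABLES[[pka_table]]
  if (is.null(pka)) {
    stop("unknown pKa table '", pka_table, "'; available: ",
         paste(names(PKA_TABLES), collapse = ", "))
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(unique(chars), AA_STANDARD)
  if (length(bad)) {
    stop("non-standard amino-acid letter(s): ", paste(bad, collapse = ", "))
  }
  counts <- as.list(table(chars))
  lo <- 0; hi <- 14
  q_lo <- peptide_net_charge(counts, TRUE, TRUE, pka, lo)
  q_hi <- peptide_net_charge(counts, TRUE, TRUE, pka, hi)
  if (q_lo < 0 || q_hi > 0) {
    stop("net charge does not change sign on [0, 14]; pI not defined")
  }
  for (iter in 1:200) {
    mid <- (lo + hi) / 2
    q <- peptide_net_charge(counts, TRUE, TRUE, pka, mid)
    if (abs(q) < 1e-6) break
    if (q > 0) lo <- mid else hi <- mid
  }
  if (abs(q) >= 1e-6) stop("bisection failed to converge on [0, 14]")
  structure(mid, pka_table = pka_table)
}

#' The default 203-spot matrix design
#'
#' A fixed, fully synthetic design emulating the shape of a C/EBPbeta-style
#' screen matrix: a 297-residue disordered-protein-like sequence tiled into
#' 72 overlapping 14-mers (offset 4, C-anchored tail) plus 131 single-PTM
#' variant spots covering phosphorylation, lysine acetylation/methylation,
#' arginine methylation and citrullination -- 203 spots in total. The
#' sequence and modification sites are synthetic stand-ins, not a published
#' protein.
#'
#' @return A list with elements `protein` (a [protein_sequence()]), `ptms`
#'   (the annotation table) and `design` (the 203-row `prisma_design`).
#' @export
default_design <- function() {
  seq297 <- paste0(
    "SLPYTRVVKDVFPAIEETKTKTRAGPSLTSYRTRKFPLQKLARRPSKFSNQGDPNEGPPK",
    "DIHKFETRELLAFGRKRLSEARIEDIGKNRTQAHGNPVHFLAAYQSPAAAIGGLAGSKRC",
    "AEHKGAVQTSSYDMMSLKEQSDSLTEGLATQHQAKPVSMASFHRTAHKIQVSKRKVRVFD",
    "VVAVGVAGKDPASQGAPESIPIDLMSQPEAEAKFSNAKTGIQEGVWETIRSYRQNSPHTC",
    "FEIVGPEDFDAPLLRFEGPSIKDSAKPEPSYGPYLTKGGVFESNAEGDAGSGVEQSK"
  )
  protein <- protein_sequence("SYNPROT1", seq297)
  positions <- c(1, 4, 6, 9, 20, 21, 27, 29, 30, 31, 34, 35, 44, 60, 67, 75,
                 76, 77, 79, 91, 118, 132, 141, 143, 161, 165, 173, 175, 177,
                 206, 213, 218, 219, 231, 236, 266, 276, 277, 283, 291, 297)
  residues <- c("S", "Y", "R", "K", "T", "K", "S", "T", "S", "Y", "R", "K",
                "R", "K", "T", "R", "K", "R", "S", "T", "K", "Y", "S", "S",
                "S", "T", "K", "K", "R", "S", "K", "K", "T", "S", "S", "K",
                "T", "K", "S", "S", "K")
  mods <- c("phospho_S", "phospho_Y", "methyl_R", "methyl_K", "phospho_T",
            "methyl_K", "phospho_S", "phospho_T", "phospho_S", "phospho_Y",
            "methyl_R", "methyl_K", "methyl_R", "acetyl_K", "phospho_T",
            "citrulline_R", "acetyl_K", "citrulline_R", "phospho_S",
            "phospho_T", "acetyl_K", "phospho_Y", "phospho_S", "phospho_S",
            "phospho_S", "phospho_T", "methyl_K", "methyl_K", "citrulline_R",
            "phospho_S", "methyl_K", "acetyl_K", "phospho_T", "phospho_S",
            "phospho_S", "acetyl_K", "phospho_T", "methyl_K", "phospho_S",
            "phospho_S", "methyl_K")
  ptms <- data.frame(position = positions, residue = residues,
                     mod_type = mods, stringsAsFactors = FALSE)
  tiles <- tile_sequence(protein)
  design <- expand_ptm_variants(tiles, ptms, protein)
  list(protein = protein, ptms = ptms, design = design)
}
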