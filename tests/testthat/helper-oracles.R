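# Independent oracles, kept deliberately separate from the package code.

# Upper-tail hypergeometric probability by enumeration over all subsets of
# size n from a background 1..N in which the category is {1..K}.
brute_force_hyper <- function(k, n, K, N) {
  if (n == 0L || K == 0L) return(if (k == 0L) 1 else 0)
  subsets <- utils::combn(N, n)
  overlap <- colSums(subsets <= K)
  mean(overlap >= k)
}

# Step-up Benjamini-Hochberg written from the definition: adjusted p for the
# i-th smallest value is min over j >= i of p_(j) * m / j, capped at 1.
step_up_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ranked <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Per-residue lookup-and-average GRAVY oracle with its own copy of the
# Kyte-Doolittle table.
oracle_gravy <- function(sequence) {
  tab <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
           E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
           M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
           Y = -1.3, V = 4.2)
  vals <- tab[strsplit(sequence, "")[[1]]]
  sum(vals) / length(vals)
}

# Coarse grid-scan pI oracle over the same Henderson-Hasselbalch charge
# model (EMBOSS pKa set), independent of the bisection routine.
oracle_pi <- function(sequence) {
  pka <- c(Nterm = 8.6, Cterm = 3.6, C = 8.5, D = 3.9, E = 4.1, H = 6.5,
           K = 10.8, R = 12.5, Y = 10.1)
  chars <- strsplit(sequence, "")[[1]]
  charge_at <- function(pH) {
    pos <- 1 / (1 + 10^(pH - pka["Nterm"]))
    for (g in c("K", "R", "H")) {
      pos <- pos + sum(chars == g) / (1 + 10^(pH - pka[g]))
    }
    neg <- 1 / (1 + 10^(pka["Cterm"] - pH))
    for (g in c("D", "E", "C", "Y")) {
      neg <- neg + sum(chars == g) / (1 + 10^(pka[g] - pH))
    }
    unname(pos - neg)
  }
  grid <- seq(0, 14, by = 0.001)
  grid[which.min(abs(vapply(grid, charge_at, numeric(1))))]
}

random_peptide <- function(n, letters = c("A", "R", "N", "D", "C", "Q", "E",
                                          "G", "H", "I", "L", "K", "M", "F",
                                          "P", "S", "T", "W", "Y", "V")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Small helpers to build in-memory tables for the pipeline tests.
make_table <- function(replicate_id, ids, mat, genes = ids) {
  colnames(mat) <- colnames(mat)
  prisma:::new_intensity_table(
    replicate_id, mat,
    data.frame(uniprot_id = ids, gene_name = genes, stringsAsFactors = FALSE)
  )
}

# A bare tiling design data frame (no PTM spots) with arbitrary sequences.
make_design <- function(n_tiles, sequences = NULL) {
  spot_id <- sprintf("t%03d", seq_len(n_tiles))
  data.frame(
    spot_id = spot_id,
    sequence = if (is.null(sequences)) strrep("A", 14) else sequences,
    start = 4L * (seq_len(n_tiles) - 1L) + 1L,
    end = 4L * (seq_len(n_tiles) - 1L) + 14L,
    ptms = "",
    parent_spot_id = spot_id,
    tile_index = seq_len(n_tiles) - 1L,
    stringsAsFactors = FALSE
  )
}

profiles_from_matrix <- function(mat, normalized = FALSE,
                                 outlier_filtered = FALSE) {
  conf <- matrix("absent", nrow(mat), ncol(mat), dimnames = dimnames(mat))
  conf[mat > 0] <- "double"
  prisma:::new_profiles(mat, conf, c("rep1", "rep2"),
                        normalized = normalized,
                        outlier_filtered = outlier_filtered)
}
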