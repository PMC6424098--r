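Package: prisma
Title: Analysis of Protein Interaction Screens on Peptide Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of protein interaction screens on peptide
    matrices (PRISMA): tiling-peptide matrix designs with post-translational
    modification (PTM) variant spots, replicate protein-by-spot intensity
    tables in MaxQuant proteinGroups-style dialects, per-protein 0-1
    normalization, outlier filtering on each protein's signal distribution,
    the consecutive-binding criterion, interaction footprints in parent
    protein coordinates, PTM-dependent binding classification into four
    response categories, intersection-based interaction false discovery
    rate estimation, hypergeometric annotation enrichment with
    Benjamini-Hochberg control, and CORUM-style protein-complex ranking.
    Includes a synthetic screen generator with planted ground truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
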