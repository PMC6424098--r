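#' Read a protein sequence from a FASTA file
#'
#' @param path FASTA file; the first record is used.
#' @return A [protein_sequence()].
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path)
  id <- strsplit(names(aa)[1], "\\s+")[[1]][1]
  protein_sequence(id, as.character(aa[[1]]))
}

#' Read / write a matrix design table
#'
#' Tab-separated with header
#' `spot_id sequence start end ptms parent_spot_id tile_index`; `ptms` is a
#' semicolon-separated list like `methyl_R:163` (empty for unmodified spots).
#'
#' @param path File path.
#' @return A `prisma_design` data frame.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(ptms = "character"))
  req <- c("spot_id", "sequence", "start", "end", "ptms", "parent_spot_id",
           "tile_index")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("design file missing column(s): ",
                         paste(miss, collapse = ", "))
  df$ptms[is.na(df$ptms)] <- ""
  class(df) <- c("prisma_design", "data.frame")
  df
}

#' @rdname read_design
#' @param design A `prisma_design`.
#' @export
write_design <- function(design, path) {
  utils::write.table(as.data.frame(design), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a region annotation table
#'
#' Tab-separated `name start end`, 1-based inclusive protein coordinates.
#' @param path File path.
#' @return Data frame of regions.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("name", "start", "end"), names(df))
  if (length(miss)) stop("region file missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$name)) stop("region names must be unique")
  df
}

normalize_uniprot_ids <- function(ids) {
  sub("-[0-9]+$", "", ids)
}

new_intensity_table <- function(replicate_id, intensities, proteins) {
  stopifnot(is.matrix(intensities), nrow(intensities) == nrow(proteins))
  if (any(intensities < 0)) stop("intensities must be non-negative")
  structure(
    list(replicate_id = replicate_id, intensities = intensities,
         proteins = proteins),
    class = "prisma_intensities"
  )
}

#' @export
print.prisma_intensities <- function(x, ...) {
  cat("<prisma_intensities> replicate '", x$replicate_id, "': ",
      nrow(x$intensities), " proteins x ", ncol(x$intensities),
      " spots\n", sep = "")
  invisible(x)
}

#' Read a protein-by-spot intensity table
#'
#' Two dialects are supported. `generic_tsv` expects columns `uniprot_id`,
#' `gene_name` and one numeric column per spot id. `maxquant_protein_groups`
#' expects `Majority protein IDs`, `Gene names`, the flag columns `Reverse`
#' and `Potential contaminant`, and one `Intensity <spot_id>` column per
#' spot; rows flagged as reverse decoys or contaminants (flag `+` or
#' identifier prefixes `REV__` / `CON__`) are dropped and the count reported.
#' Spot columns are aligned to the design order; spots missing from the file
#' are filled with zeros with a warning.
#'
#' @param path File path.
#' @param design The matrix design whose `spot_id` order defines the columns.
#' @param dialect `"generic_tsv"` (default) or `"maxquant_protein_groups"`.
#' @param replicate_id Label for the replicate (default: file name).
#' @param strict If `TRUE` (default) an intensity column matching no design
#'   spot is an error; if `FALSE` it is dropped with a warning.
#' @return A `prisma_intensities` object.
#' @export
read_intensity_table <- function(path, design,
                                 dialect = c("generic_tsv",
                                             "maxquant_protein_groups"),
                                 replicate_id = basename(path),
                                 strict = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  spots <- design$spot_id
  if (dialect == "generic_tsv") {
    if (!"uniprot_id" %in% names(df)) {
      stop("intensity table is missing the 'uniprot_id' column")
    }
    if (!"gene_name" %in% names(df)) df$gene_name <- df$uniprot_id
    value_cols <- setdiff(names(df), c("uniprot_id", "gene_name"))
    proteins <- data.frame(uniprot_id = df$uniprot_id,
                           gene_name = df$gene_name,
                           stringsAsFactors = FALSE)
  } else {
    idc <- "Majority protein IDs"
    if (!idc %in% names(df)) {
      stop("intensity table is missing the '", idc, "' column")
    }
    flagged <- rep(FALSE, nrow(df))
    if ("Reverse" %in% names(df)) flagged <- flagged | df$Reverse == "+"
    if ("Potential contaminant" %in% names(df)) {
      flagged <- flagged | df[["Potential contaminant"]] == "+"
    }
    flagged <- flagged | grepl("^(REV__|CON__)", df[[idc]])
    if (any(flagged)) {
      message("dropped ", sum(flagged), " contaminant/decoy row(s)")
      df <- df[!flagged, , drop = FALSE]
    }
    first_id <- vapply(strsplit(df[[idc]], ";"), `[`, "", 1L)
    genes <- if ("Gene names" %in% names(df)) {
      vapply(strsplit(df[["Gene names"]], ";"), `[`, "", 1L)
    } else first_id
    proteins <- data.frame(uniprot_id = first_id, gene_name = genes,
                           stringsAsFactors = FALSE)
    value_cols <- grep("^Intensity ", names(df), value = TRUE)
    names(df)[match(value_cols, names(df))] <-
      sub("^Intensity ", "", value_cols)
    value_cols <- sub("^Intensity ", "", value_cols)
  }
  unknown <- setdiff(value_cols, spots)
  if (length(unknown)) {
    if (strict) {
      stop("intensity column(s) not in the design: ",
           paste(unknown, collapse = ", "))
    }
    warning("dropping ", length(unknown), " column(s) not in the design")
    value_cols <- setdiff(value_cols, unknown)
  }
  mat <- matrix(0, nrow = nrow(df), ncol = length(spots),
                dimnames = list(NULL, spots))
  for (cc in value_cols) {
    v <- df[[cc]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    if (anyNA(v)) {
      stop("non-numeric intensity in column '", cc, "', row(s) ",
           paste(utils::head(which(is.na(v)), 3), collapse = ", "))
    }
    mat[, cc] <- v
  }
  missing_spots <- setdiff(spots, value_cols)
  if (length(missing_spots)) {
    warning(length(missing_spots),
            " design spot(s) missing from the file; filled with 0")
  }
  new_intensity_table(replicate_id, mat, proteins)
}

#' Merge isoform and duplicate protein identifiers
#'
#' Strips isoform suffixes (`-<digits>`) from UniProt identifiers and merges
#' rows sharing the normalized identifier, taking the per-spot maximum
#' intensity (so shared peptides are never double-counted). The merged row's
#' gene name is taken from the input row with the highest total intensity.
#' Idempotent.
#'
#' @param table A `prisma_intensities` object.
#' @return The merged `prisma_intensities`, rows sorted by identifier.
#' @export
merge_protein_ids <- function(table) {
  stopifnot(inherits(table, "prisma_intensities"))
  ids <- normalize_uniprot_ids(table$proteins$uniprot_id)
  groups <- split(seq_along(ids), ids)
  n <- length(groups)
  mat <- matrix(0, nrow = n, ncol = ncol(table$intensities),
                dimnames = list(NULL, colnames(table$intensities)))
  genes <- character(n)
  uid <- names(groups)
  for (i in seq_len(n)) {
    rows <- groups[[i]]
    block <- table$intensities[rows, , drop = FALSE]
    mat[i, ] <- apply(block, 2, max)
    genes[i] <- table$proteins$gene_name[rows[which.max(rowSums(block))]]
  }
  ord <- order(uid)
  new_intensity_table(
    table$replicate_id,
    mat[ord, , drop = FALSE],
    data.frame(uniprot_id = uid[ord], gene_name = genes[ord],
               stringsAsFactors = FALSE)
  )
}

#' Read a CORUM-style complex catalog
#'
#' Tab-separated with columns `complex_id`, `complex_name`, `organism` and
#' `subunits` (semicolon-separated UniProt identifiers). Member identifiers
#' are isoform-normalized; rows with no members are skipped with a warning;
#' complexes with identical member sets are deduplicated keeping the lowest
#' `complex_id`.
#'
#' @param path File path.
#' @param organism_filter `"human_only"` (default) keeps rows with
#'   `organism == "Human"`; `"none"` keeps all.
#' @return A `prisma_complexes` object: a list with `complexes` (data frame
#'   `complex_id`, `complex_name`, `size`), `members` (named list of member
#'   id vectors) and `background` (union of all members).
#' @export
read_complex_catalog <- function(path,
                                 organism_filter = c("human_only", "none")) {
  organism_filter <- match.arg(organism_filter)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("complex_id", "complex_name", "organism", "subunits"),
                  names(df))
  if (length(miss)) stop("catalog missing column(s): ",
                         paste(miss, collapse = ", "))
  if (organism_filter == "human_only") {
    df <- df[df$organism == "Human", , drop = FALSE]
  }
  members <- lapply(strsplit(df$subunits, ";"), function(m) {
    sort(unique(normalize_uniprot_ids(m[nzchar(m)])))
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warning("skipped ", sum(empty), " complex row(s) with no members")
    df <- df[!empty, , drop = FALSE]
    members <- members[!empty]
  }
  ord <- order(df$complex_id)
  df <- df[ord, , drop = FALSE]
  members <- members[ord]
  key <- vapply(members, paste, "", collapse = ";")
  keep <- !duplicated(key)
  df <- df[keep, , drop = FALSE]
  members <- members[keep]
  if (anyDuplicated(df$complex_id)) stop("duplicate complex_id after dedup")
  names(members) <- df$complex_id
  new_complex_catalog(df$complex_id, df$complex_name, members)
}

new_complex_catalog <- function(complex_id, complex_name, members) {
  stopifnot(length(complex_id) == length(members))
  structure(
    list(
      complexes = data.frame(complex_id = complex_id,
                             complex_name = complex_name,
                             size = lengths(members),
                             stringsAsFactors = FALSE),
      members = members,
      background = sort(unique(unlist(members, use.names = FALSE)))
    ),
    class = "prisma_complexes"
  )
}

#' @export
print.prisma_complexes <- function(x, ...) {
  cat("<prisma_complexes> ", nrow(x$complexes), " complexes, ",
      length(x$background), " background proteins\n", sep = "")
  invisible(x)
}

#' Read a reference protein set
#'
#' Accepts either one identifier per line or a TSV with a `uniprot_id`
#' column. Identifiers are isoform-normalized and deduplicated.
#'
#' @param path File path.
#' @param name Label for the set.
#' @param role `"reference_interactome"` or `"ip_dataset"`.
#' @return A `prisma_refset`: list with `name`, `members`, `role`.
#' @export
read_reference_set <- function(path, name = basename(path),
                               role = c("reference_interactome",
                                        "ip_dataset")) {
  role <- match.arg(role)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("reference set file is empty: ", path)
  if (grepl("\t", lines[1]) || lines[1] == "uniprot_id") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (!"uniprot_id" %in% names(df)) {
      stop("reference TSV is missing the 'uniprot_id' column")
    }
    ids <- df$uniprot_id
  } else {
    ids <- lines
  }
  reference_set(name, ids, role)
}

#' @rdname read_reference_set
#' @param ids Character vector of identifiers.
#' @export
reference_set <- function(name, ids,
                          role = c("reference_interactome", "ip_dataset")) {
  role <- match.arg(role)
  members <- sort(unique(normalize_uniprot_ids(trimws(ids))))
  members <- members[nzchar(members)]
  if (!length(members)) stop("reference set '", name, "' has no members")
  structure(list(name = name, members = members, role = role),
            class = "prisma_refset")
}

#' @export
print.prisma_refset <- function(x, ...) {
  cat("<prisma_refset> '", x$name, "' (", x$role, "): ",
      length(x$members), " proteins\n", sep = "")
  invisible(x)
}

#' Write an intensity table as generic TSV
#'
#' @param table A `prisma_intensities`.
#' @param path Output path.
#' @export
write_intensity_table <- function(table, path) {
  df <- data.frame(table$proteins, table$intensities, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df <- df[order(df$uniprot_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a bundle of result tables with a checksum manifest
#'
#' Every data frame in `results` is written as a TSV named `<name>.tsv`,
#' rows sorted by the first column, columns in their given order. A
#' `manifest.tsv` records each file with its MD5 checksum, and the
#' configuration and seed are echoed into `run_info.tsv`, so two runs with
#' identical inputs produce byte-identical output directories.
#'
#' @param results Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param config Optional named list echoed into `run_info.tsv`.
#' @param seed Optional seed echoed into `run_info.tsv`.
#' @return Invisibly, the manifest data frame.
#' @export
write_results <- function(results, out_dir, config = NULL, seed = NULL) {
  stopifnot(is.list(results), length(names(results)) == length(results))
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    if (nrow(df) > 1L) df <- df[order(df[[1]]), , drop = FALSE]
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  info <- c(
    list(package_version = as.character(utils::packageVersion("prisma")),
         seed = if (is.null(seed)) "" else as.character(seed)),
    lapply(config, function(v) paste(as.character(v), collapse = ";"))
  )
  info_df <- data.frame(key = names(info), value = unlist(info),
                        stringsAsFactors = FALSE, row.names = NULL)
  info_path <- file.path(out_dir, "run_info.tsv")
  utils::write.table(info_df, info_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, info_path)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = unname(file.size(files)),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}
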