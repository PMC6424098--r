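read_run_config <- function(config = list(), config_file = NULL) {
  base <- list()
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stop("config file not found: ",
                                        config_file)
    base <- yaml::read_yaml(config_file)
    if (is.null(base)) base <- list()
  }
  ## explicit arguments override file values
  for (nm in names(config)) base[[nm]] <- config[[nm]]
  base
}

require_config <- function(config, keys) {
  miss <- keys[!vapply(keys, function(k) !is.null(config[[k]]), logical(1))]
  if (length(miss)) {
    stop("missing required config key(s): ", paste(miss, collapse = ", "))
  }
  invisible(config)
}

config_pipeline <- function(config) {
  pipeline_config(
    outlier_quantile = config$outlier_quantile %||% 0.90,
    min_run = config$min_run %||% 2L
  )
}

config_ptm <- function(config) {
  ptm_config(
    fold_threshold = config$fold_threshold %||% 2,
    cap_value = config$cap_value %||% 64,
    min_detected_variants = config$min_detected_variants %||% 1L
  )
}

load_design <- function(config) {
  if (!is.null(config$design)) read_design(config$design)
  else default_design()$design
}

load_replicates <- function(config, design) {
  require_config(config, c("rep1", "rep2"))
  dialect <- config$dialect %||% "generic_tsv"
  list(rep1 = read_intensity_table(config$rep1, design, dialect, "rep1"),
       rep2 = read_intensity_table(config$rep2, design, dialect, "rep2"))
}

#' Run one pipeline stage end to end
#'
#' Single entry point wiring all stages with deterministic outputs. Each
#' subcommand reads its inputs from the configuration (a flat named list,
#' optionally loaded from a YAML file; explicit values override the file),
#' executes the corresponding package functions and writes its result
#' tables plus a checksum manifest via [write_results()].
#'
#' Subcommands: `design` (write the tiling design, from a FASTA or the
#' built-in default), `simulate` (synthetic replicate pair with truth),
#' `pipeline` (integrate, normalize, outlier-filter, consecutive-binding
#' filter, interactor sets), `footprint` (accumulation and footprint
#' intervals), `ptm` (PTM-response classification), `enrich` (annotation
#' enrichment), `complexes` (complex ranking), `validate` (overlap
#' statistics and intersection FDR against reference sets).
#'
#' @param subcommand One of the stage names above.
#' @param config Named list of configuration values.
#' @param config_file Optional YAML file of configuration values.
#' @param out_dir Output directory (required).
#' @param seed Integer seed recorded in the manifest and used for any
#'   randomness.
#' @return Invisibly, the manifest data frame of written files.
#' @export
prisma_run <- function(subcommand = c("design", "simulate", "pipeline",
                                      "footprint", "ptm", "enrich",
                                      "complexes", "validate"),
                       config = list(), config_file = NULL,
                       out_dir = config$out_dir, seed = 1L) {
  subcommand <- match.arg(subcommand)
  config <- read_run_config(config, config_file)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stop("missing required config key(s): out_dir")
  seed <- as.integer(seed)

  results <- switch(
    subcommand,
    design = {
      if (!is.null(config$fasta)) {
        protein <- read_protein_fasta(config$fasta)
        design <- tile_sequence(protein,
                                length = config$peptide_length %||% 14L,
                                offset = config$offset %||% 4L)
      } else {
        design <- default_design()$design
      }
      list(design = as.data.frame(design))
    },
    simulate = {
      spec <- truth_spec(
        n_true_binders = config$n_true_binders %||% 500L,
        n_background_binders = config$n_background_binders %||% 1500L,
        dropout = config$dropout %||% 0.1,
        noise_cv = config$noise_cv %||% 0.3,
        seed = seed
      )
      screen <- generate_screen(spec)
      list(
        design = as.data.frame(screen$design),
        rep1 = intensity_df(screen$rep1),
        rep2 = intensity_df(screen$rep2),
        truth = screen$truth,
        ptm_truth = screen$ptm_truth
      )
    },
    pipeline = {
      design <- load_design(config)
      reps <- load_replicates(config, design)
      cfg <- config_pipeline(config)
      sets <- derive_interactor_sets(reps$rep1, reps$rep2, design, cfg)
      list(
        interactor_sets = sets_df(sets),
        profiles = profiles_df(sets$profiles),
        runs = sets$runs
      )
    },
    footprint = {
      design <- load_design(config)
      reps <- load_replicates(config, design)
      cfg <- config_pipeline(config)
      sets <- derive_interactor_sets(reps$rep1, reps$rep2, design, cfg)
      unfiltered <- normalize_profiles(sets$raw_profiles)
      list(
        accumulation_filtered = accumulated_spot_intensity(sets$profiles),
        accumulation_unfiltered = accumulated_spot_intensity(unfiltered),
        footprints = footprint_table(sets$profiles, design,
                                     ids = sets$core,
                                     min_run = cfg$min_run)
      )
    },
    ptm = {
      design <- load_design(config)
      reps <- load_replicates(config, design)
      raw <- integrate_replicates(merge_protein_ids(reps$rep1),
                                  merge_protein_ids(reps$rep2))
      res <- ptm_response_matrix(raw, design, config_ptm(config))
      list(ptm_responses = res$table,
           ptm_classifications = res$classifications,
           ptm_counts = data.frame(category = names(res$counts),
                                   n = as.integer(res$counts)))
    },
    enrich = {
      require_config(config, c("query", "annotations", "background"))
      query <- read_reference_set(config$query, "query")
      background <- read_reference_set(config$background, "background")
      ann <- utils::read.delim(config$annotations, stringsAsFactors = FALSE)
      list(enrichment = annotation_enrichment(
        query$members, ann, background$members,
        alpha = config$alpha %||% 0.01))
    },
    complexes = {
      require_config(config, c("prisma_set", "ip_set", "catalog"))
      catalog <- read_complex_catalog(config$catalog)
      ranking <- rank_complexes(
        read_reference_set(config$prisma_set, "prisma"),
        read_reference_set(config$ip_set, "ip", role = "ip_dataset"),
        catalog,
        min_prisma = config$min_prisma %||% 1L,
        min_combined = config$min_combined %||% 3L
      )
      list(complex_ranking = as.data.frame(ranking))
    },
    validate = {
      require_config(config, c("query", "coscreen", "reference"))
      A <- read_reference_set(config$query, "query")
      B <- read_reference_set(config$coscreen, "coscreen")
      R <- read_reference_set(config$reference, "reference")
      fdr <- estimate_interaction_fdr(A, B, R)
      list(
        overlap = rbind(overlap_stats(A, R), overlap_stats(B, R)),
        fdr = data.frame(dataset = A$name, fdr = fdr$fdr,
                         estimator = fdr$estimator, n_A = fdr$n_A,
                         n_AB = fdr$n_AB, n_R = fdr$n_R, n_BR = fdr$n_BR)
      )
    }
  )
  manifest <- write_results(results, out_dir,
                            config = c(list(subcommand = subcommand),
                                       config[setdiff(names(config),
                                                      "design")]),
                            seed = seed)
  invisible(manifest)
}

intensity_df <- function(table) {
  data.frame(table$proteins, table$intensities, check.names = FALSE,
             stringsAsFactors = FALSE)
}

profiles_df <- function(profiles) {
  data.frame(uniprot_id = rownames(profiles$values), profiles$values,
             check.names = FALSE, stringsAsFactors = FALSE)
}

sets_df <- function(sets) {
  ids <- sets$union
  data.frame(
    uniprot_id = ids,
    in_set1 = ids %in% sets$set1,
    in_set2 = ids %in% sets$set2,
    in_both = ids %in% sets$both,
    in_core = ids %in% sets$core,
    outlier_quantile = sets$provenance$outlier_quantile,
    min_run = sets$provenance$min_run,
    stringsAsFactors = FALSE
  )
}
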