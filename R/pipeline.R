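#' Pipeline configuration
#'
#' Validated, schema-checked configuration for [run_pipeline()]. Unknown
#' keys are rejected. Inputs come either from a simulation block (a
#' [simulation_config()]) or from file paths to the external formats.
#'
#' @param simulation a [simulation_config()], or `NULL` when reading files.
#' @param input_dir directory holding `counts_<species>.tsv`,
#'   `metadata.tsv`, `Orthogroups.tsv`, `go_annotations.tsv`,
#'   `species_tree.nwk` (ignored when `simulation` is given).
#' @param output_dir where stage outputs and the manifest are written.
#' @param alpha_screen raw-p screen threshold (ANOVA effects).
#' @param alpha_de BH-adjusted threshold defining DE sets for GO input.
#' @param top_k orthogroups clustered in the congruence stage.
#' @param n_null congruence null replicates.
#' @param mcmc an [mcmc_settings()].
#' @param lambda_max_orthogroups cap on orthogroups fitted in the lambda
#'   stage (the strongest-signal orthogroups are fitted first); `Inf` fits
#'   all complete rows.
#' @param seed global seed; per-stage sub-seeds are derived from it and
#'   recorded in the manifest.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL, input_dir = NULL,
                            output_dir = tempfile("ogde_run_"),
                            alpha_screen = 0.1, alpha_de = 0.1,
                            top_k = 30L, n_null = 1000L,
                            mcmc = mcmc_settings(),
                            lambda_max_orthogroups = 400L,
                            seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(alpha_screen > 0, alpha_screen < 1, alpha_de > 0, alpha_de < 1,
            top_k >= 1L, n_null >= 1L, is.numeric(seed))
  if (is.null(simulation) && is.null(input_dir))
    stop("config needs either a simulation block or an input_dir")
  if (!is.null(simulation) && !inherits(simulation, "sim_config"))
    stop("simulation must be a simulation_config()")
  if (!inherits(mcmc, "mcmc_settings")) stop("mcmc must be mcmc_settings()")
  class(cfg) <- "pipeline_config"
  cfg
}

# deterministic per-stage sub-seed, kept under 2^31
stage_seed <- function(seed, stage) {
  (as.integer(seed) * 1000L + stage) %% .Machine$integer.max
}

#' Load a dataset directory written by [write_dataset()]
#'
#' Reads the per-species count TSVs, metadata, Orthogroups.tsv, GO map and
#' species tree from one directory into an `og_dataset` (without ground
#' truth).
#'
#' @param dir directory with the pipeline's external file formats.
#' @return an `og_dataset` list.
#' @export
load_dataset_dir <- function(dir) {
  meta <- read_sample_metadata(file.path(dir, "metadata.tsv"))
  species <- sort(unique(meta$species_id))
  counts <- lapply(species, function(sp)
    read_count_matrix(file.path(dir, paste0("counts_", sp, ".tsv")), sp))
  names(counts) <- species
  map <- read_orthogroups(file.path(dir, "Orthogroups.tsv"), species = species)
  go <- read_go_annotations(file.path(dir, "go_annotations.tsv"))
  tree <- read_species_tree(file.path(dir, "species_tree.nwk"))
  structure(list(counts = counts, metadata = meta, orthogroups = map,
                 go = go, tree = tree, truth = NULL, config = NULL),
            class = "og_dataset")
}

#' Run the full comparative-transcriptomics pipeline
#'
#' Stages, in order: (1) simulate or load the dataset; (2) per-species
#' median-of-ratios normalization, orthogroup aggregation and core
#' restriction; (3) per-species NB Wald DE at orthogroup and transcript
#' level; (4) cross-species effect decomposition and pairwise Wald
#' correlations; (5) per-species GO enrichment and odds-ratio
#' correlations; (6) top-orthogroup clustering and Icong congruence
#' against the species tree; (7) per-orthogroup Pagel's lambda and DIC
#' model comparison. Every stage writes its table under
#' `config$output_dir` and the manifest records content hashes, the seed
#' and thresholds, so a re-run with the same config reproduces identical
#' hashes.
#'
#' @param config a [pipeline_config()].
#' @return list with all stage results plus `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(config$output_dir, name)
    if (is.data.frame(obj)) {
      write.table(obj, p, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      jsonlite::write_json(obj, p, digits = NA, auto_unbox = TRUE, force = TRUE)
    }
    paths[[name]] <<- p
    p
  }

  # 1. data
  if (!is.null(config$simulation)) {
    sim_cfg <- config$simulation
    sim_cfg$seed <- stage_seed(config$seed, 1L)
    dataset <- simulate_dataset(sim_cfg)
  } else {
    dataset <- load_dataset_dir(config$input_dir)
  }

  # 2. normalize + aggregate + core restriction
  size_factors <- lapply(dataset$counts, compute_size_factors,
                         pseudo_reference = TRUE)
  normalized <- Map(normalize_counts, dataset$counts, size_factors)
  og_all <- aggregate_orthogroups(normalized, dataset$orthogroups)
  og_core <- restrict_to_core(og_all)
  emit(data.frame(orthogroup_id = rownames(og_core),
                  as.data.frame(unclass(og_core)), check.names = FALSE),
       "orthogroup_expression.tsv")

  # 3. differential expression
  de_og <- run_species_de(dataset, level = "orthogroup", og_matrix = og_core)
  de_tx <- run_species_de(dataset, level = "transcript")
  emit(de_og, "de_orthogroup.tsv")
  emit(de_tx, "de_transcript.tsv")

  # 4. cross-species decomposition and correlations
  anova_tab <- fit_all_og_anova(og_core, dataset$metadata)
  emit(anova_tab, "effect_sizes.tsv")
  eff <- effect_size_summary(anova_tab, alpha_screen = config$alpha_screen)
  wald_cor <- pairwise_wald_correlations(de_og)
  emit(wald_cor, "pairwise_wald_correlations.tsv")
  wald_cor_test <- correlation_distribution_test(wald_cor$r)
  cn_cor <- copy_number_lfc_correlation(de_og, attr(og_core, "copy_number"))

  # 5. GO enrichment
  enrichment <- run_go_enrichment(de_tx, dataset$go, alpha_de = config$alpha_de)
  emit(enrichment, "go_enrichment.tsv")
  or_cor <- pairwise_enrichment_correlations(enrichment)
  emit(or_cor, "pairwise_or_correlations.tsv")
  or_cor_test <- correlation_distribution_test(or_cor$r)

  # 6. congruence
  top <- top_de_orthogroups(de_og, k = min(config$top_k,
                                           length(unique(de_og$unit_id))))
  dend <- cluster_species_dendrogram(de_og, top)
  write_species_tree(dend, file.path(config$output_dir, "expression_dendrogram.nwk"))
  paths[["expression_dendrogram.nwk"]] <- file.path(config$output_dir, "expression_dendrogram.nwk")
  congruence <- icong_test(dend, dataset$tree, n_null = config$n_null,
                           seed = stage_seed(config$seed, 6L))
  emit(unclass(congruence), "congruence.json")

  # 7. phylogenetic signal
  wald_mat <- stat_matrix(de_og)
  complete <- apply(is.finite(wald_mat), 1L, all)
  wald_mat <- wald_mat[complete, , drop = FALSE]
  if (is.finite(config$lambda_max_orthogroups) &&
      nrow(wald_mat) > config$lambda_max_orthogroups) {
    keep <- order(-apply(abs(wald_mat), 1L, max))[seq_len(config$lambda_max_orthogroups)]
    wald_mat <- wald_mat[sort(keep), , drop = FALSE]
  }
  C <- tree_to_covariance(dataset$tree)$C
  mc <- config$mcmc
  mc$seed <- stage_seed(config$seed, 7L)
  lambda_tab <- fit_lambda_table(wald_mat, C, settings = mc)
  emit(lambda_tab, "lambda_fits.tsv")

  manifest <- list(
    package_version = as.character(utils::packageVersion("ogde")),
    seed = config$seed,
    stage_seeds = setNames(vapply(c(1L, 6L, 7L), stage_seed,
                                  0L, seed = config$seed),
                           c("simulate", "congruence", "lambda")),
    thresholds = list(alpha_screen = config$alpha_screen,
                      alpha_de = config$alpha_de),
    n_samples = nrow(dataset$metadata),
    n_species = length(dataset$counts),
    n_orthogroups_total = attr(og_core, "n_total"),
    n_orthogroups_core = attr(og_core, "n_core"),
    unassigned_fraction = as.list(attr(og_all, "unassigned_fraction")),
    outputs = lapply(paths, function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, force = TRUE)

  list(dataset = dataset, og_matrix = og_core, de_orthogroup = de_og,
       de_transcript = de_tx, anova = anova_tab, effect_summary = eff,
       wald_correlations = wald_cor, wald_correlation_test = wald_cor_test,
       copy_number_correlation = cn_cor, enrichment = enrichment,
       or_correlations = or_cor, or_correlation_test = or_cor_test,
       top_orthogroups = top, dendrogram = dend, congruence = congruence,
       lambda = lambda_tab, manifest = manifest)
}
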