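#' Simulate a rooted binary species tree
#'
#' Pure-birth (Yule) tree over `n_species` leaves, used as a stand-in for an
#' inferred species phylogeny. Deterministic given `seed`.
#'
#' @param n_species number of leaves (>= 2).
#' @param seed integer seed.
#' @param birth birth rate of the Yule process.
#' @return an [ape::phylo] rooted binary tree with leaf labels
#'   `sp01, sp02, ...` and positive branch lengths.
#' @export
simulate_species_tree <- function(n_species, seed = 1L, birth = 1) {
  if (n_species < 2L) stop("need at least 2 species")
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = birth, death = 0)
  tree$tip.label <- sprintf("sp%02d", seq_len(n_species))
  tree
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the pipeline targets: 14 species,
#' two injection treatments (PBS control vs alum adjuvant), 158 samples in
#' total (9 species with 6 fish per treatment, 5 with 5 per treatment, each
#' species balanced across treatments), negative-binomial 3'TagSeq-like
#' counts with per-sample library size factors, per-orthogroup species
#' baseline effects, a shared treatment log2 fold change for a `de_fraction`
#' of orthogroups, and species-by-treatment interaction deviations with
#' phylogenetic (Brownian, lambda-scaled) covariance.
#'
#' All effect-size parameters are on the log2 scale.
#'
#' @param n_species number of species (leaves of the tree).
#' @param n_orthogroups number of orthogroups to simulate.
#' @param samples_per_species_per_treatment integer vector (recycled to
#'   `n_species`) of fish per treatment in each species. The default yields
#'   158 samples at 14 species.
#' @param frac_core fraction of orthogroups present (copy number >= 1) in
#'   every species; the rest lose each species independently with
#'   probability `dropout`.
#' @param copy_mean mean of the zero-truncated geometric copy-number
#'   distribution per species (>= 1).
#' @param dropout per-species absence probability for non-core orthogroups.
#' @param baseline_log2_mean,baseline_log2_sd Normal parameters of the
#'   per-orthogroup baseline log2 expression.
#' @param species_effect_sd sd of per-orthogroup per-species baseline
#'   deviations (log2).
#' @param de_fraction fraction of orthogroups with a nonzero shared
#'   treatment effect.
#' @param treatment_lfc_sd sd of the shared treatment log2 fold change for
#'   affected orthogroups (ignored when `de_lfc` is given).
#' @param de_lfc optional fixed |log2 fold change| for affected orthogroups
#'   (sign random); `NULL` draws from `N(0, treatment_lfc_sd^2)`.
#' @param interaction_sd sd of species-by-treatment interaction deviations
#'   (log2); deviations are centered to sum to zero across species so the
#'   shared and species-specific components are identifiable.
#' @param lambda_true Pagel's lambda in `[0,1]` scaling the phylogenetic
#'   correlation of interaction deviations (0 = independent, 1 = Brownian).
#' @param nb_dispersion NB dispersion alpha (> 0); variance = mu + alpha mu^2.
#' @param size_factor_log_sd sd of log library size factors (natural log);
#'   factors are rescaled to geometric mean 1.
#' @param n_go_terms number of GO terms in the simulated vocabulary.
#' @param go_terms_per_transcript Poisson mean of terms per transcript.
#' @param seed integer seed; a fixed seed gives a bit-identical dataset.
#' @return a named list of class `sim_config`.
#' @export
simulation_config <- function(n_species = 14L,
                              n_orthogroups = 2000L,
                              samples_per_species_per_treatment =
                                c(rep(6L, 9L), rep(5L, 5L)),
                              frac_core = 0.7,
                              copy_mean = 1.5,
                              dropout = 0.35,
                              baseline_log2_mean = log2(100),
                              baseline_log2_sd = 1.5,
                              species_effect_sd = 0.5,
                              de_fraction = 0.1,
                              treatment_lfc_sd = 1,
                              de_lfc = NULL,
                              interaction_sd = 0.5,
                              lambda_true = 0.5,
                              nb_dispersion = 0.3,
                              size_factor_log_sd = 0.3,
                              n_go_terms = 200L,
                              go_terms_per_transcript = 2,
                              seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 2L, cfg$n_orthogroups >= 1L,
            cfg$lambda_true >= 0, cfg$lambda_true <= 1,
            cfg$nb_dispersion > 0, cfg$copy_mean >= 1,
            cfg$species_effect_sd >= 0, cfg$treatment_lfc_sd >= 0,
            cfg$interaction_sd >= 0, cfg$size_factor_log_sd >= 0,
            cfg$frac_core >= 0, cfg$frac_core <= 1,
            all(cfg$samples_per_species_per_treatment >= 1L))
  cfg$samples_per_species_per_treatment <-
    rep_len(as.integer(cfg$samples_per_species_per_treatment), cfg$n_species)
  class(cfg) <- "sim_config"
  cfg
}

# zero-truncated geometric with mean mu >= 1: 1 + Geom(p), p = 1/mu
rztgeom <- function(n, mu) 1L + rgeom(n, prob = min(1, 1 / mu))

#' Simulate a multi-species 3'TagSeq-like dataset
#'
#' Counts for transcript t (in orthogroup g, species s, sample j with
#' treatment x in {0,1}) are drawn
#' `NB(mean = s_j * w_t * exp(ln2 * (b_g + u_gs + x * (beta_g + delta_gs))),
#' dispersion alpha)` where `w_t` are symmetric Dirichlet weights splitting
#' the orthogroup mean over that species' transcript copies, and the
#' interaction deviations `delta_g.` are multivariate normal with covariance
#' `interaction_sd^2 * C(lambda)`, `C(lambda) = lambda*C + (1-lambda)*I` the
#' lambda-scaled tree correlation matrix, then centered to sum to zero
#' across species.
#'
#' @param config a [simulation_config()].
#' @param tree rooted binary tree whose leaves are the species; defaults to
#'   a Yule tree drawn from the config seed.
#' @return list of class `og_dataset` with elements `counts` (named list of
#'   per-species transcript count matrices), `metadata`, `orthogroups`
#'   (an `orthogroup_map`), `go` (long-form GO annotations), `tree`, and
#'   `truth` (per-orthogroup shared lfc `beta`, interaction matrix `delta`,
#'   `lambda_true`, per-sample size factors, per-transcript DE flag, core
#'   flag per orthogroup).
#' @export
simulate_dataset <- function(config, tree = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  S <- config$n_species
  G <- config$n_orthogroups
  if (is.null(tree)) tree <- ape::rphylo(S, birth = 1, death = 0)
  if (length(tree$tip.label) != S)
    stop("tree has ", length(tree$tip.label), " leaves but config expects ", S)
  tree$tip.label <- sprintf("sp%02d", seq_len(S))
  species <- tree$tip.label
  ln2 <- log(2)

  og_ids <- sprintf("OG%07d", seq_len(G))
  core <- rep(FALSE, G)
  core[seq_len(round(config$frac_core * G))] <- TRUE

  # copy numbers: >= 1 for core orthogroups; others lose species at random
  copies <- matrix(rztgeom(G * S, config$copy_mean), G, S,
                   dimnames = list(og_ids, species))
  absent <- matrix(!core & (runif(G * S) < config$dropout), G, S)
  copies[absent] <- 0L

  # orthogroup-level effects (log2 scale)
  b <- rnorm(G, config$baseline_log2_mean, config$baseline_log2_sd)
  u <- matrix(rnorm(G * S, 0, config$species_effect_sd), G, S,
              dimnames = list(og_ids, species))
  is_de <- runif(G) < config$de_fraction
  beta <- numeric(G)
  if (any(is_de)) {
    beta[is_de] <- if (is.null(config$de_lfc)) {
      rnorm(sum(is_de), 0, config$treatment_lfc_sd)
    } else {
      sample(c(-1, 1), sum(is_de), replace = TRUE) * config$de_lfc
    }
  }

  # interaction deviations with lambda-scaled phylogenetic correlation
  C <- tree_correlation(tree)[species, species]
  Cl <- config$lambda_true * C + (1 - config$lambda_true) * diag(S)
  L <- t(chol(Cl + 1e-10 * diag(S)))
  delta <- matrix(0, G, S, dimnames = list(og_ids, species))
  if (config$interaction_sd > 0) {
    z <- matrix(rnorm(G * S), S, G)
    delta <- t(config$interaction_sd * (L %*% z))
    delta <- delta - rowMeans(delta)      # sum-to-zero across species
    dimnames(delta) <- list(og_ids, species)
  }

  # samples
  nper <- config$samples_per_species_per_treatment
  meta <- do.call(rbind, lapply(seq_len(S), function(s) {
    n <- nper[s]
    data.frame(sample_id = sprintf("%s_%s%02d", species[s],
                                   rep(c("pbs", "alum"), each = n), c(seq_len(n), seq_len(n))),
               species_id = species[s],
               treatment = rep(c("PBS", "alum"), each = n),
               stringsAsFactors = FALSE)
  }))
  meta$treatment <- factor(meta$treatment, levels = c("PBS", "alum"))
  meta$fibrosis_score <- ifelse(meta$treatment == "alum",
                                pmin(3L, rpois(nrow(meta), 1.5)),
                                pmin(3L, rpois(nrow(meta), 0.2)))
  sf <- exp(rnorm(nrow(meta), 0, config$size_factor_log_sd))
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- meta$sample_id

  # per-species transcript matrices
  counts <- list()
  map_rows <- list()
  truth_tx <- list()
  for (s in seq_len(S)) {
    sp <- species[s]
    ms <- meta[meta$species_id == sp, ]
    x <- as.integer(ms$treatment == "alum")
    sfs <- sf[ms$sample_id]
    ncopy <- copies[, s]
    present <- which(ncopy > 0L)
    tx_og <- rep(present, ncopy[present])
    tx_ids <- unlist(lapply(present, function(g)
      sprintf("%s_t%d_%s", og_ids[g], seq_len(ncopy[g]), sp)), use.names = FALSE)
    # Dirichlet(1,...,1) weights splitting the orthogroup mean over copies
    gam <- rexp(length(tx_og))
    wsum <- vapply(split(gam, tx_og), sum, 0)
    w <- gam / wsum[as.character(tx_og)]
    og_mu <- exp(ln2 * (b[tx_og] + u[tx_og, s]))        # PBS mean, orthogroup level
    lfc <- beta[tx_og] + delta[tx_og, s]
    mu <- outer(w * og_mu, sfs) * exp(ln2 * outer(lfc, x))
    k <- matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
                nrow = nrow(mu),
                dimnames = list(tx_ids, ms$sample_id))
    counts[[sp]] <- validate_count_matrix(k, sp)
    map_rows[[sp]] <- data.frame(orthogroup_id = og_ids[tx_og], species_id = sp,
                                 transcript_id = tx_ids, stringsAsFactors = FALSE)
    truth_tx[[sp]] <- data.frame(transcript_id = tx_ids, species_id = sp,
                                 orthogroup_id = og_ids[tx_og],
                                 true_lfc = lfc, is_de = is_de[tx_og],
                                 stringsAsFactors = FALSE)
  }
  map <- as_orthogroup_map(do.call(rbind, map_rows), source = "simulated map")

  # random GO annotation over the simulated vocabulary
  vocab <- sprintf("GO:%07d", seq_len(config$n_go_terms))
  n_terms <- pmin(rpois(nrow(map), config$go_terms_per_transcript),
                  config$n_go_terms)
  go <- data.frame(
    transcript_id = rep(map$transcript_id, n_terms),
    species_id = rep(map$species_id, n_terms),
    go_term = vocab[unlist(lapply(n_terms, function(k)
      if (k > 0) sample.int(config$n_go_terms, min(k, config$n_go_terms)) else integer()),
      use.names = FALSE)],
    stringsAsFactors = FALSE)
  attr(go, "universe") <- map[, c("transcript_id", "species_id")]

  truth <- list(beta = setNames(beta, og_ids), delta = delta,
                is_de = setNames(is_de, og_ids),
                lambda_true = config$lambda_true,
                size_factors = sf, core = setNames(core, og_ids),
                copies = copies,
                transcripts = do.call(rbind, truth_tx))
  structure(list(counts = counts, metadata = meta, orthogroups = map,
                 go = go, tree = tree, truth = truth, config = config),
            class = "og_dataset")
}

#' Write a simulated dataset to disk in the pipeline's external formats
#'
#' One count TSV per species, metadata TSV, Orthogroups.tsv, GO TSV, newick
#' tree, and a JSON ground-truth sidecar.
#'
#' @param dataset an `og_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (sp in names(dataset$counts)) {
    p <- file.path(dir, paste0("counts_", sp, ".tsv"))
    write_count_matrix(dataset$counts[[sp]], p)
    paths[paste0("counts_", sp)] <- p
  }
  write_sample_metadata(dataset$metadata, paths["metadata"] <- file.path(dir, "metadata.tsv"))
  write_orthogroups(dataset$orthogroups, paths["orthogroups"] <- file.path(dir, "Orthogroups.tsv"),
                    species = names(dataset$counts))
  write_go_annotations(dataset$go, paths["go"] <- file.path(dir, "go_annotations.tsv"))
  write_species_tree(dataset$tree, paths["tree"] <- file.path(dir, "species_tree.nwk"))
  truth <- dataset$truth
  truth$delta <- as.data.frame(truth$delta)
  truth$copies <- as.data.frame(truth$copies)
  jsonlite::write_json(truth, paths["truth"] <- file.path(dir, "ground_truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(paths)
}
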