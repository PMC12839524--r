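balanced_meta <- function(n_species, n_per_cell,
                          species = sprintf("sp%02d", seq_len(n_species))) {
  data.frame(
    sample_id = sprintf("%s_%s%02d", rep(species, each = 2L * n_per_cell),
                        rep(rep(c("p", "a"), each = n_per_cell), n_species),
                        rep(seq_len(n_per_cell), 2L * n_species)),
    species_id = rep(species, each = 2L * n_per_cell),
    treatment = factor(rep(rep(c("PBS", "alum"), each = n_per_cell), n_species),
                       levels = c("PBS", "alum")),
    stringsAsFactors = FALSE)
}

test_that("two-way ANOVA matches the hand-partitioned 2x2x2 design", {
  # 2 species x 2 treatments x 2 replicates, cell means (0, 0, 0, 4):
  # grand mean 1; treatment SS = 8*(1)^2? -> compute by hand:
  # cells: sp1/PBS=0, sp1/alum=0, sp2/PBS=0, sp2/alum=4 (no within-cell noise)
  meta <- balanced_meta(2L, 2L)
  y <- ifelse(meta$species_id == "sp02" & meta$treatment == "alum", 4, 0)
  # hand partition: marginal treatment means 0 and 2 -> SS_t = 8
  # marginal species means 0 and 2 -> SS_s = 8; total SS = 8*(0-1)^2? :
  # y has six 0s and two 4s: SS_total = 6*1 + 2*9 = 24; interaction = 24-8-8 = 8
  row <- fit_og_anova(y, meta)
  expect_equal(row$eta2_treatment, 8 / 24, tolerance = 1e-12)
  expect_equal(row$eta2_species, 8 / 24, tolerance = 1e-12)
  expect_equal(row$eta2_interaction, 8 / 24, tolerance = 1e-12)
  expect_equal(row$eta2_residual, 0, tolerance = 1e-12)
  expect_equal(row$df_residual, 8L - 4L)

  # degenerate constant response is flagged
  const <- fit_og_anova(rep(3, nrow(meta)), meta)
  expect_equal(const$flag, "constant")
  expect_equal(const$eta2_treatment, 0)

  # a species missing one treatment makes the row rank-deficient
  bad <- meta[!(meta$species_id == "sp01" & meta$treatment == "alum"), ]
  expect_equal(fit_og_anova(rnorm(nrow(bad)), bad)$flag, "rank_deficient")
})

test_that("Type-II F statistics agree with car::Anova under imbalance", {
  skip_if_not_installed("car")
  set.seed(10)
  # proportional but unequal species sizes (balanced within species)
  meta <- rbind(balanced_meta(2L, 4L), balanced_meta(1L, 6L, species = "sp03"))
  y <- rnorm(nrow(meta), mean = 2 * (meta$treatment == "alum") +
               as.integer(factor(meta$species_id)))
  row <- fit_og_anova(y, meta)
  fit <- lm(y ~ treatment * species_id, data = transform(meta,
            treatment = factor(treatment, levels = c("PBS", "alum"))))
  ca <- car::Anova(fit, type = 2)
  expect_equal(row$F_treatment, ca["treatment", "F value"], tolerance = 1e-8)
  expect_equal(row$F_species, ca["species_id", "F value"], tolerance = 1e-8)
  expect_equal(row$F_interaction, ca["treatment:species_id", "F value"],
               tolerance = 1e-8)
  expect_equal(row$p_interaction, ca["treatment:species_id", "Pr(>F)"],
               tolerance = 1e-8)

  # effect + residual shares partition the total SS on proportional designs
  tot <- row$eta2_treatment + row$eta2_species + row$eta2_interaction +
    row$eta2_residual
  expect_equal(tot, 1, tolerance = 1e-10)

  # eta^2 invariant to affine rescaling of the response
  row2 <- fit_og_anova(10 + 3 * y, meta)
  expect_equal(row2$eta2_interaction, row$eta2_interaction, tolerance = 1e-10)
  expect_equal(row2$eta2_treatment, row$eta2_treatment, tolerance = 1e-10)
})

test_that("shared vs species-specific regimes move the eta^2 comparison", {
  # strong shared treatment effect, no interaction
  cfg_t <- simulation_config(n_species = 5L, n_orthogroups = 150L,
                             samples_per_species_per_treatment = 4L,
                             de_fraction = 1, de_lfc = 2,
                             interaction_sd = 0, seed = 31L)
  ds_t <- simulate_dataset(cfg_t)
  norm <- lapply(ds_t$counts, function(m)
    normalize_counts(m, compute_size_factors(m, pseudo_reference = TRUE)))
  og_t <- restrict_to_core(aggregate_orthogroups(norm, ds_t$orthogroups))
  an_t <- fit_all_og_anova(og_t, ds_t$metadata)
  s_t <- effect_size_summary(an_t)
  expect_gt(s_t$median_eta2_treatment, s_t$median_eta2_interaction)
  expect_gt(s_t$frac_treatment_above, 0.5)

  # interaction-dominated regime reverses the comparison
  cfg_i <- simulation_config(n_species = 5L, n_orthogroups = 150L,
                             samples_per_species_per_treatment = 4L,
                             de_fraction = 0, interaction_sd = 1.5,
                             seed = 32L)
  ds_i <- simulate_dataset(cfg_i)
  norm_i <- lapply(ds_i$counts, function(m)
    normalize_counts(m, compute_size_factors(m, pseudo_reference = TRUE)))
  og_i <- restrict_to_core(aggregate_orthogroups(norm_i, ds_i$orthogroups))
  s_i <- effect_size_summary(fit_all_og_anova(og_i, ds_i$metadata))
  expect_lt(s_i$frac_treatment_above, 0.5)
  expect_gt(s_i$median_eta2_interaction, s_i$median_eta2_treatment)

  # empty table summarizes to count zero
  empty <- effect_size_summary(an_t[an_t$flag == "none", ])
  expect_equal(empty$n, 0L)
})

test_that("pairwise Wald correlations are symmetric and well normalized", {
  de <- small_de()
  pc <- pairwise_wald_correlations(de)
  S <- length(unique(de$species_id))
  expect_equal(nrow(pc), S * (S - 1L) / 2L)
  expect_true(all(abs(pc$r) <= 1, na.rm = TRUE))

  # audit mode: a species against itself correlates exactly 1
  dup <- de[de$species_id == de$species_id[1L], ]
  dup2 <- dup; dup2$species_id <- "copy"
  self <- pairwise_wald_correlations(rbind(dup, dup2))
  expect_equal(self$r, 1, tolerance = 1e-12)

  # orthogroup order does not matter
  perm <- de[sample(nrow(de)), ]
  pc2 <- pairwise_wald_correlations(perm)
  expect_equal(pc2[order(pc2$species_a, pc2$species_b), "r"],
               pc[order(pc$species_a, pc$species_b), "r"], tolerance = 1e-12)

  # fewer than 3 shared orthogroups: flagged NA
  tiny <- de[de$unit_id %in% unique(de$unit_id)[1:2], ]
  pc3 <- pairwise_wald_correlations(tiny)
  expect_true(all(is.na(pc3$r)))
})

test_that("shared responses push the pairwise correlation distribution up", {
  cfg <- simulation_config(n_species = 5L, n_orthogroups = 250L,
                           samples_per_species_per_treatment = 5L,
                           de_fraction = 0.3, de_lfc = 2,
                           interaction_sd = 0.1, seed = 33L)
  de_shared <- run_species_de(simulate_dataset(cfg), "orthogroup")
  pc <- pairwise_wald_correlations(de_shared)
  expect_true(all(pc$r > 0))
  tt <- correlation_distribution_test(pc$r)
  expect_lt(tt$p, 0.01)
  expect_gt(tt$mean_r, 0)

  # no treatment signal anywhere: Wald vectors are pure noise and the
  # mean pairwise correlation sits at zero
  cfg0 <- simulation_config(n_species = 5L, n_orthogroups = 250L,
                            samples_per_species_per_treatment = 5L,
                            de_fraction = 0, interaction_sd = 0,
                            seed = 34L)
  pc0 <- pairwise_wald_correlations(run_species_de(simulate_dataset(cfg0),
                                                   "orthogroup"))
  se <- sd(pc0$r) / sqrt(nrow(pc0))
  expect_lt(abs(mean(pc0$r)), 4 * se + 0.02)

  # species-specific responses centered to sum to zero induce the expected
  # weak negative cross-species correlation (about -1/(S-1) before noise)
  cfg_i <- cfg0; cfg_i$interaction_sd <- 0.8; cfg_i$seed <- 35L
  pc_i <- pairwise_wald_correlations(run_species_de(simulate_dataset(cfg_i),
                                                    "orthogroup"))
  expect_lt(mean(pc_i$r), 0)
  expect_gt(mean(pc_i$r), -0.25)
})

test_that("the correlation-distribution t-test matches the closed form", {
  r <- c(0.1, 0.2, 0.3)
  out <- correlation_distribution_test(r)
  expect_equal(out$t, mean(r) / (sd(r) / sqrt(3)), tolerance = 1e-12)
  expect_equal(out$t, 3.4641016, tolerance = 1e-6)
  zero <- correlation_distribution_test(c(0, 0, 0))
  expect_equal(zero$t, 0)
  expect_equal(zero$p, 1)
  expect_error(correlation_distribution_test(0.5), "at least 2")
})

test_that("copy-number vs |lfc| correlation handles extremes", {
  # constructed perfect linear relation gives r = -1
  cn <- matrix(1:10, 10L, 1L, dimnames = list(paste0("OG", 1:10), "sp01"))
  de <- data.frame(unit_id = paste0("OG", 1:10), species_id = "sp01",
                   lfc = 5 - 0.3 * (1:10), stringsAsFactors = FALSE)
  out <- copy_number_lfc_correlation(de, cn)
  expect_equal(out$r, -1, tolerance = 1e-12)

  # constant copy number: NA with a reason
  cn1 <- matrix(2L, 10L, 1L, dimnames = list(paste0("OG", 1:10), "sp01"))
  out1 <- copy_number_lfc_correlation(de, cn1)
  expect_true(is.na(out1$r))
  expect_match(out1$reason, "constant")

  # the generator draws true fold changes independently of copy number;
  # estimated |lfc| picks up at most a weak (noise-driven) association
  ds <- small_dataset()
  de_og <- small_de()
  cn <- attr(small_og_matrix(), "copy_number")
  idx <- cbind(match(de_og$unit_id, rownames(cn)),
               match(de_og$species_id, colnames(cn)))
  truth_lfc <- abs(ds$truth$beta[de_og$unit_id] +
                     ds$truth$delta[cbind(de_og$unit_id, de_og$species_id)])
  expect_lt(abs(cor(truth_lfc, cn[idx])), 0.07)
  null_cor <- copy_number_lfc_correlation(de_og, cn)
  expect_lt(abs(null_cor$r), 0.2)
})
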