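#!/usr/bin/env Rscript
# Stage 4 — is the transcriptional response to alum shared or
# species-specific? Per-orthogroup Type-II ANOVA decomposes expression
# variance into treatment, species and treatment-by-species effects
# (eta^2); pairwise species correlations of orthogroup Wald statistics
# measure transcriptome-wide similarity; |lfc| is correlated against
# orthogroup copy number.

library(ogde)

ds <- load_dataset_dir("results/data")
norm <- lapply(ds$counts, function(m)
  normalize_counts(m, compute_size_factors(m, pseudo_reference = TRUE)))
og <- restrict_to_core(aggregate_orthogroups(norm, ds$orthogroups))
de_og <- read.delim("results/de_orthogroup.tsv")

an <- fit_all_og_anova(og, ds$metadata)
write.table(an, "results/effect_sizes.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
eff <- effect_size_summary(an, alpha_screen = 0.1)

pc <- pairwise_wald_correlations(de_og)
write.table(pc, "results/pairwise_wald_correlations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
tt <- correlation_distribution_test(pc$r)
cn <- copy_number_lfc_correlation(de_og, attr(og, "copy_number"))

jsonlite::write_json(list(effect_summary = eff, wald_correlation_test = tt,
                          copy_number_correlation = cn),
                     "results/cross_species_summary.json",
                     digits = NA, auto_unbox = TRUE)

cat(sprintf("residual df of the factorial fit: %d\n", an$df_residual[1]))
cat(sprintf("orthogroups with treatment eta^2 above interaction eta^2: %.1f%%\n",
            100 * eff$frac_treatment_above))
cat(sprintf("median eta^2: treatment %.4f, interaction %.4f\n",
            eff$median_eta2_treatment, eff$median_eta2_interaction))
cat(sprintf("pairwise Wald correlations: mean r = %.3f (t = %.2f, p = %.2g)\n",
            tt$mean_r, tt$t, tt$p))
cat(sprintf("|lfc| vs copy number: r = %.3f (p = %.2g)\n", cn$r, cn$p))
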