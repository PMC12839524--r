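#' Two-way Type-II ANOVA with eta-squared, one orthogroup
#'
#' OLS of summed normalized orthogroup expression on
#' `treatment + species + treatment:species` across all samples of all
#' species. Sums of squares are Type II, computed by model comparison
#' (treatment SS conditional on species and vice versa; interaction SS as
#' the final increment), which stays correct under mild imbalance. Effect
#' sizes are `eta^2 = SS_effect / SS_total`. With each species balanced
#' across treatments the cell frequencies are proportional, the three
#' effect SS plus the residual SS partition `SS_total` exactly, and the
#' residual df is `N - 2 S`.
#'
#' @param y numeric response across all samples (one orthogroup's summed
#'   normalized expression; `log1p` optionally applied first).
#' @param metadata data.frame with `treatment` (factor PBS/alum) and
#'   `species_id` aligned with `y`.
#' @param log1p_transform transform the response by `log1p` before fitting.
#' @return one-row data.frame with F statistics, dfs, p-values and eta^2
#'   for treatment, species and interaction, `eta2_residual`, `df_residual`
#'   and a `flag` ("ok", "constant", "rank_deficient").
#' @export
fit_og_anova <- function(y, metadata, log1p_transform = FALSE) {
  stopifnot(length(y) == nrow(metadata))
  if (log1p_transform) y <- log1p(y)
  treatment <- factor(metadata$treatment, levels = c("PBS", "alum"))
  species <- factor(metadata$species_id)
  S <- nlevels(species)
  n <- length(y)
  row <- data.frame(F_treatment = NA_real_, df1_treatment = 1L,
                    F_species = NA_real_, df1_species = S - 1L,
                    F_interaction = NA_real_, df1_interaction = S - 1L,
                    df_residual = n - 2L * S,
                    p_treatment = NA_real_, p_species = NA_real_,
                    p_interaction = NA_real_,
                    eta2_treatment = 0, eta2_species = 0, eta2_interaction = 0,
                    eta2_residual = NA_real_, flag = "ok",
                    stringsAsFactors = FALSE)
  ss_total <- sum((y - mean(y))^2)
  if (ss_total <= 0) { row$flag <- "constant"; row$eta2_residual <- 0; return(row) }
  # a species with a missing treatment makes the interaction inestimable
  if (any(table(species, treatment) == 0L)) { row$flag <- "rank_deficient"; return(row) }
  rss <- function(f) sum(residuals(lm(f))^2)
  rss_t <- rss(y ~ treatment)
  rss_s <- rss(y ~ species)
  rss_ts <- rss(y ~ treatment + species)
  rss_full <- rss(y ~ treatment * species)
  ss_treat <- rss_s - rss_ts          # treatment | species
  ss_spec <- rss_t - rss_ts           # species | treatment
  ss_int <- rss_ts - rss_full
  df_res <- n - 2L * S
  ms_res <- rss_full / df_res
  row$F_treatment <- (ss_treat / 1) / ms_res
  row$F_species <- (ss_spec / (S - 1)) / ms_res
  row$F_interaction <- (ss_int / (S - 1)) / ms_res
  row$p_treatment <- stats::pf(row$F_treatment, 1, df_res, lower.tail = FALSE)
  row$p_species <- stats::pf(row$F_species, S - 1, df_res, lower.tail = FALSE)
  row$p_interaction <- stats::pf(row$F_interaction, S - 1, df_res, lower.tail = FALSE)
  row$eta2_treatment <- ss_treat / ss_total
  row$eta2_species <- ss_spec / ss_total
  row$eta2_interaction <- ss_int / ss_total
  row$eta2_residual <- rss_full / ss_total
  row
}

#' Effect-size decomposition for every orthogroup
#'
#' @param og_matrix orthogroups x samples matrix (summed normalized
#'   expression, typically core-restricted).
#' @param metadata sample metadata covering every column.
#' @inheritParams fit_og_anova
#' @return data.frame, one row per orthogroup (`orthogroup_id` first).
#' @export
fit_all_og_anova <- function(og_matrix, metadata, log1p_transform = FALSE) {
  meta <- metadata[match(colnames(og_matrix), metadata$sample_id), ]
  if (anyNA(meta$sample_id)) stop("orthogroup matrix has samples missing from metadata")
  rows <- lapply(seq_len(nrow(og_matrix)), function(i)
    fit_og_anova(og_matrix[i, ], meta, log1p_transform))
  cbind(data.frame(orthogroup_id = rownames(og_matrix), stringsAsFactors = FALSE),
        do.call(rbind, rows))
}

#' Summary of treatment vs interaction effect sizes
#'
#' The per-orthogroup comparison behind the effect-size scatter: how many
#' orthogroups fall above the 1:1 line (treatment eta^2 > interaction
#' eta^2), and the fractions passing a raw-P screen for each effect.
#'
#' @param anova_table output of [fit_all_og_anova()].
#' @param alpha_screen raw p-value threshold of the screen (default 0.1).
#' @return list with `n`, `frac_treatment_above`, `frac_treatment_sig`,
#'   `frac_interaction_sig`, `median_eta2_treatment`,
#'   `median_eta2_interaction`.
#' @export
effect_size_summary <- function(anova_table, alpha_screen = 0.1) {
  ok <- anova_table[anova_table$flag == "ok", ]
  if (nrow(ok) == 0L)
    return(list(n = 0L, frac_treatment_above = NA_real_,
                frac_treatment_sig = NA_real_, frac_interaction_sig = NA_real_,
                median_eta2_treatment = NA_real_, median_eta2_interaction = NA_real_))
  list(n = nrow(ok),
       frac_treatment_above = mean(ok$eta2_treatment > ok$eta2_interaction),
       frac_treatment_sig = mean(ok$p_treatment < alpha_screen, na.rm = TRUE),
       frac_interaction_sig = mean(ok$p_interaction < alpha_screen, na.rm = TRUE),
       median_eta2_treatment = median(ok$eta2_treatment),
       median_eta2_interaction = median(ok$eta2_interaction))
}

#' Pairwise species correlations of a DE statistic
#'
#' Pearson correlation, for every pair of species, of the per-orthogroup
#' vectors of a statistic (Wald by default) over the orthogroups finite in
#' both members of the pair.
#'
#' @param de orthogroup-level table from [run_species_de()].
#' @param statistic column to correlate (`"wald"` or `"lfc"`).
#' @return data.frame `species_a`, `species_b`, `r`, `n_og`, `t`, `p`
#'   (one row per unordered pair; pairs with < 3 shared orthogroups get
#'   `NA` with `n_og` recorded).
#' @export
pairwise_wald_correlations <- function(de, statistic = "wald") {
  wide <- stat_matrix(de, statistic)
  species <- colnames(wide)
  pairs <- utils::combn(species, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    x <- wide[, pr[1L]]; y <- wide[, pr[2L]]
    keep <- is.finite(x) & is.finite(y)
    n <- sum(keep)
    if (n < 3L)
      return(data.frame(species_a = pr[1L], species_b = pr[2L], r = NA_real_,
                        n_og = n, t = NA_real_, p = NA_real_))
    ct <- cor.test(x[keep], y[keep], method = "pearson")
    data.frame(species_a = pr[1L], species_b = pr[2L],
               r = unname(ct$estimate), n_og = n,
               t = unname(ct$statistic), p = ct$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Orthogroup x species matrix of one DE statistic
#'
#' Reshapes a long per-species DE table into a units x species matrix of
#' one column (`wald` by default), `NA` where a unit was not tested in a
#' species.
#'
#' @param de table from [run_species_de()].
#' @param statistic column name to spread.
#' @return numeric matrix, rows sorted by unit id, columns by species.
#' @export
stat_matrix <- function(de, statistic = "wald") {
  ogs <- sort(unique(de$unit_id))
  species <- sort(unique(de$species_id))
  m <- matrix(NA_real_, length(ogs), length(species),
              dimnames = list(ogs, species))
  m[cbind(match(de$unit_id, ogs), match(de$species_id, species))] <- de[[statistic]]
  m
}

#' One-sample t-test of a correlation distribution against zero
#'
#' Treats the pairwise correlation coefficients as observations and tests
#' whether their mean differs from zero, exactly as done on the pairwise
#' Wald-statistic correlations. The pairs share species so they are not
#' independent; the test is reported as-is, with that caveat documented.
#'
#' @param r vector of pairwise correlation coefficients (NAs dropped).
#' @return list `mean_r`, `t`, `df`, `p`.
#' @export
correlation_distribution_test <- function(r) {
  r <- r[is.finite(r)]
  if (length(r) < 2L) stop("need at least 2 correlation values")
  if (sd(r) == 0) {
    if (all(r == 0)) return(list(mean_r = 0, t = 0, df = length(r) - 1L, p = 1))
    stop("zero variance of correlation values")
  }
  tt <- t.test(r, mu = 0)
  list(mean_r = mean(r), t = unname(tt$statistic),
       df = unname(tt$parameter), p = tt$p.value)
}

#' Correlation between |lfc| and orthogroup copy number
#'
#' Pools, over species, the per-species absolute orthogroup log2 fold
#' change paired with that species' transcript copy number in the
#' orthogroup, and reports the Pearson correlation with its t-test.
#'
#' @param de orthogroup-level DE table.
#' @param copy_number orthogroups x species integer matrix.
#' @return list `r`, `t`, `df`, `p`, `n`; `r = NA` (with `reason`) when the
#'   copy number is constant across the pooled pairs.
#' @export
copy_number_lfc_correlation <- function(de, copy_number) {
  idx <- cbind(match(de$unit_id, rownames(copy_number)),
               match(de$species_id, colnames(copy_number)))
  copies <- copy_number[idx]
  abs_lfc <- abs(de$lfc)
  keep <- is.finite(abs_lfc) & !is.na(copies)
  copies <- copies[keep]; abs_lfc <- abs_lfc[keep]
  if (length(copies) < 3L || sd(copies) == 0 || sd(abs_lfc) == 0)
    return(list(r = NA_real_, t = NA_real_, df = NA_integer_, p = NA_real_,
                n = length(copies), reason = "constant input"))
  ct <- cor.test(abs_lfc, copies, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n = length(copies))
}
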