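#' Fisher's exact GO enrichment for one species
#'
#' For each GO term, tests whether differentially expressed transcripts
#' (BH-adjusted p below `alpha_de` in that species' transcript-level DE
#' table) are enriched among the transcripts annotated with the term. The
#' universe is the annotated, tested transcripts of the species. The 2x2
#' table per term is (DE & term, DE & !term, !DE & term, !DE & !term); p is
#' the exact two-sided value (sum of tables with point probability <= the
#' observed one) and the odds ratio is the conditional MLE of the
#' noncentral hypergeometric, both via [stats::fisher.test] — the same
#' convention the analysis in the field uses.
#'
#' @param de transcript-level DE table for one species (or several; it is
#'   subset by `species_id`).
#' @param go long-form GO annotations (from [read_go_annotations()] or the
#'   generator), with a `universe` attribute listing all annotated
#'   transcripts.
#' @param species_id species to test.
#' @param alpha_de BH-adjusted significance threshold defining the DE set
#'   (default 0.1).
#' @return data.frame, one row per term present in the universe:
#'   `species_id`, `go_term`, `a`, `b`, `c`, `d`, `odds_ratio`
#'   (`Inf` coded as `Inf`), `p`.
#' @export
fisher_enrichment <- function(de, go, species_id, alpha_de = 0.1) {
  de <- de[de$species_id == species_id & !is.na(de$padj), ]
  uni_df <- attr(go, "universe")
  if (is.null(uni_df)) uni_df <- unique(go[, c("transcript_id", "species_id")])
  annotated <- uni_df$transcript_id[uni_df$species_id == species_id]
  universe <- intersect(de$unit_id, annotated)
  if (length(universe) == 0L) stop("empty universe for species ", species_id)
  de_set <- de$unit_id[de$padj < alpha_de]
  is_de <- universe %in% de_set
  go_sp <- go[go$species_id == species_id & go$transcript_id %in% universe, ]
  terms <- sort(unique(go_sp$go_term))
  members <- split(go_sp$transcript_id, go_sp$go_term)
  n_uni <- length(universe)
  n_de <- sum(is_de)
  rows <- lapply(terms, function(tm) {
    in_term <- universe %in% members[[tm]]
    a <- sum(is_de & in_term)
    b <- n_de - a
    c_ <- sum(in_term) - a
    d <- n_uni - a - b - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2L, byrow = TRUE))
    data.frame(species_id = species_id, go_term = tm,
               a = a, b = b, c = c_, d = d,
               odds_ratio = unname(ft$estimate), p = ft$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' GO enrichment for every species in a DE table
#'
#' @inheritParams fisher_enrichment
#' @return row-bound enrichment tables over all species present.
#' @export
run_go_enrichment <- function(de, go, alpha_de = 0.1) {
  species <- sort(unique(de$species_id))
  do.call(rbind, lapply(species, function(sp)
    fisher_enrichment(de, go, sp, alpha_de = alpha_de)))
}

#' Pairwise species correlations of GO-enrichment odds ratios
#'
#' Pearson correlation, per species pair, of the odds ratios over GO terms
#' tested in both species. Infinite odds ratios (empty-margin tables) are
#' excluded by default; `infinite_or = "haldane"` instead recomputes a
#' finite sample odds ratio with 0.5 added to every cell.
#'
#' @param enrichment table from [run_go_enrichment()].
#' @param infinite_or `"exclude"` or `"haldane"`.
#' @return data.frame as in [pairwise_wald_correlations()], over GO terms.
#' @export
pairwise_enrichment_correlations <- function(enrichment,
                                             infinite_or = c("exclude", "haldane")) {
  infinite_or <- match.arg(infinite_or)
  or <- enrichment$odds_ratio
  if (infinite_or == "haldane") {
    or <- with(enrichment, ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
  }
  fake_de <- data.frame(unit_id = enrichment$go_term,
                        species_id = enrichment$species_id,
                        wald = or, stringsAsFactors = FALSE)
  pairwise_wald_correlations(fake_de, statistic = "wald")
}
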