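# ogde — cross-species orthogroup differential expression and phylogenetic signal

`ogde` is an R package and analysis workflow for comparative
transcriptomics of a multi-species immune-challenge experiment: fishes
from across the ray-finned phylogeny injected intraperitoneally with
either PBS (control) or alum (an adjuvant that broadly induces peritoneal
fibrosis), head-kidney expression profiled by 3'TagSeq against each
species' own de novo reference transcriptome. Because references differ
between species, all cross-species comparison happens at the level of
**orthogroups** (transcript families descended from one ancestral gene).

The package implements, as tested reusable functions:

- **IO** for the pipeline's external formats: per-species count TSVs,
  OrthoFinder-style `Orthogroups.tsv`, sample metadata (species,
  treatment, ordinal fibrosis score), newick species trees, and
  per-transcript GO maps.
- **Normalization and aggregation** — within-species median-of-ratios
  size factors, `normalized(t,j) = k_tj / s_j`, summed over each
  orthogroup's member transcripts per sample, restricted to orthogroups
  with ≥ 1 copy in every species.
- **Differential expression** — per species, the NB GLM
  `k ~ treatment` with log link, offsets `log s_j`, variance
  `μ + αμ²`, Wald statistic `β̂/SE` (alum vs PBS in log2), BH-adjusted
  within species. A deliberately simplified DESeq2-style fit: no
  shrinkage, no filtering; it matches `DESeq2::nbinomWaldTest` to 1e-5
  at matched dispersions (tested).
- **Effect decomposition** — per orthogroup, Type-II two-way ANOVA
  `expression ~ treatment * species` with effect sizes
  `η² = SS_effect / SS_total`, separating a shared treatment response
  from species-by-treatment interaction.
- **Cross-species correlation** — Pearson correlations of per-species
  Wald-statistic vectors for all species pairs, a one-sample t-test of
  the correlation distribution against zero, and the |lfc|-vs-copy-number
  correlation.
- **GO enrichment** — per species, Fisher's exact test per GO term on
  the (DE × annotated) 2×2 table (conditional-MLE odds ratio), and
  pairwise species correlations of the odds ratios.
- **Congruence** — the top-30 DE orthogroups give each species a
  profile; hierarchical clustering (Euclidean, complete linkage) yields a
  dendrogram that is compared to the species tree via the rooted maximum
  agreement subtree; `Icong = MAST / E[MAST | random Yule trees]` with a
  randomization p-value.
- **Phylogenetic signal** — per orthogroup, the phylogenetic mixed model
  `y = μ + u + e`, `u ~ N(0, σ²_p C)`, `e ~ N(0, σ²_e I)` with `C` the
  tree correlation matrix, fitted by a conjugate Gibbs sampler;
  Pagel's `λ = σ²_p / (σ²_p + σ²_e)` with 95% credible intervals, DIC
  comparison against the non-phylogenetic reduced model, and an
  independent profile-ML cross-check (agrees with `phytools::phylosig`).
- **A synthetic data generator** reproducing the study's structure (14
  species, 158 balanced samples, NB 3'TagSeq-like counts, shared +
  phylogenetically covarying species-specific treatment effects, copy
  number variation, random GO assignment) with full ground truth, so the
  entire pipeline is testable without any sequencing data.

## Worked example

The `analysis/` directory is the workflow: numbered scripts that
simulate the dataset and run each stage, writing tables under
`results/`. Running them in order (about two minutes in total):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_normalize_aggregate.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_cross_species_effects.R
Rscript analysis/05_go_enrichment.R
Rscript analysis/06_tree_congruence.R
Rscript analysis/07_phylo_signal.R
```

Stage 4 prints, for the default simulation (seed 1):

```
residual df of the factorial fit: 130
orthogroups with treatment eta^2 above interaction eta^2: 5.6%
median eta^2: treatment 0.0034, interaction 0.1020
pairwise Wald correlations: mean r = 0.174 (t = 25.92, p = 1.6e-43)
|lfc| vs copy number: r = -0.060 (p = 5e-17)
```

Read: with 158 samples and 14 species the factorial fit has
158 − 28 = 130 residual df; for ~94% of orthogroups the
species-by-treatment interaction explains more variance than the shared
treatment effect (the response to alum is mostly species-specific), yet
transcriptome-wide the per-species response vectors are weakly but
consistently positively correlated, and high-copy orthogroups show
slightly smaller |lfc|. Stage 6 then reports

```
  MAST size: 5 (null expectation 5.717)
  Icong = 0.8746, p = 0.987
```

— the expression dendrogram is no more congruent with the species tree
than random trees are — and stage 7 summarizes the per-orthogroup
phylogenetic signal (median λ, wide credible intervals, and the fraction
of orthogroups where the reduced non-phylogenetic model has the lower
DIC, 75% here).

The same end-to-end run is available in one call:

```r
library(ogde)
res <- run_pipeline(pipeline_config(simulation = simulation_config(), seed = 1))
res$effect_summary
res$congruence
head(res$lambda)
```

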