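---
title: "Methods: cross-species orthogroup differential expression and phylogenetic signal"
author: "ogde"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species orthogroup differential expression and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the unit of analysis

`ogde` analyzes how a conserved inducible phenotype — peritoneal fibrosis
triggered by intraperitoneal alum injection — maps onto gene expression
across a phylogenetically diverse panel of ray-finned fishes. Each species
has its own de novo reference transcriptome, so expression cannot be
compared transcript-by-transcript. The unit of cross-species comparison is
the *orthogroup*: the set of transcripts across species descended from one
ancestral gene. Per-species transcript counts (3'TagSeq, which sequences
only 3' ends and is therefore length-independent) are normalized within
species, summed to orthogroup level, and every downstream statistic is
computed on those orthogroup profiles.

The pipeline answers five questions in order:

1. Which orthogroups respond to alum within each species (NB Wald
   differential expression)?
2. Is variance in orthogroup expression dominated by a shared treatment
   effect or by a treatment-by-species interaction (Type-II eta-squared
   decomposition)?
3. Are transcriptome-wide response profiles correlated between species
   (pairwise Pearson correlations of Wald-statistic vectors, and of GO
   enrichment odds ratios)?
4. Does the similarity structure of expression responses recapitulate the
   species tree (dendrogram vs tree congruence, Icong)?
5. Per orthogroup, how much of the cross-species variation in differential
   expression is explained by phylogeny (Pagel's lambda from a
   phylogenetic mixed model, with DIC model comparison)?

# Normalization and aggregation

Size factors are the median-of-ratios estimator: for sample $j$,
$s_j = \mathrm{median}_{t \in R}\, k_{tj} / (\prod_{j'} k_{tj'})^{1/n}$,
with the reference set $R$ the transcripts positive in every sample of
that species, rescaled so the factors have geometric mean 1. The median is
taken on the ratio scale; with an odd reference count this is identical to
the log-scale median some implementations use, and with an even count it
averages the two central ratios arithmetically rather than geometrically —
a difference well below any downstream resolution, fixed here so the
estimator matches its own definition exactly. When no transcript is
positive everywhere (common in sparse 3'TagSeq transcript matrices) the
`pseudo_reference = TRUE` fallback computes geometric means over positive
entries only; the pipeline uses the fallback, the default errors so the
condition is never silent.

Normalization is computed *per species*: species have different reference
transcriptomes, so a joint matrix would be meaningless. The burden of
cross-species comparability is carried by the downstream models, which
only ever compare statistics, not raw expression. The order of operations
is normalize, then sum to orthogroups. Orthogroups with at least one
transcript copy in every species ("core") are retained for all
cross-species analyses; transcript-level tests keep everything.

# Differential expression

Each unit (orthogroup or transcript) is fitted with the NB GLM
$k_j \sim \mathrm{NB}(s_j \mu_{x_j}, \alpha)$, log link, design
`~ treatment`, offset $\log s_j$, variance $\mu + \alpha\mu^2$. The
dispersion $\alpha$ is a per-unit method-of-moments estimate pooled across
treatment groups and floored at $10^{-8}$ — deliberately simpler than
DESeq2's machinery: no dispersion trend or shrinkage, no LFC shrinkage, no
independent filtering, no outlier replacement. The downstream inferences
consume signs and magnitudes of Wald statistics in aggregate, not
borderline calls on individual genes, so the refinements would add
dependence without changing any conclusion the pipeline draws. At matched
dispersions the fit agrees with DESeq2's `nbinomWaldTest` to $10^{-5}$
(tested), because for the saturated two-group design the IRLS score
equations decouple into one Newton solve per group, which is how the fit
is implemented. Wald $= \hat\beta/\mathrm{SE}$ with the expected-information
SE, $p$ from the standard normal, BH adjustment within each species table.
alum is always the numerator: positive lfc means up-regulation after
immune challenge.

Orthogroup-level input is the summed *normalized* matrix rounded
half-to-even, with size factors re-estimated on it — re-estimation (rather
than carrying transcript-level factors) mirrors what a count-based DE tool
does to whatever matrix it receives, and the re-estimated factors are near
1 because the input was already normalized.

Two significance conventions coexist deliberately: ANOVA screens use raw
`alpha_screen = 0.1`; DE sets feeding GO enrichment use BH-adjusted
`alpha_de = 0.1`.

# Effect-size decomposition

Per orthogroup, OLS of summed normalized expression on
`treatment + species + treatment:species` over all samples. Sums of
squares are Type II via model comparison (treatment conditional on
species, and vice versa), and $\eta^2 = SS_{\rm effect}/SS_{\rm total}$.
The response is left untransformed by default (a `log1p` option exists)
— the decomposition is reported as a variance share on the scale the
expression is displayed on, and $\eta^2$ is invariant to affine rescaling.

The simulated design keeps each species balanced between PBS and alum
(9 species at 6 fish per treatment, 5 at 5, 158 samples in all). Balanced
treatment allocation within species gives proportional cell frequencies,
so the three effect SS plus the residual partition the total exactly and
the residual df is $N - 2S = 158 - 28 = 130$. Under arbitrary imbalance
Type-II components need not sum to the total; the pipeline still reports
them, flagging rank-deficient rows (a species missing a treatment).

# Cross-species correlations

Pairwise species correlations are Pearson, over orthogroups with finite
statistics in both species; the distribution of the
$\binom{S}{2}$ coefficients is tested against zero with a one-sample
t-test. The pairs share species and are not independent, so the t-test is
anticonservative; it is reported in this form because it is the form the
comparison is conventionally made in, and the pipeline's conclusions rest
on the magnitude of the mean correlation, not the exact p-value.

One property of the generator matters when reading these correlations:
species-by-treatment deviations are centered to sum to zero across
species (so "shared" and "species-specific" variance components are
identifiable in the ANOVA sense). Centering induces a true cross-species
correlation of $-1/(S-1)$ among the deviations; with interaction-only
signal the pairwise Wald correlations therefore sit slightly below zero,
not at zero. A shared treatment effect pushes them positive, which is the
pattern of interest.

The |lfc|-vs-copy-number correlation pools per-species absolute log2 fold
changes against the species' transcript count in the orthogroup. Even
with fold changes drawn independently of copy number, a weak negative
estimated correlation is expected: an orthogroup sum over more transcript
copies is less overdispersed, so high-copy orthogroups have less
estimation noise inflating $|\hat{\mathrm{lfc}}|$. The tests assert
independence on the true fold changes and tolerate this artifact on the
estimates.

# GO enrichment

Within each species, the universe is the annotated, tested transcripts;
the DE set is BH padj < `alpha_de`. Per GO term, a 2x2 table (DE/term) is
tested with Fisher's exact test — two-sided p by summation of tables with
point probability at most the observed one, odds ratio as the conditional
MLE of the noncentral hypergeometric (the `fisher.test` conventions,
stated because two-sided exact tests have competing definitions; both are
verified against exhaustive hypergeometric enumeration in the tests).
Odds ratios are correlated across species over shared terms, on the raw
OR scale; infinite ORs are excluded by default, with a Haldane-corrected
sample-OR alternative. No GO-graph propagation is performed — term
membership is taken as annotated.

# Congruence between expression structure and the species tree

The top `k = 30` orthogroups by max |Wald| across species (ties broken by
orthogroup id) give each species a profile; species are clustered with
Euclidean distance and complete linkage — the defaults of the base R
heatmap clustering — and the dendrogram is compared to the species tree
with the rooted maximum agreement subtree (MAST): the largest leaf subset
on which both trees induce identical rooted topologies, computed by the
standard dynamic program over node pairs (verified against exhaustive
subset search). The congruence index Icong is the observed MAST size
divided by its Monte-Carlo expectation for pairs of independent random
Yule topologies on the same number of leaves; the p-value is the fraction
of null MAST sizes at least as large, with the +1 correction so
$p \in (0, 1]$. A leaf-permutation null is available as an alternative.
The ranking statistic, distance and linkage are all configuration keys,
since heatmap figures rarely state them.

# Phylogenetic signal: Pagel's lambda

Per orthogroup, the response $y$ is the vector of per-species Wald
statistics (lfc is a config alternative). The model is the
two-variance-component phylogenetic mixed model
$$y = \mu + u + e, \qquad u \sim N(0, \sigma^2_p C), \qquad
  e \sim N(0, \sigma^2_e I),$$
with $C$ the unit-diagonal tree correlation (shared root-to-MRCA path
lengths, scaled). Because $\mathrm{diag}(C) = 1$, the marginal covariance
is $(\sigma^2_p + \sigma^2_e)\,[\lambda C + (1-\lambda) I]$ with
$\lambda = \sigma^2_p/(\sigma^2_p + \sigma^2_e)$ — the variance-ratio and
covariance-transform readings of Pagel's lambda coincide, which is why
the Gibbs sampler parameterizes the first and the ML cross-check the
second.

All full conditionals are conjugate. The random effect is updated in the
eigenbasis of $C$, where its conditional is componentwise independent, so
one iteration costs $O(S)$ and thousands of orthogroups are advanced in
lock-step as matrix operations. Priors are inverse-gamma(0.001, 0.001) on
both variances (MCMCglmm-style weakly informative; prior sensitivity is a
test, not a hidden constant) and effectively flat normal on the
intercept. Desk-scale chains are 1,000 burn-in + 20,000 iterations
(thinned by 10) by default; the heavier published-style setting of 10,000
+ 600,000 is one `mcmc_settings()` call away. The batch runs in the
pipeline use 500 + 5,500 thinned by 5, which reproduces the longer-chain
summaries to within Monte-Carlo error on this model (it is a small, fully
conjugate sampler). DIC is Spiegelhalter's
$2\bar D - D(\bar\theta)$ on the marginalized Gaussian deviance; the
reduced model drops $u$. `delta_dic = dic_reduced - dic_full`, positive
favoring the phylogenetic model.

Numerical choices: eigenvalues are clipped at zero and a singular $C$ is
jittered by $10^{-8}$ with a warning; chains are checked with a
split-$\hat R$ on the lambda trace (flagged above 1.1); the ML profile is
maximized by golden-section on $[0,1]$ with the endpoints checked
explicitly, and a flat profile (star tree) is flagged unidentifiable
rather than returning an arbitrary interior value.

**What the estimators can and cannot do at S = 14.** With one observation
per species and 14 species, Pagel's lambda is weakly identified, and the
problem is scale-invariant, so no signal strength changes it. The ML
estimator is boundary-consistent but biased at interior truth (mean
$\hat\lambda \approx 0.06/0.34/0.86$ at $\lambda_{\rm true} = 0/0.5/1$
over replicate Yule trees — indistinguishable from
`phytools::phylosig`, which this package's ML agrees with to three
decimals); the posterior mean is pulled toward the interior
($\approx 0.22/0.42/0.86$). Credible intervals are wide (mean 95% range
$\approx 0.84$ on the synthetic study data) but honest: under
self-consistent conjugate simulation their coverage is 0.95 within
Monte-Carlo error (tested). Single-orthogroup lambda point estimates
should therefore be read through their intervals and the DIC comparison,
not as precise values — which is also why the per-orthogroup lower CI and
DIC preference, not the point estimate, are the quantities the analysis
leans on.

# The synthetic data generator

The generator emulates the study conditions so every stage is testable
with known ground truth: 14 species on a Yule tree; 158 samples (9
species with 6 fish per treatment, 5 with 5; each species balanced across
treatments); 2,000 orthogroups, 70% core; per-species copy numbers
zero-truncated geometric (mean 1.5) with 35% dropout for non-core
orthogroups; baseline log2 expression $N(\log_2 100, 1.5^2)$; per-species
baseline deviations (sd 0.5 log2); a shared treatment lfc for 10% of
orthogroups ($N(0, 1)$ in log2, or a fixed magnitude for calibration
runs); species-by-treatment deviations (sd 0.5 log2) drawn MVN with
covariance $\tau^2[\lambda C + (1-\lambda)I]$ at $\lambda = 0.5$ and
centered to sum to zero across species; NB counts with dispersion
$\alpha = 0.3$ (variance $\mu + \alpha\mu^2$, stated to avoid the r/p vs
$\mu/\alpha$ ambiguity); lognormal library size factors (sd 0.3, geometric
mean 1); orthogroup means split over transcript copies by symmetric
Dirichlet weights; GO terms assigned at random (200-term vocabulary,
Poisson mean 2 per transcript). One seed drives every draw, so a fixed
seed reproduces the dataset bit for bit.

Defaults were chosen once as representative of 3'TagSeq head-kidney data
at these sample sizes (moderate overdispersion, a minority of responsive
orthogroups, species-specific deviations comparable to the shared
response) and are not tuned per analysis. What the generator deliberately
does not emulate: unassigned transcripts (every simulated transcript maps
to an orthogroup, so the reported unassigned fractions are zero, whereas
real de novo assemblies leave 8–35% unassigned), 3' coverage bias,
correlated GO structure (random annotation means enrichment correlations
are a null — the GO machinery's positive-signal behavior is exercised by
constructed fixtures in the tests), assembly artifacts, and
between-species differences in annotation quality. Passing tests
therefore demonstrate the statistics are computed correctly and behave as
designed under the model's assumptions — not that the model captures
every feature of real multi-species count data.

# Problem sizes and reproducibility

The shipped analysis (`analysis/01_simulate.R` … `07_phylo_signal.R`) and
the acceptance script run the full 14-species, 158-sample, 2,000-orthogroup
dataset; the lambda stage fits the 400 orthogroups with the strongest DE
signal (the congruence and lambda analyses target differentially
expressed orthogroups, and 400 fits characterize the lambda distribution
to Monte-Carlo accuracy far finer than the between-orthogroup spread).
The test suite uses smaller replicates of the same structure. Every
stochastic step derives its stream from one user-visible seed; the
pipeline manifest records per-stage sub-seeds, thresholds and content
hashes of all outputs, and a re-run with the same config reproduces the
hashes exactly.
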