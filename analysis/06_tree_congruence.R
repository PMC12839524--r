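#!/usr/bin/env Rscript
# Stage 6 — does expression divergence track the phylogeny? The top 30
# differentially expressed orthogroups (max |Wald| across species) are
# clustered into a species dendrogram (Euclidean distance, complete
# linkage) and compared with the species tree via the rooted maximum
# agreement subtree, normalized by its random-tree expectation (Icong)
# with a randomization p-value.

library(ogde)

seed <- 1L
ds <- load_dataset_dir("results/data")
de_og <- read.delim("results/de_orthogroup.tsv")

top <- top_de_orthogroups(de_og, k = 30L)
dend <- cluster_species_dendrogram(de_og, top)
write_species_tree(dend, "results/expression_dendrogram.nwk")
res <- icong_test(dend, ds$tree, n_null = 1000L, seed = seed)
jsonlite::write_json(unclass(res), "results/congruence.json",
                     digits = NA, auto_unbox = TRUE)

cat("top orthogroups:", paste(head(top, 5), collapse = ", "), "...\n")
print(res)
cat("an Icong near 1 with a large p means the expression dendrogram is no
more congruent with the species tree than random trees are\n")
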