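# shared fixtures, built in code at test time

# small but complete simulated dataset reused across files
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_species = 5L, n_orthogroups = 120L,
                               samples_per_species_per_treatment = 4L,
                               seed = 42L)
      cache <<- simulate_dataset(cfg)
    }
    cache
  }
})

# orthogroup matrix (core-restricted) of the small dataset
small_og_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- small_dataset()
      norm <- lapply(ds$counts, function(m)
        normalize_counts(m, compute_size_factors(m, pseudo_reference = TRUE)))
      cache <<- restrict_to_core(aggregate_orthogroups(norm, ds$orthogroups))
    }
    cache
  }
})

small_de <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_species_de(small_dataset(), "orthogroup",
                               og_matrix = small_og_matrix())
    }
    cache
  }
})

# random rooted binary tree with distinct labels, for tree tests
random_labeled_tree <- function(n, labels = sprintf("t%02d", seq_len(n))) {
  tr <- ape::rphylo(n, birth = 1, death = 0)
  tr$tip.label <- sample(labels)
  tr
}

# node leaf-sets of a rooted tree as bitmasks over `labels`
node_bitmasks <- function(tree, labels) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  mask <- integer(nnode)
  mask[seq_len(n)] <- bitwShiftL(1L, match(tree$tip.label, labels) - 1L)
  for (i in rev(seq_len(nrow(tree$edge))))
    mask[tree$edge[i, 1L]] <- bitwOr(mask[tree$edge[i, 1L]], mask[tree$edge[i, 2L]])
  # reorder so parents accumulate fully regardless of edge order
  repeat {
    prev <- mask
    for (i in seq_len(nrow(tree$edge)))
      mask[tree$edge[i, 1L]] <- bitwOr(mask[tree$edge[i, 1L]], mask[tree$edge[i, 2L]])
    if (identical(prev, mask)) break
  }
  mask
}

# exhaustive rooted MAST: check every leaf subset for identical restricted
# cluster hierarchies (independent of the dynamic program)
brute_mast <- function(t1, t2) {
  labels <- sort(t1$tip.label)
  n <- length(labels)
  m1 <- node_bitmasks(t1, labels)
  m2 <- node_bitmasks(t2, labels)
  restricted <- function(masks, sub) {
    r <- bitwAnd(masks, sub)
    sort(unique(r[r != 0L]))
  }
  best <- 1L
  for (sub in seq_len(bitwShiftL(1L, n) - 1L)) {
    size <- sum(bitwAnd(sub, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (size <= best) next
    if (identical(restricted(m1, sub), restricted(m2, sub))) best <- size
  }
  best
}

expect_setequal_rows <- function(a, b) {
  expect_equal(a[order(a$orthogroup_id), ], b[order(b$orthogroup_id), ],
               ignore_attr = TRUE)
}
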