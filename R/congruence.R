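#' Top differentially expressed orthogroups
#'
#' Ranks orthogroups by the maximum |Wald statistic| across species (ties
#' broken by orthogroup id, so the ranking is deterministic) and returns
#' the top `k`.
#'
#' @param de orthogroup-level DE table.
#' @param k how many orthogroups (default 30).
#' @param statistic ranking column (absolute value is taken).
#' @return character vector of `k` orthogroup ids, strongest first.
#' @export
top_de_orthogroups <- function(de, k = 30L, statistic = "wald") {
  m <- stat_matrix(de, statistic)
  score <- apply(abs(m), 1L, max, na.rm = TRUE)
  score[!is.finite(score)] <- -Inf
  if (k > length(score)) stop("k = ", k, " exceeds the ", length(score),
                              " available orthogroups")
  ord <- order(-score, names(score))
  names(score)[ord][seq_len(k)]
}

#' Species dendrogram from expression statistics
#'
#' Hierarchical clustering of species over the selected orthogroups'
#' per-species statistics: Euclidean distance, complete linkage (the
#' defaults of the base R heatmap clustering). Rows are ordered by species
#' label first, so ties merge deterministically.
#'
#' @param de orthogroup-level DE table.
#' @param orthogroups which orthogroups to use (e.g. from
#'   [top_de_orthogroups()]).
#' @param statistic column clustered (default `"wald"`).
#' @return a rooted binary [ape::phylo] dendrogram over the species, with
#'   merge heights as branch lengths; attribute `hclust` keeps the raw
#'   clustering.
#' @export
cluster_species_dendrogram <- function(de, orthogroups, statistic = "wald") {
  m <- stat_matrix(de, statistic)[orthogroups, , drop = FALSE]
  prof <- t(m)[sort(rownames(t(m))), , drop = FALSE]
  prof[!is.finite(prof)] <- 0
  hc <- hclust(dist(prof, method = "euclidean"), method = "complete")
  tree <- ape::as.phylo(hc)
  attr(tree, "hclust") <- hc
  tree
}

# internal: children list and leaf-label table of a rooted binary phylo
tree_structure <- function(tree) {
  n <- length(tree$tip.label)
  nnode <- n + tree$Nnode
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1L]]] <- c(children[[tree$edge[i, 1L]]], tree$edge[i, 2L])
  if (any(vapply(children[(n + 1L):nnode], length, 0L) != 2L))
    stop("tree must be binary")
  # postorder over nodes
  post <- integer(0)
  stack <- n + 1L; visited <- logical(nnode)
  order_stack <- integer(0)
  stack <- c(n + 1L)
  while (length(stack)) {
    nd <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_stack <- c(order_stack, nd)
    stack <- c(stack, children[[nd]])
  }
  post <- rev(order_stack)
  list(n = n, nnode = nnode, children = children, post = post,
       labels = tree$tip.label)
}

#' Rooted maximum agreement subtree size
#'
#' Size of the largest leaf subset on which two rooted binary trees over
#' the same labels induce identical rooted topologies, by the standard
#' dynamic program over node pairs: for internal nodes, the best of
#' matching the two child pairs either way or dropping one child on either
#' side; for leaves, label membership.
#'
#' @param t1,t2 rooted binary [ape::phylo] trees with identical leaf sets.
#' @return integer MAST size in `[1, S]`.
#' @export
rooted_mast_size <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  s1 <- tree_structure(t1)
  s2 <- tree_structure(t2)
  # leaf id in t2 for each label of t1
  lab2 <- match(s1$labels, s2$labels)
  M <- matrix(0L, s1$nnode, s2$nnode)
  # leaves-below sets for membership at leaf-vs-internal pairs are implied
  # by the recursion itself, so a uniform postorder fill suffices
  for (u in s1$post) {
    uc <- s1$children[[u]]
    for (v in s2$post) {
      vc <- s2$children[[v]]
      if (is.null(uc) && is.null(vc)) {
        M[u, v] <- as.integer(lab2[u] == v)
      } else if (is.null(uc)) {
        M[u, v] <- max(M[u, vc[1L]], M[u, vc[2L]])
      } else if (is.null(vc)) {
        M[u, v] <- max(M[uc[1L], v], M[uc[2L], v])
      } else {
        M[u, v] <- max(M[uc[1L], vc[1L]] + M[uc[2L], vc[2L]],
                       M[uc[1L], vc[2L]] + M[uc[2L], vc[1L]],
                       M[uc[1L], v], M[uc[2L], v], M[u, vc[1L]], M[u, vc[2L]])
      }
    }
  }
  M[s1$n + 1L, s2$n + 1L]
}

#' Icong congruence test between a dendrogram and a species tree
#'
#' Congruence index: observed rooted MAST size divided by its expectation
#' for pairs of independent random (Yule) binary trees over the same number
#' of leaves, with a randomization p-value (fraction of null MAST sizes at
#' least as large as observed, with the +1 correction so p is in (0, 1]).
#' `icong > 1` means the two trees agree more than random trees do.
#'
#' @param dendrogram,species_tree rooted binary trees over the same species.
#' @param n_null number of null tree pairs (>= 100 recommended; fewer warns).
#' @param seed integer seed for the null draws.
#' @param null `"yule"` (independent random topologies) or
#'   `"permutation"` (leaf labels of both observed topologies shuffled).
#' @return list of class `icong_result`: `mast_size`, `expected_mast`,
#'   `icong`, `p`, `n_null`, `n_species`.
#' @export
icong_test <- function(dendrogram, species_tree, n_null = 1000L, seed = 1L,
                       null = c("yule", "permutation")) {
  null <- match.arg(null)
  if (!setequal(dendrogram$tip.label, species_tree$tip.label))
    stop("trees must share the same leaf set")
  S <- length(species_tree$tip.label)
  if (S < 4L) stop("need at least 4 shared leaves")
  if (n_null < 100L) warning("n_null < 100 gives a coarse null distribution")
  obs <- rooted_mast_size(dendrogram, species_tree)
  set.seed(seed)
  labs <- species_tree$tip.label
  null_mast <- vapply(seq_len(n_null), function(i) {
    if (null == "yule") {
      a <- ape::rphylo(S, birth = 1, death = 0)
      b <- ape::rphylo(S, birth = 1, death = 0)
      a$tip.label <- labs
      b$tip.label <- sample(labs)
    } else {
      a <- dendrogram; a$tip.label <- sample(labs)
      b <- species_tree; b$tip.label <- sample(labs)
    }
    rooted_mast_size(a, b)
  }, 0L)
  structure(list(mast_size = obs, expected_mast = mean(null_mast),
                 icong = obs / mean(null_mast),
                 p = (1 + sum(null_mast >= obs)) / (n_null + 1),
                 n_null = n_null, n_species = S),
            class = "icong_result")
}

#' @export
print.icong_result <- function(x, ...) {
  cat(sprintf("Icong congruence test (%d species, %d null tree pairs)\n",
              x$n_species, x$n_null))
  cat(sprintf("  MAST size: %d (null expectation %.3f)\n", x$mast_size, x$expected_mast))
  cat(sprintf("  Icong = %.4f, p = %.4g\n", x$icong, x$p))
  invisible(x)
}
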