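# brute-force MRCA shared-depth traversal, independent of ape::vcv
brute_covariance <- function(tree) {
  S <- length(tree$tip.label)
  nnode <- S + tree$Nnode
  parent <- integer(nnode); depth <- numeric(nnode)
  for (i in seq_len(nrow(tree$edge))) parent[tree$edge[i, 2L]] <- tree$edge[i, 1L]
  root <- S + 1L
  path <- function(tip) {
    nodes <- tip; while (nodes[length(nodes)] != root)
      nodes <- c(nodes, parent[nodes[length(nodes)]])
    nodes
  }
  elen <- setNames(tree$edge.length, tree$edge[, 2L])
  depth_of <- function(node) {
    nodes <- path(node)
    sum(elen[as.character(nodes[-length(nodes)])])
  }
  sig <- matrix(0, S, S, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(S)) for (j in seq_len(S)) {
    common <- intersect(path(i), path(j))
    # the MRCA is the first shared node along either path
    mrca <- path(i)[min(which(path(i) %in% common))]
    sig[i, j] <- depth_of(mrca)
  }
  sig
}

test_that("tree covariance equals shared root-to-MRCA path lengths", {
  # star tree: no shared history, C = I
  star <- ape::read.tree(text = "(A:1,B:1,C:1,D:1);")
  expect_equal(tree_to_covariance(star)$C, diag(4),
               ignore_attr = TRUE)

  # cherry at depth 1 splitting at 0.5 shares correlation 0.5
  cherry <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  C <- tree_to_covariance(cherry)$C
  expect_equal(C["A", "B"], 0.5, tolerance = 1e-12)
  expect_equal(C["A", "C"], 0, tolerance = 1e-12)

  # random trees match the brute-force traversal
  set.seed(17)
  for (i in 1:10) {
    tr <- random_labeled_tree(7)
    sig <- tree_to_covariance(tr)$sigma
    expect_equal(sig[tr$tip.label, tr$tip.label],
                 brute_covariance(tr), tolerance = 1e-10)
  }

  # zero root-to-leaf path is rejected
  degen <- ape::read.tree(text = "((A:0,B:0):0,C:1);")
  expect_error(tree_to_covariance(degen), "zero-length")
})

test_that("the ML profile flags star trees and recovers lambda on a grid", {
  set.seed(18)
  # star tree: C = I makes the profile flat in lambda
  flat <- fit_lambda_ml(rnorm(8), C = diag(8))
  expect_true(flat$boundary_flag)

  tr <- simulate_species_tree(14, seed = 18)
  eg <- decompose_C(tree_to_covariance(tr)$C)
  C <- tree_to_covariance(tr)$C
  means <- sapply(c(0, 0.5, 1), function(lt) {
    Cl <- lt * C + (1 - lt) * diag(14)
    Ll <- t(chol(Cl + 1e-12 * diag(14)))
    mean(replicate(120, {
      y <- drop(Ll %*% rnorm(14)) * 3
      fit_lambda_ml(y, eigen_C = eg)$lambda
    }))
  })
  # with 14 taxa the ML of lambda is boundary-consistent but biased at
  # interior values; assert the behavior the estimator actually guarantees
  expect_lt(means[1L], 0.15)
  expect_gt(means[3L], 0.75)
  expect_true(means[1L] < means[2L] && means[2L] < means[3L])
})

test_that("lambda estimates are invariant to shifting and scaling y", {
  set.seed(19)
  tr <- simulate_species_tree(10, seed = 19)
  C <- tree_to_covariance(tr)$C
  eg <- decompose_C(C)
  y <- drop(t(chol(C)) %*% rnorm(10))
  st <- mcmc_settings(burn_in = 300L, n_iter = 3300L, thin = 3L, seed = 7L)
  base_ml <- fit_lambda_ml(y, eigen_C = eg)$lambda
  expect_equal(fit_lambda_ml(5 + 2 * y, eigen_C = eg)$lambda, base_ml,
               tolerance = 1e-5)
  # the fixed inverse-gamma prior breaks exact scale equivariance, so the
  # Gibbs posterior mean matches only up to prior and Monte-Carlo error
  g1 <- fit_lambda_gibbs(y, settings = st, eigen_C = eg)
  g2 <- fit_lambda_gibbs(5 + 2 * y, settings = st, eigen_C = eg)
  expect_equal(g1$lambda, g2$lambda, tolerance = 0.08)
})

test_that("Gibbs chains are deterministic and diagnosable", {
  set.seed(20)
  tr <- simulate_species_tree(8, seed = 20)
  C <- tree_to_covariance(tr)$C
  y <- rnorm(8)
  st <- mcmc_settings(burn_in = 200L, n_iter = 1200L, thin = 2L, seed = 5L)
  a <- fit_lambda_gibbs(y, C, st)
  b <- fit_lambda_gibbs(y, C, st)
  expect_identical(a$samples, b$samples)
  expect_identical(a$dic, b$dic)
  expect_true(is.finite(a$rhat))
  # a singular correlation matrix is jittered with a warning
  Cs <- matrix(1, 4, 4)
  expect_warning(decompose_C(Cs), "singular")
})

test_that("lambda posteriors separate Brownian from independent responses", {
  set.seed(22)
  tr <- simulate_species_tree(14, seed = 22)
  C <- tree_to_covariance(tr)$C
  L <- t(chol(C))
  st <- mcmc_settings(burn_in = 300L, n_iter = 3300L, thin = 3L, seed = 9L)
  G <- 40L
  Yb <- t(L %*% matrix(rnorm(14 * G), 14, G)) * 4
  Yi <- matrix(rnorm(G * 14), G, 14) * 4
  rownames(Yb) <- paste0("b", seq_len(G)); rownames(Yi) <- paste0("i", seq_len(G))
  colnames(Yb) <- colnames(Yi) <- colnames(C)
  tb <- fit_lambda_table(Yb, C, st)
  ti <- fit_lambda_table(Yi, C, st)
  expect_gt(median(tb$lambda), 0.5)
  expect_lt(median(ti$lambda), median(tb$lambda))
  # DIC prefers the phylogenetic model under strong signal,
  # the reduced model under pure noise, in the majority of orthogroups
  expect_gt(mean(tb$delta_dic > 0), 0.5)
  expect_gt(mean(ti$delta_dic < 0), 0.5)
})

test_that("signal classes follow the thresholds with lower-bin boundaries", {
  expect_equal(as.character(classify_signal(c(0.01, 0.05, 0.051, 0.2, 0.3,
                                              0.4, 0.41, 1.0))),
               c("negligible", "negligible", "weak", "weak", "moderate",
                 "moderate", "strong", "strong"))
  expect_error(classify_signal(1.5))
})

test_that("model comparison reports the DIC difference with sane signs", {
  full <- list(dic = 100)
  red <- list(dic = 108)
  expect_equal(compare_models(full, red), 8)
  expect_warning(na <- compare_models(list(dic = NaN), red), "non-finite")
  expect_true(is.na(na))
  # near-identical models differ only by Monte-Carlo error
  set.seed(23)
  y <- rnorm(10)
  st <- mcmc_settings(burn_in = 500L, n_iter = 10500L, thin = 5L, seed = 11L)
  red1 <- fit_reduced_gibbs(y, st)
  st2 <- st; st2$seed <- 99L
  red2 <- fit_reduced_gibbs(y, st2)
  expect_lt(abs(red1$dic - red2$dic), 1)
})

test_that("the lambda posterior is prior-driven when C is the identity", {
  # unidentifiable case: with C = I the likelihood carries no information
  # about the split, so the posterior matches the one obtained on permuted
  # data rather than concentrating anywhere
  set.seed(24)
  y <- rnorm(12, sd = 2)
  st <- mcmc_settings(burn_in = 500L, n_iter = 5500L, thin = 5L, seed = 13L)
  f1 <- suppressWarnings(fit_lambda_gibbs(y, diag(12) + 0, st))
  st2 <- st; st2$seed <- 14L
  f2 <- suppressWarnings(fit_lambda_gibbs(sample(y), diag(12) + 0, st2))
  expect_lt(abs(f1$lambda - f2$lambda), 0.25)
  expect_gt(f1$ci95[2L] - f1$ci95[1L], 0.3)   # wide: nothing learned
})

test_that("the ML lambda profile agrees with phytools::phylosig", {
  skip_if_not_installed("phytools")
  set.seed(62)
  tr <- simulate_species_tree(12, seed = 62)
  C <- tree_to_covariance(tr)$C
  eg <- decompose_C(C)
  for (i in 1:5) {
    lt <- runif(1)
    Cl <- lt * C + (1 - lt) * diag(12)
    y <- setNames(drop(t(chol(Cl + 1e-12 * diag(12))) %*% rnorm(12)),
                  colnames(C))
    mine <- fit_lambda_ml(y, eigen_C = eg)$lambda
    ref <- suppressWarnings(phytools::phylosig(tr, y, method = "lambda"))
    # phylosig optimizes lambda over a slightly different feasible interval;
    # compare after clamping its estimate to [0, 1]
    expect_equal(mine, min(1, max(0, ref$lambda)), tolerance = 0.02)
  }
})
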