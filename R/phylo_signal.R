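#' Phylogenetic covariance and correlation from a species tree
#'
#' `Sigma[i, j]` is the shared root-to-MRCA path length of species i and j
#' (the Brownian-motion covariance implied by the tree); `C` is its
#' unit-diagonal correlation form, the matrix whose off-diagonal Pagel's
#' lambda rescales.
#'
#' @param tree rooted [ape::phylo] with branch lengths.
#' @return list `sigma` (covariance), `C` (correlation), both S x S with
#'   species dimnames.
#' @export
tree_to_covariance <- function(tree) {
  sigma <- ape::vcv.phylo(tree)
  if (any(diag(sigma) <= 0))
    stop("zero-length root-to-leaf path for species ",
         rownames(sigma)[diag(sigma) <= 0][1L])
  C <- stats::cov2cor(sigma)
  list(sigma = sigma, C = C)
}

# internal shorthand used by the generator
tree_correlation <- function(tree) tree_to_covariance(tree)$C

#' MCMC settings for the lambda mixed model
#'
#' `n_iter` counts total Gibbs iterations including `burn_in`; retained
#' samples are the post-burn-in iterations at spacing `thin`. Both
#' variance components get inverse-gamma(shape, rate) priors
#' (weakly-informative 0.001/0.001 by default); the intercept gets a
#' `N(0, prior_mean_var)` prior, effectively flat by default.
#'
#' @param burn_in,n_iter,thin chain lengths (defaults are the package's
#'   desk-scale choice; 10000 / 600000 reproduce the heavier published
#'   setting).
#' @param seed integer seed.
#' @param prior_shape,prior_rate inverse-gamma prior parameters shared by
#'   both variances.
#' @param prior_mean_var prior variance of the intercept.
#' @return named list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(burn_in = 1000L, n_iter = 21000L, thin = 10L,
                          seed = 1L, prior_shape = 0.001, prior_rate = 0.001,
                          prior_mean_var = 1e8) {
  stopifnot(n_iter > burn_in, burn_in >= 0L, thin >= 1L,
            prior_shape > 0, prior_rate > 0, prior_mean_var > 0)
  structure(as.list(environment()), class = "mcmc_settings")
}

# eigen-decompose a correlation matrix once, with jitter if near-singular
decompose_C <- function(C, jitter = 1e-8) {
  eg <- eigen(C, symmetric = TRUE)
  if (min(eg$values) < 1e-10) {
    warning("phylogenetic correlation matrix is numerically singular; ",
            "adding 1e-8 jitter to the diagonal")
    eg <- eigen(C + jitter * diag(nrow(C)), symmetric = TRUE)
  }
  eg
}

gauss_deviance <- function(ystar, w, mu, d) {
  r <- ystar - mu * w
  sum(log(2 * pi * d)) + sum(r^2 / d)
}

# Vectorized Gibbs engine for the two-variance-component model, run in the
# eigenbasis of C where all full conditionals are componentwise. Y is
# G x S (one row per unit); all G chains advance in lockstep so each
# iteration is a handful of S x G matrix operations.
gibbs_lambda_engine <- function(Y, eigen_C, settings) {
  G <- nrow(Y); S <- ncol(Y)
  Q <- eigen_C$vectors
  lam <- pmax(eigen_C$values, 0)
  pos <- lam > 1e-12
  npos <- sum(pos)
  Ystar <- crossprod(Q, t(Y))                 # S x G
  w <- drop(crossprod(Q, rep(1, S)))
  a0 <- settings$prior_shape; b0 <- settings$prior_rate
  v0 <- settings$prior_mean_var
  set.seed(settings$seed)
  keep_at <- seq(settings$burn_in + 1L, settings$n_iter, by = settings$thin)
  n_keep <- length(keep_at)
  lambda_draws <- matrix(NA_real_, n_keep, G)
  s2p_draws <- matrix(NA_real_, n_keep, G)
  s2e_draws <- matrix(NA_real_, n_keep, G)
  mu_draws <- matrix(NA_real_, n_keep, G)
  dev_draws <- matrix(NA_real_, n_keep, G)
  mu <- rowMeans(Y)
  s2e <- pmax(apply(Y, 1L, var) / 2, 1e-6)
  s2p <- s2e
  U <- matrix(0, S, G)
  inv_lam <- ifelse(pos, 1 / lam, 0)
  log2pi <- log(2 * pi)
  ki <- 1L
  for (it in seq_len(settings$n_iter)) {
    # u* | . (rows with lam == 0 stay exactly 0)
    prec <- outer(rep(1, S), 1 / s2e) + outer(inv_lam, 1 / s2p)
    meanU <- sweep(Ystar - outer(w, mu), 2L, s2e, `/`) / prec
    U <- meanU + matrix(rnorm(S * G), S, G) / sqrt(prec)
    if (npos < S) U[!pos, ] <- 0
    # mu | .
    prec_mu <- S / s2e + 1 / v0
    mean_mu <- colSums(w * (Ystar - U)) / s2e / prec_mu
    mu <- rnorm(G, mean_mu, sqrt(1 / prec_mu))
    # variances | .
    ssu <- colSums(U[pos, , drop = FALSE]^2 * inv_lam[pos])
    s2p <- 1 / rgamma(G, a0 + npos / 2, b0 + ssu / 2)
    R <- Ystar - outer(w, mu) - U
    s2e <- 1 / rgamma(G, a0 + S / 2, b0 + colSums(R^2) / 2)
    if (ki <= n_keep && it == keep_at[ki]) {
      lambda_draws[ki, ] <- s2p / (s2p + s2e)
      s2p_draws[ki, ] <- s2p; s2e_draws[ki, ] <- s2e; mu_draws[ki, ] <- mu
      D <- outer(lam, s2p) + outer(rep(1, S), s2e)
      Rm <- Ystar - outer(w, mu)
      dev_draws[ki, ] <- colSums(log(2 * pi * D)) + colSums(Rm^2 / D)
      ki <- ki + 1L
    }
  }
  # DIC at posterior means
  mu_bar <- colMeans(mu_draws); s2p_bar <- colMeans(s2p_draws)
  s2e_bar <- colMeans(s2e_draws)
  Dbar <- colMeans(dev_draws)
  Dhat <- vapply(seq_len(G), function(g)
    gauss_deviance(Ystar[, g], w, mu_bar[g], s2p_bar[g] * lam + s2e_bar[g]), 0)
  list(lambda_mean = colMeans(lambda_draws),
       lambda_median = apply(lambda_draws, 2L, median),
       ci_lo = apply(lambda_draws, 2L, quantile, 0.025),
       ci_hi = apply(lambda_draws, 2L, quantile, 0.975),
       posterior_var = s2p_bar, residual_var = s2e_bar,
       dic = 2 * Dbar - Dhat,
       rhat = apply(lambda_draws, 2L, split_rhat),
       n_samples = n_keep,
       lambda_draws = lambda_draws, s2p_draws = s2p_draws,
       s2e_draws = s2e_draws, mu_draws = mu_draws)
}

#' Gibbs sampler for the two-variance-component phylogenetic mixed model
#'
#' Model: `y = mu + u + e`, `u ~ N(0, sigma2_p * C)`, `e ~ N(0, sigma2_e I)`
#' with `C` the unit-diagonal tree correlation, so the marginal covariance
#' is `(sigma2_p + sigma2_e) * (lambda C + (1 - lambda) I)` with Pagel's
#' `lambda = sigma2_p / (sigma2_p + sigma2_e)`. All full conditionals are
#' conjugate; the random effect is updated in the eigenbasis of `C`, where
#' its conditional is componentwise independent, so every iteration is
#' O(S). DIC is Spiegelhalter's `2 * mean(D) - D(posterior means)` with the
#' deviance of the marginalized Gaussian likelihood.
#'
#' @param y per-species response for one orthogroup (typically the Wald
#'   statistic of its differential expression), length S >= 4, finite.
#' @param C S x S unit-diagonal phylogenetic correlation (or the result of
#'   a cached [decompose_C] eigendecomposition via `eigen_C`).
#' @param settings an [mcmc_settings()].
#' @param eigen_C optional precomputed `eigen(C)` to share across
#'   orthogroups.
#' @return list of class `lambda_fit`: `lambda` (posterior mean), `ci95`,
#'   `lambda_median`, `posterior_var` (posterior mean sigma2_p),
#'   `residual_var`, `total_var`, `dic`, `rhat` (split-Rhat of the lambda
#'   chain, > 1.1 flags divergence), `n_samples`, and `samples` (matrix of
#'   retained lambda / sigma2_p / sigma2_e / mu draws).
#' @export
fit_lambda_gibbs <- function(y, C = NULL, settings = mcmc_settings(),
                             eigen_C = NULL) {
  S <- length(y)
  stopifnot(S >= 4L, all(is.finite(y)))
  if (is.null(eigen_C)) eigen_C <- decompose_C(C)
  eng <- gibbs_lambda_engine(matrix(y, nrow = 1L), eigen_C, settings)
  draws <- cbind(lambda = eng$lambda_draws[, 1L],
                 sigma2_p = eng$s2p_draws[, 1L],
                 sigma2_e = eng$s2e_draws[, 1L],
                 mu = eng$mu_draws[, 1L])
  structure(list(
    lambda = eng$lambda_mean[1L],
    lambda_median = eng$lambda_median[1L],
    ci95 = c(eng$ci_lo[1L], eng$ci_hi[1L]),
    posterior_var = eng$posterior_var[1L],
    residual_var = eng$residual_var[1L],
    total_var = eng$posterior_var[1L] + eng$residual_var[1L],
    dic = eng$dic[1L], rhat = eng$rhat[1L], n_samples = eng$n_samples,
    samples = draws), class = "lambda_fit")
}

#' Gibbs fit of the reduced (non-phylogenetic) model
#'
#' `y = mu + e` with the same priors; its DIC is the comparison point for
#' [compare_models()].
#'
#' @inheritParams fit_lambda_gibbs
#' @return list with `dic`, `residual_var`, `mu`, `n_samples`.
#' @export
fit_reduced_gibbs <- function(y, settings = mcmc_settings()) {
  eng <- gibbs_reduced_engine(matrix(y, nrow = 1L), settings)
  list(dic = eng$dic[1L], residual_var = eng$residual_var[1L],
       mu = eng$mu[1L], n_samples = eng$n_samples)
}

# vectorized reduced-model (intercept + iid error) engine, G chains at once
gibbs_reduced_engine <- function(Y, settings) {
  G <- nrow(Y); S <- ncol(Y)
  a0 <- settings$prior_shape; b0 <- settings$prior_rate
  v0 <- settings$prior_mean_var
  set.seed(settings$seed + 1L)
  keep_at <- seq(settings$burn_in + 1L, settings$n_iter, by = settings$thin)
  n_keep <- length(keep_at)
  dev <- matrix(NA_real_, n_keep, G)
  mus <- matrix(NA_real_, n_keep, G)
  s2s <- matrix(NA_real_, n_keep, G)
  Yt <- t(Y)                                   # S x G
  ysum <- colSums(Yt)
  mu <- ysum / S
  s2e <- pmax(apply(Y, 1L, var), 1e-6)
  ki <- 1L
  for (it in seq_len(settings$n_iter)) {
    prec_mu <- S / s2e + 1 / v0
    mu <- rnorm(G, ysum / s2e / prec_mu, sqrt(1 / prec_mu))
    rss <- colSums(sweep(Yt, 2L, mu, `-`)^2)
    s2e <- 1 / rgamma(G, a0 + S / 2, b0 + rss / 2)
    if (ki <= n_keep && it == keep_at[ki]) {
      mus[ki, ] <- mu; s2s[ki, ] <- s2e
      dev[ki, ] <- S * log(2 * pi * s2e) + rss / s2e
      ki <- ki + 1L
    }
  }
  mu_bar <- colMeans(mus); s2_bar <- colMeans(s2s)
  rss_bar <- colSums(sweep(Yt, 2L, mu_bar, `-`)^2)
  dhat <- S * log(2 * pi * s2_bar) + rss_bar / s2_bar
  list(dic = 2 * colMeans(dev) - dhat, residual_var = s2_bar, mu = mu_bar,
       n_samples = n_keep)
}

# split-Rhat of one chain (first half vs second half)
split_rhat <- function(x) {
  n <- floor(length(x) / 2)
  if (n < 2L) return(NA_real_)
  halves <- list(x[seq_len(n)], x[seq_len(n) + n])
  m <- vapply(halves, mean, 0); v <- vapply(halves, var, 0)
  W <- mean(v)
  B <- n * var(m)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Profile maximum-likelihood estimate of Pagel's lambda
#'
#' Marginal Gaussian likelihood `y ~ N(mu 1, sigma2 (lambda C + (1-lambda) I))`
#' profiled over `mu` (GLS) and `sigma2` (closed form), maximized over
#' `lambda` in `[0, 1]` by golden-section search ([stats::optimize]). Used
#' as an independent cross-check of the Gibbs posterior.
#'
#' @inheritParams fit_lambda_gibbs
#' @return list `lambda`, `loglik`, `boundary_flag` (`TRUE` when the
#'   profile is flat, e.g. a star tree, where lambda is unidentifiable),
#'   and `profile` (function of lambda returning the profile log-likelihood).
#' @export
fit_lambda_ml <- function(y, C = NULL, eigen_C = NULL) {
  S <- length(y)
  stopifnot(S >= 3L, all(is.finite(y)))
  if (is.null(eigen_C)) eigen_C <- decompose_C(C)
  Q <- eigen_C$vectors
  lamC <- pmax(eigen_C$values, 0)
  ystar <- drop(crossprod(Q, y))
  w <- drop(crossprod(Q, rep(1, S)))
  profile <- function(lambda) {
    d <- lambda * lamC + (1 - lambda)
    d <- pmax(d, 1e-12)
    mu <- sum(w * ystar / d) / sum(w^2 / d)
    s2 <- sum((ystar - mu * w)^2 / d) / S
    -0.5 * (S * log(2 * pi * s2) + sum(log(d)) + S)
  }
  grid <- vapply(seq(0, 1, length.out = 21L), profile, 0)
  flat <- diff(range(grid)) < 1e-8
  if (flat)
    return(list(lambda = NA_real_, loglik = grid[1L], boundary_flag = TRUE,
                profile = profile))
  opt <- optimize(profile, c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- c(0, opt$maximum, 1)
  ll <- vapply(cand, profile, 0)
  best <- which.max(ll)
  list(lambda = cand[best], loglik = ll[best], boundary_flag = FALSE,
       profile = profile)
}

#' Bin a lambda estimate into a signal class
#'
#' Thresholds: negligible (lambda < 0.05), weak (0.05-0.2), moderate
#' (0.2-0.4), strong (> 0.4); boundary values go to the lower bin.
#'
#' @param lambda value(s) in `[0, 1]`.
#' @return factor with levels negligible, weak, moderate, strong.
#' @export
classify_signal <- function(lambda) {
  stopifnot(all(lambda >= 0 & lambda <= 1, na.rm = TRUE))
  cut(lambda, breaks = c(-Inf, 0.05, 0.2, 0.4, Inf),
      labels = c("negligible", "weak", "moderate", "strong"),
      right = TRUE)
}

#' DIC comparison of the phylogenetic and reduced models
#'
#' @param fit_full a `lambda_fit` (or anything with `$dic`).
#' @param fit_reduced reduced-model fit with `$dic`.
#' @return `delta_dic = dic_reduced - dic_full`; positive favors the
#'   phylogenetic model.
#' @export
compare_models <- function(fit_full, fit_reduced) {
  d <- fit_reduced$dic - fit_full$dic
  if (!is.finite(d)) {
    warning("non-finite DIC in model comparison")
    return(NA_real_)
  }
  d
}

#' Per-orthogroup lambda table
#'
#' Fits the phylogenetic and reduced models to every row of an orthogroup
#' x species statistic matrix (sharing one eigendecomposition of `C`) and
#' assembles the per-orthogroup summary used downstream.
#'
#' @param stat orthogroup x species matrix (e.g. from [stat_matrix()] on an
#'   orthogroup DE table); rows with non-finite entries are skipped.
#' @param C phylogenetic correlation matrix with matching species columns.
#' @param settings an [mcmc_settings()]; all orthogroups advance in one
#'   lock-step batch of chains seeded from `settings$seed`.
#' @return data.frame: `orthogroup_id`, `lambda`, `ci_lo`, `ci_hi`,
#'   `ci_range`, `posterior_var`, `total_var`, `dic_full`, `dic_reduced`,
#'   `delta_dic`, `rhat`, `signal_class`.
#' @export
fit_lambda_table <- function(stat, C, settings = mcmc_settings()) {
  stopifnot(all(colnames(stat) %in% colnames(C)))
  C <- C[colnames(stat), colnames(stat)]
  eg <- decompose_C(C)
  complete <- apply(stat, 1L, function(y) all(is.finite(y)))
  Y <- stat[complete, , drop = FALSE]
  if (nrow(Y) == 0L) stop("no orthogroup has a finite statistic in every species")
  full <- gibbs_lambda_engine(Y, eg, settings)
  red <- gibbs_reduced_engine(Y, settings)
  out <- data.frame(orthogroup_id = rownames(Y),
                    lambda = full$lambda_mean,
                    ci_lo = full$ci_lo, ci_hi = full$ci_hi,
                    ci_range = full$ci_hi - full$ci_lo,
                    posterior_var = full$posterior_var,
                    total_var = full$posterior_var + full$residual_var,
                    dic_full = full$dic, dic_reduced = red$dic,
                    delta_dic = red$dic - full$dic,
                    rhat = full$rhat,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out$signal_class <- classify_signal(pmin(1, pmax(0, out$lambda)))
  out
}
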