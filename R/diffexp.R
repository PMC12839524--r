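ALPHA_MIN <- 1e-8

#' Method-of-moments NB dispersion per unit
#'
#' For one unit (transcript or orthogroup) with counts `k_j`, size factors
#' `s_j` and a two-level treatment, the dispersion alpha of the NB
#' variance function `var = mu + alpha mu^2` is estimated from group-wise
#' moments of the normalized counts `y_j = k_j / s_j`: within each group,
#' `E y = mu`, `var y ~= mu * mean(1/s) + alpha mu^2`, so
#' `alpha_group = (v - m * mean(1/s)) / m^2`; groups are pooled by residual
#' degrees of freedom. The estimate is floored at `1e-8` (no shrinkage
#' trend, unlike DESeq2's full machinery).
#'
#' @param counts numeric vector of raw counts for the unit.
#' @param treatment factor of length `length(counts)` with 2 levels.
#' @param size_factors positive per-sample factors (default all 1).
#' @return dispersion estimate (scalar >= 1e-8), or `NA` if any treatment
#'   group has fewer than 2 samples.
#' @export
estimate_dispersion_mom <- function(counts, treatment,
                                    size_factors = rep(1, length(counts))) {
  groups <- split(seq_along(counts), treatment)
  if (any(lengths(groups) < 2L)) return(NA_real_)
  num <- 0; den <- 0
  for (idx in groups) {
    y <- counts[idx] / size_factors[idx]
    m <- mean(y)
    if (m <= 0) next
    v <- var(y)
    a <- (v - m * mean(1 / size_factors[idx])) / m^2
    w <- length(idx) - 1L
    num <- num + w * a
    den <- den + w
  }
  if (den == 0) return(ALPHA_MIN)
  max(ALPHA_MIN, num / den)
}

# Newton solve of the per-group score of the NB GLM with log link and
# offsets: gamma is the log of the group mean parameter, the score is
# sum_j (k_j - mu_j) / (1 + alpha mu_j) with mu_j = s_j exp(gamma).
# Returns gamma and the expected information sum_j mu_j / (1 + alpha mu_j).
nb_group_fit <- function(k, s, alpha, floor_mu = 1e-8) {
  if (sum(k) == 0) {
    gamma <- log(floor_mu)
  } else {
    gamma <- log(sum(k) / sum(s))
    for (it in seq_len(50L)) {
      mu <- s * exp(gamma)
      f <- sum((k - mu) / (1 + alpha * mu))
      fp <- -sum(mu * (1 + alpha * k) / (1 + alpha * mu)^2)
      step <- f / fp
      step <- max(min(step, 5), -5)      # damp wild steps
      gamma <- gamma - step
      if (abs(step) < 1e-12) break
    }
    gamma <- max(gamma, log(floor_mu))
  }
  mu <- s * exp(gamma)
  list(gamma = gamma, info = sum(mu / (1 + alpha * mu)))
}

#' Negative-binomial Wald test for one unit
#'
#' Maximum-likelihood fit of the NB GLM `count ~ treatment` with log link
#' and offset `log(size_factor)` at fixed dispersion `alpha` (variance
#' `mu + alpha mu^2`). For the saturated two-group design the fit reduces
#' to one Newton solve per treatment group of the IRLS score equations;
#' the Wald standard error comes from the expected information, as in
#' Fisher scoring. The treatment coefficient is reported on the log2
#' scale, with alum always the numerator: positive lfc means higher
#' expression in alum than PBS.
#'
#' @param counts numeric vector of raw counts.
#' @param treatment factor with levels `c("PBS", "alum")`.
#' @param size_factors per-sample size factors.
#' @param alpha NB dispersion; `NULL` estimates it by
#'   [estimate_dispersion_mom()].
#' @return one-row data.frame: `base_mean` (mean normalized count), `lfc`,
#'   `se`, `wald`, `p`, `alpha`, `status` ("ok", "all_zero",
#'   "too_few_samples").
#' @export
nb_wald_test <- function(counts, treatment, size_factors = rep(1, length(counts)),
                         alpha = NULL) {
  stopifnot(length(counts) == length(treatment),
            all(levels(treatment) == c("PBS", "alum")))
  base_mean <- mean(counts / size_factors)
  empty <- function(status, a = NA_real_)
    data.frame(base_mean = base_mean, lfc = NA_real_, se = NA_real_,
               wald = NA_real_, p = NA_real_, alpha = a, status = status,
               stringsAsFactors = FALSE)
  if (any(table(treatment) < 2L)) return(empty("too_few_samples"))
  if (all(counts == 0)) return(empty("all_zero"))
  if (is.null(alpha)) alpha <- estimate_dispersion_mom(counts, treatment, size_factors)
  ctrl <- treatment == "PBS"
  fit0 <- nb_group_fit(counts[ctrl], size_factors[ctrl], alpha)
  fit1 <- nb_group_fit(counts[!ctrl], size_factors[!ctrl], alpha)
  beta <- (fit1$gamma - fit0$gamma) / log(2)
  se <- sqrt(1 / fit0$info + 1 / fit1$info) / log(2)
  wald <- beta / se
  data.frame(base_mean = base_mean, lfc = beta, se = se, wald = wald,
             p = 2 * pnorm(-abs(wald)), alpha = alpha, status = "ok",
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust]); `NaN`/`NA` inputs
#' propagate.
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  p.adjust(p, method = "BH")
}

#' Per-species differential expression tables
#'
#' Runs the NB Wald test for every unit of every species at the requested
#' level and BH-adjusts p-values within each species table.
#'
#' At `level = "transcript"` the inputs are the raw per-species count
#' matrices with freshly estimated size factors. At `level = "orthogroup"`
#' the input is the per-species slice of the summed normalized orthogroup
#' matrix, rounded half-to-even to integers, with size factors re-estimated
#' on that matrix (mirroring what a count-based DE fit does to whatever
#' matrix it is handed).
#'
#' @param dataset an `og_dataset`, or a list with elements `counts`
#'   (named list of per-species matrices) and `metadata`.
#' @param level `"orthogroup"` or `"transcript"`.
#' @param og_matrix for `level = "orthogroup"`, the (core-restricted)
#'   matrix from [aggregate_orthogroups()]; computed from the dataset when
#'   omitted.
#' @param pseudo_reference passed to [compute_size_factors()].
#' @return data.frame with columns `unit_id`, `species_id`, `base_mean`,
#'   `lfc`, `se`, `wald`, `p`, `padj`, `alpha`, `status`; species lacking
#'   both treatments are skipped with a message.
#' @export
run_species_de <- function(dataset, level = c("orthogroup", "transcript"),
                           og_matrix = NULL, pseudo_reference = TRUE) {
  level <- match.arg(level)
  meta <- dataset$metadata
  out <- list()
  if (level == "orthogroup") {
    if (is.null(og_matrix)) {
      norm <- lapply(dataset$counts, function(m)
        normalize_counts(m, compute_size_factors(m, pseudo_reference = pseudo_reference)))
      og_matrix <- restrict_to_core(aggregate_orthogroups(norm, dataset$orthogroups))
    }
    counts_by_species <- lapply(split(meta$sample_id, meta$species_id), function(ss) {
      ss <- intersect(colnames(og_matrix), ss)
      round(og_matrix[, ss, drop = FALSE])       # round() is half-to-even
    })
  } else {
    counts_by_species <- lapply(dataset$counts, unclass)
  }
  for (sp in names(counts_by_species)) {
    m <- counts_by_species[[sp]]
    if (is.null(m) || ncol(m) == 0L) next
    tr <- meta$treatment[match(colnames(m), meta$sample_id)]
    if (anyNA(tr)) stop("samples of species ", sp, " missing from metadata")
    if (length(unique(tr[!is.na(tr)])) < 2L) {
      message("skipping species ", sp, ": both treatments not present")
      next
    }
    sf <- compute_size_factors(m, pseudo_reference = pseudo_reference)
    rows <- lapply(seq_len(nrow(m)), function(i)
      nb_wald_test(m[i, ], tr, sf))
    tab <- do.call(rbind, rows)
    tab <- cbind(data.frame(unit_id = rownames(m), species_id = sp,
                            stringsAsFactors = FALSE), tab)
    tab$padj <- bh_adjust(tab$p)
    out[[sp]] <- tab
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "level") <- level
  res
}

#' Write / read DE tables
#' @param de data.frame from [run_species_de()].
#' @param path TSV path.
#' @export
write_de_table <- function(de, path) {
  write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
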