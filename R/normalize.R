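#' Median-of-ratios size factors
#'
#' The DESeq2-style estimator, computed within one species' matrix: for each
#' sample j, `s_j = median over reference transcripts of count(t,j) /
#' geometric mean of transcript t across samples`, where the reference set
#' is the transcripts with strictly positive geometric mean (i.e. positive
#' in every sample). Factors are rescaled to geometric mean 1.
#'
#' @param counts transcript x sample count matrix.
#' @param pseudo_reference if no transcript is positive in all samples,
#'   setting this to `TRUE` computes geometric means over positive entries
#'   only (a pseudo-reference fallback); the default is an error with a
#'   remediation hint.
#' @return named positive numeric vector of size factors, one per sample,
#'   with geometric mean 1.
#' @export
compute_size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  logc <- log(counts)
  if (pseudo_reference) {
    logc[!is.finite(logc)] <- NA
    loggeo <- rowMeans(logc, na.rm = TRUE)
    ref <- is.finite(loggeo)
  } else {
    loggeo <- rowMeans(logc)
    ref <- is.finite(loggeo)           # all-positive rows only
    if (!any(ref))
      stop("no transcript is positive in all samples; ",
           "set pseudo_reference = TRUE to use positive-entry geometric means")
  }
  geo <- exp(loggeo[ref])
  s <- apply(counts[ref, , drop = FALSE], 2L, function(col)
    median(col / geo, na.rm = TRUE))
  if (any(!is.finite(s) | s <= 0))
    stop("degenerate size factor; too many zeros in the reference set")
  s <- s / exp(mean(log(s)))
  setNames(s, colnames(counts))
}

#' Divide counts by size factors
#'
#' @param counts transcript x sample matrix.
#' @param size_factors named vector covering every sample of `counts`.
#' @return numeric matrix of normalized expression, same dimnames.
#' @export
normalize_counts <- function(counts, size_factors) {
  miss <- setdiff(colnames(counts), names(size_factors))
  if (length(miss)) stop("missing size factor for sample ", miss[1L])
  sweep(unclass(counts), 2L, size_factors[colnames(counts)], `/`)
}

#' Sum normalized transcript expression to orthogroup level
#'
#' Per sample, normalized counts of all transcripts with membership in an
#' orthogroup are summed. Matrices from different species (disjoint sample
#' sets) are combined into one orthogroups x samples matrix; a transcript
#' absent from the map contributes to the per-species unassigned fraction
#' instead of any orthogroup.
#'
#' @param normalized named list (by species) of normalized transcript
#'   matrices.
#' @param map an `orthogroup_map`.
#' @return orthogroups x samples matrix with attributes `copy_number`
#'   (orthogroups x species, for the species present), `species` (per-sample
#'   species label) and `unassigned_fraction` (per species, fraction of
#'   transcripts not in the map).
#' @export
aggregate_orthogroups <- function(normalized, map) {
  species <- names(normalized)
  stopifnot(!is.null(species), !anyDuplicated(species))
  all_samples <- unlist(lapply(normalized, colnames), use.names = FALSE)
  if (anyDuplicated(all_samples))
    stop("sample '", all_samples[duplicated(all_samples)][1L],
         "' appears in more than one species matrix")
  ogs <- sort(unique(map$orthogroup_id))
  out <- matrix(0, length(ogs), length(all_samples),
                dimnames = list(ogs, all_samples))
  unassigned <- setNames(numeric(length(species)), species)
  sample_species <- setNames(rep(species, vapply(normalized, ncol, 0L)), all_samples)
  for (sp in species) {
    m <- normalized[[sp]]
    sel <- map[map$species_id == sp, ]
    idx <- match(sel$transcript_id, rownames(m))
    sel <- sel[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
    unassigned[sp] <- 1 - length(unique(idx)) / nrow(m)
    if (length(idx)) {
      grp <- factor(sel$orthogroup_id, levels = ogs)
      summed <- rowsum(m[idx, , drop = FALSE], grp)
      out[rownames(summed), colnames(m)] <- summed
    }
  }
  cn <- copy_number_matrix(map, species)[ogs, , drop = FALSE]
  structure(out, copy_number = cn, species = sample_species,
            unassigned_fraction = unassigned)
}

#' Restrict an orthogroup matrix to core orthogroups
#'
#' Keeps exactly the orthogroups with at least one transcript copy in every
#' species, the retention rule applied before all cross-species comparisons.
#'
#' @param og_matrix matrix from [aggregate_orthogroups()].
#' @return the restricted matrix (attributes carried over); attribute
#'   `n_total` / `n_core` record how many orthogroups went in and survived.
#' @export
restrict_to_core <- function(og_matrix) {
  cn <- attr(og_matrix, "copy_number")
  if (is.null(cn)) stop("matrix lacks a copy_number attribute")
  core <- rownames(cn)[apply(cn >= 1L, 1L, all)]
  out <- og_matrix[core, , drop = FALSE]
  structure(out, copy_number = cn[core, , drop = FALSE],
            species = attr(og_matrix, "species"),
            unassigned_fraction = attr(og_matrix, "unassigned_fraction"),
            n_total = nrow(og_matrix), n_core = length(core))
}
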