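#' @importFrom stats median optimize pnorm pt qt quantile rnorm rgamma rpois
#'   rnbinom rbinom rgeom runif sd var cor cor.test t.test fisher.test lm
#'   anova p.adjust dist hclust as.dist setNames complete.cases
#'   dhyper coef residuals qnorm rexp rbeta
#' @importFrom utils read.delim write.table head
NULL

# internal: stop with a structured message naming file / line / field
io_error <- function(file, what, ...) {
  stop(sprintf("[%s] %s", file, sprintf(what, ...)), call. = FALSE)
}

#' Read a per-species transcript count matrix
#'
#' Reads a TSV with a header row of sample ids and transcript ids in the
#' first column into an integer matrix (transcripts x samples). Counts must
#' be non-negative integers; duplicate transcript or sample ids are rejected.
#'
#' @param path path to a tab-separated file.
#' @param species_id label attached to the matrix (one matrix per species;
#'   species have distinct reference transcriptomes).
#' @return integer matrix with `rownames` = transcript ids, `colnames` =
#'   sample ids and attribute `species_id`.
#' @export
read_count_matrix <- function(path, species_id) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 3L)
    io_error(path, "need a transcript id column plus >= 2 sample columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids))
    io_error(path, "duplicate transcript id '%s'", ids[duplicated(ids)][1L])
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples))
    io_error(path, "duplicate sample id '%s'", samples[duplicated(samples)][1L])
  m <- matrix(0L, nrow = nrow(df), ncol = length(samples),
              dimnames = list(ids, samples))
  for (j in seq_along(samples)) {
    cell <- df[[j + 1L]]
    num <- suppressWarnings(as.numeric(cell))
    bad <- which(!is.finite(num) | num < 0 | num != round(num))
    if (length(bad))
      io_error(path, "non-integer or negative count '%s' at row '%s', column '%s'",
               cell[bad[1L]], ids[bad[1L]], samples[j])
    m[, j] <- as.integer(num)
  }
  validate_count_matrix(m, species_id)
}

#' @rdname read_count_matrix
#' @param counts integer matrix to validate / write.
#' @export
validate_count_matrix <- function(counts, species_id = attr(counts, "species_id")) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)), !is.null(colnames(counts)))
  if (ncol(counts) < 2L) stop("count matrix needs at least 2 samples")
  if (anyDuplicated(rownames(counts))) stop("duplicate transcript ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate sample ids")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  attr(counts, "species_id") <- species_id
  class(counts) <- c("transcript_counts", class(unclass(counts)))
  counts
}

#' @rdname read_count_matrix
#' @export
write_count_matrix <- function(counts, path) {
  df <- data.frame(transcript_id = rownames(counts), counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `species_id`, `treatment` (PBS or alum) and
#' `fibrosis_score` (ordinal 0-3, may be missing). Fibrosis score is carried
#' as metadata only.
#'
#' @param path path to a tab-separated file.
#' @return data.frame with treatment as a factor with levels PBS, alum
#'   (PBS is the reference level: fold changes are alum vs PBS).
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  need <- c("sample_id", "species_id", "treatment")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) io_error(path, "missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    io_error(path, "duplicate sample_id '%s'", df$sample_id[duplicated(df$sample_id)][1L])
  bad <- setdiff(unique(df$treatment), c("PBS", "alum"))
  if (length(bad)) io_error(path, "treatment must be PBS or alum, got '%s'", bad[1L])
  if (!"fibrosis_score" %in% colnames(df)) df$fibrosis_score <- NA_character_
  fs <- df$fibrosis_score
  fs[fs %in% c("", "NA")] <- NA_character_
  ok <- is.na(fs) | fs %in% as.character(0:3)
  if (!all(ok)) io_error(path, "fibrosis_score must be in 0..3, got '%s'", fs[!ok][1L])
  data.frame(sample_id = df$sample_id,
             species_id = df$species_id,
             treatment = factor(df$treatment, levels = c("PBS", "alum")),
             fibrosis_score = as.integer(fs),
             stringsAsFactors = FALSE)
}

#' @rdname read_sample_metadata
#' @param metadata data.frame as returned by [read_sample_metadata()].
#' @export
write_sample_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OrthoFinder-style Orthogroups.tsv
#'
#' Header is `Orthogroup` followed by one column per species; each cell is a
#' comma (+ optional space) separated list of that species' transcripts in
#' the orthogroup, possibly empty. A transcript may belong to at most one
#' orthogroup. The legacy one-line `OG: id id id` dialect is rejected.
#'
#' @param path path to the table.
#' @param species optional character vector restricting/validating the
#'   species columns; unknown columns are an error.
#' @return a long-format data.frame (`orthogroup_id`, `species_id`,
#'   `transcript_id`) of class `orthogroup_map`.
#' @export
read_orthogroups <- function(path, species = NULL) {
  first <- readLines(path, n = 1L)
  if (!grepl("\t", first) || !startsWith(first, "Orthogroup"))
    io_error(path, "expected tab-separated header starting with 'Orthogroup'")
  df <- read.delim(path, sep = "\t", check.names = FALSE, colClasses = "character")
  sp_cols <- colnames(df)[-1L]
  if (!is.null(species)) {
    unknown <- setdiff(sp_cols, species)
    if (length(unknown)) io_error(path, "unknown species column '%s'", unknown[1L])
  }
  out <- vector("list", length(sp_cols))
  for (k in seq_along(sp_cols)) {
    cells <- df[[k + 1L]]
    lists <- strsplit(cells, ",[ ]*")
    n <- lengths(lists)
    keep <- n > 0L
    ids <- unlist(lists[keep], use.names = FALSE)
    ids <- ids[nzchar(ids)]
    og <- rep(df[[1L]][keep], lengths(lapply(lists[keep], function(x) x[nzchar(x)])))
    out[[k]] <- data.frame(orthogroup_id = og, species_id = sp_cols[k],
                           transcript_id = ids, stringsAsFactors = FALSE)
  }
  map <- do.call(rbind, out)
  as_orthogroup_map(map, source = path)
}

#' @rdname read_orthogroups
#' @param map long-format assignment data.frame.
#' @param source label used in error messages.
#' @export
as_orthogroup_map <- function(map, source = "orthogroup map") {
  stopifnot(all(c("orthogroup_id", "species_id", "transcript_id") %in% colnames(map)))
  key <- paste(map$species_id, map$transcript_id, sep = "::")
  dup <- duplicated(key) & !duplicated(paste(key, map$orthogroup_id))
  if (any(dup))
    io_error(source, "transcript '%s' (%s) listed under more than one orthogroup",
             map$transcript_id[dup][1L], map$species_id[dup][1L])
  map <- map[, c("orthogroup_id", "species_id", "transcript_id")]
  rownames(map) <- NULL
  class(map) <- c("orthogroup_map", "data.frame")
  map
}

#' @rdname read_orthogroups
#' @export
write_orthogroups <- function(map, path, species = sort(unique(map$species_id))) {
  ogs <- sort(unique(map$orthogroup_id))
  wide <- matrix("", nrow = length(ogs), ncol = length(species),
                 dimnames = list(ogs, species))
  sp <- split(map, map$species_id)
  for (s in names(sp)) {
    per_og <- split(sp[[s]]$transcript_id, sp[[s]]$orthogroup_id)
    wide[names(per_og), s] <- vapply(per_og, paste, "", collapse = ", ")
  }
  df <- data.frame(Orthogroup = ogs, wide, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-orthogroup per-species copy numbers
#'
#' @param map an `orthogroup_map`.
#' @param species species to include as columns (default: those present).
#' @return integer matrix orthogroups x species of transcript copy numbers
#'   (0 where a species has no member).
#' @export
copy_number_matrix <- function(map, species = sort(unique(map$species_id))) {
  tab <- table(factor(map$orthogroup_id), factor(map$species_id, levels = species))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- NULL
  m
}

#' Read / write a rooted species tree (newick)
#'
#' The tree must be rooted and binary with branch lengths (substitutions per
#' site). Multifurcations are an error unless `resolve = TRUE`, in which case
#' they are resolved arbitrarily with zero-length branches.
#'
#' @param path newick file.
#' @param resolve resolve multifurcations instead of erroring.
#' @param allow_missing_lengths replace missing branch lengths with 0
#'   instead of erroring.
#' @return an [ape::phylo] tree.
#' @export
read_species_tree <- function(path, resolve = FALSE, allow_missing_lengths = FALSE) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) io_error(path, "could not parse newick")
  if (anyDuplicated(tree$tip.label)) io_error(path, "duplicate leaf labels")
  if (is.null(tree$edge.length)) {
    if (!allow_missing_lengths) io_error(path, "tree has no branch lengths")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    if (!allow_missing_lengths) io_error(path, "missing branch length")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0)) io_error(path, "negative branch length")
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    if (!resolve) io_error(path, "tree must be rooted and binary (set resolve = TRUE to force)")
    tree <- ape::multi2di(tree)
  }
  tree
}

#' @rdname read_species_tree
#' @param tree an `ape::phylo`.
#' @export
write_species_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read / write per-transcript GO annotations
#'
#' TSV with columns `transcript_id`, `species_id`, `go_terms` where
#' `go_terms` is a pipe-separated list of GO identifiers (`GO:` + 7 digits);
#' the list may be empty.
#'
#' @param path annotation file.
#' @return data.frame `transcript_id`, `species_id`, `go_term` in long form
#'   (transcripts with no terms are dropped from the long form but counted
#'   in the `universe` attribute, a data.frame of all annotated transcripts).
#' @export
read_go_annotations <- function(path) {
  df <- read.delim(path, sep = "\t", colClasses = "character")
  need <- c("transcript_id", "species_id", "go_terms")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) io_error(path, "missing column(s): %s", paste(miss, collapse = ", "))
  lists <- strsplit(df$go_terms, "\\|")
  terms <- unlist(lists, use.names = FALSE)
  terms <- terms[nzchar(terms)]
  bad <- terms[!grepl("^GO:[0-9]{7}$", terms)]
  if (length(bad)) io_error(path, "malformed GO identifier '%s'", bad[1L])
  n <- vapply(lists, function(x) sum(nzchar(x)), 0L)
  long <- data.frame(
    transcript_id = rep(df$transcript_id, n),
    species_id = rep(df$species_id, n),
    go_term = unlist(lapply(lists, function(x) x[nzchar(x)]), use.names = FALSE),
    stringsAsFactors = FALSE)
  attr(long, "universe") <- df[, c("transcript_id", "species_id")]
  long
}

#' @rdname read_go_annotations
#' @param annotations long-form annotation data.frame (with `universe` attribute).
#' @export
write_go_annotations <- function(annotations, path) {
  uni <- attr(annotations, "universe")
  if (is.null(uni))
    uni <- unique(annotations[, c("transcript_id", "species_id")])
  key <- paste(annotations$species_id, annotations$transcript_id, sep = "::")
  per <- split(annotations$go_term, factor(key, levels = paste(uni$species_id, uni$transcript_id, sep = "::")))
  df <- data.frame(transcript_id = uni$transcript_id,
                   species_id = uni$species_id,
                   go_terms = vapply(per, paste, "", collapse = "|"))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
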