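#' Construct an abundance matrix
#'
#' The universal community representation used throughout the package: an
#' integer count matrix with samples as rows and taxa as columns. Row names
#' are sample identifiers, column names are taxon identifiers; both must be
#' unique. All other functions accept either an `abundance_matrix` or a plain
#' named matrix, which is validated on entry.
#'
#' @param counts numeric matrix of non-negative counts, samples x taxa.
#' @param sample_ids,taxon_ids optional character vectors overriding the
#'   dimnames of `counts`.
#' @return an integer matrix of class `abundance_matrix`.
#' @export
abundance_matrix <- function(counts, sample_ids = rownames(counts),
                             taxon_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%03d", seq_len(nrow(counts)))
  if (is.null(taxon_ids)) taxon_ids <- sprintf("taxon_%04d", seq_len(ncol(counts)))
  if (length(sample_ids) != nrow(counts) || length(taxon_ids) != ncol(counts)) {
    stopf("sample_ids/taxon_ids lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) stopf("duplicate sample ids: %s",
    paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(taxon_ids)) stopf("duplicate taxon ids: %s",
    paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  if (!is.numeric(counts)) stopf("counts must be numeric")
  bad <- which(!is.finite(counts) | counts < 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("negative or non-finite count at sample '%s', taxon '%s'",
          sample_ids[bad[1, 1]], taxon_ids[bad[1, 2]])
  }
  mode(counts) <- "integer"
  dimnames(counts) <- list(sample_ids, taxon_ids)
  structure(counts, class = c("abundance_matrix", "matrix", "array"))
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d samples x %d taxa, %d reads total\n",
              nrow(x), ncol(x), sum(x)))
  invisible(x)
}

# validate/coerce a counts argument coming from the user
as_counts <- function(m, arg = "m") {
  if (inherits(m, "abundance_matrix")) return(unclass(m))
  m <- as.matrix(m)
  if (!is.numeric(m)) stopf("'%s' must be a numeric matrix", arg)
  if (any(m < 0, na.rm = TRUE) || anyNA(m)) stopf("'%s' contains negative or missing counts", arg)
  m
}

#' Convert counts to relative abundances
#'
#' @param m abundance matrix (samples x taxa) with positive row sums.
#' @return a real matrix whose rows each sum to 1.
#' @export
relative_abundance <- function(m) {
  m <- as_counts(m)
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero) > 0) {
    stopf("sample(s) with zero total counts: %s",
          paste(if (is.null(rownames(m))) zero else rownames(m)[zero], collapse = ", "))
  }
  m / tot
}

#' Bray-Curtis dissimilarity between two communities
#'
#' `BC = sum(|x - y|) / sum(x + y)`. By default both vectors are normalised to
#' relative abundances first, so samples of different sequencing depth are
#' comparable; set `relative = FALSE` to use the raw values.
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @param relative normalise each vector to sum 1 before computing.
#' @return dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(x, y, relative = TRUE) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (any(x < 0) || any(y < 0)) stopf("abundances must be non-negative")
  sx <- sum(x); sy <- sum(y)
  if (sx == 0 && sy == 0) stopf("both communities are empty")
  if (relative) {
    if (sx == 0 || sy == 0) stopf("cannot normalise an all-zero community")
    x <- x / sx
    y <- y / sy
  }
  sum(abs(x - y)) / sum(x + y)
}

#' Taxon richness
#'
#' Number of taxa with count > 0, per sample when given a matrix.
#'
#' @param x a count vector, or an abundance matrix (samples x taxa).
#' @return integer, or named integer vector for a matrix.
#' @export
richness <- function(x) {
  if (is.matrix(x)) return(rowSums(unclass(x) > 0))
  sum(x > 0)
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample without replacement to `depth` reads. Samples below
#' the target depth are dropped with a warning. Off by default everywhere in
#' the package; exposed for users who want depth-standardised richness.
#'
#' @param m abundance matrix.
#' @param depth target reads per sample.
#' @param seed integer seed.
#' @return an `abundance_matrix` of rarefied counts.
#' @export
rarefy_counts <- function(m, depth, seed = NULL) {
  m <- as_counts(m)
  if (!is_count(depth)) stopf("depth must be a positive integer")
  local_seed(seed, {
    keep <- rowSums(m) >= depth
    if (!all(keep)) {
      warnf("dropping %d sample(s) below depth %d", sum(!keep), depth)
    }
    m <- m[keep, , drop = FALSE]
    out <- t(apply(m, 1, function(row) {
      pool <- rep.int(seq_along(row), row)
      drawn <- sample(pool, depth)
      tabulate(drawn, nbins = length(row))
    }))
    colnames(out) <- colnames(m)
    abundance_matrix(out)
  })
}

#' Per-taxon occupancy and mean relative abundance
#'
#' The two summaries the Sloan neutral model relates: the fraction of samples
#' in which a taxon is detected, and its mean relative abundance across
#' samples (the metacommunity abundance estimate p).
#'
#' @param m abundance matrix with at least 2 samples.
#' @return data.frame with columns `taxon`, `frequency`, `p`.
#' @export
occupancy_abundance <- function(m) {
  m <- as_counts(m)
  if (nrow(m) < 2) stopf("need at least 2 samples")
  rel <- relative_abundance(m)
  data.frame(
    taxon = colnames(m),
    frequency = colMeans(m > 0),
    p = colMeans(rel),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Aggregate samples by metadata keys
#'
#' Sums counts over all samples sharing the same combination of `keys` in the
#' metadata (e.g., pooling depths within lake x fraction x month). Group ids
#' are the key values joined with "|", in first-appearance order of the keys'
#' sorted combinations, so grouping is invariant to input sample order.
#'
#' @param m abundance matrix.
#' @param metadata data.frame with a `sample_id` column matching rownames(m).
#' @param keys character vector of metadata column names to group by.
#' @return an `abundance_matrix` with one row per key combination, carrying a
#'   `groups` attribute (data.frame of the key values per aggregated row).
#' @export
aggregate_samples <- function(m, metadata, keys) {
  m <- as_counts(m)
  if (!all(keys %in% names(metadata))) {
    stopf("metadata lacks key column(s): %s",
          paste(setdiff(keys, names(metadata)), collapse = ", "))
  }
  idx <- match(rownames(m), metadata$sample_id)
  if (anyNA(idx)) {
    stopf("sample(s) without a metadata row: %s",
          paste(rownames(m)[is.na(idx)], collapse = ", "))
  }
  md <- metadata[idx, keys, drop = FALSE]
  gid <- do.call(paste, c(lapply(md, as.character), sep = "|"))
  levels <- sort(unique(gid))
  out <- rowsum(m, group = factor(gid, levels = levels), reorder = TRUE)
  groups <- unique(cbind(data.frame(group = gid, stringsAsFactors = FALSE), md))
  groups <- groups[match(levels, groups$group), , drop = FALSE]
  rownames(groups) <- NULL
  res <- abundance_matrix(out, sample_ids = levels, taxon_ids = colnames(m))
  attr(res, "groups") <- groups
  res
}
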