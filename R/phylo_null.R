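# Stegen-style null models: betaMNTD / betaNTI against a tip-shuffle null,
# abundance-based Raup-Crick on Bray-Curtis, and the five-way classification
# of assembly processes (variable selection, homogeneous selection, dispersal
# limitation, homogenizing dispersal, undominated).

PROCESS_LEVELS <- c("variable_selection", "homogeneous_selection",
                    "dispersal_limitation", "homogenizing_dispersal",
                    "undominated")

#' Cophenetic (patristic) distance matrix from a tree
#'
#' Sum of branch lengths along the tip-to-tip path, for every pair of tips.
#'
#' @param tree a rooted `phylo` with branch lengths.
#' @return symmetric matrix with zero diagonal, tips as dimnames.
#' @export
cophenetic_matrix <- function(tree) {
  if (!inherits(tree, "phylo")) stopf("tree must be a 'phylo' object")
  if (is.null(tree$edge.length)) stopf("tree has no branch lengths")
  bad <- which(is.na(tree$edge.length))
  if (length(bad) > 0) {
    stopf("missing branch length on edge %d (%d -> %d)",
          bad[1], tree$edge[bad[1], 1], tree$edge[bad[1], 2])
  }
  ape::cophenetic.phylo(tree)
}

# Align a cophenetic matrix (or tree) to the taxa of a community matrix.
align_distances <- function(D, taxa) {
  if (inherits(D, "phylo")) D <- cophenetic_matrix(D)
  missing <- setdiff(taxa, rownames(D))
  if (length(missing) > 0) {
    stopf("taxa absent from the tree/distance matrix: %s%s",
          paste(utils::head(missing, 5), collapse = ", "),
          if (length(missing) > 5) ", ..." else "")
  }
  D[taxa, taxa, drop = FALSE]
}

#' betaMNTD between two communities
#'
#' Abundance-weighted mean nearest-taxon distance between communities:
#' `0.5 * (sum_i f_i min_j D_ij + sum_j f_j min_i D_ij)` where f are relative
#' abundances renormalised over each community's present taxa (uniform when
#' `weighted = FALSE`).
#'
#' @param x,y abundance or relative-abundance vectors named by taxon, or
#'   aligned with `D`.
#' @param D cophenetic matrix (or tree) covering the taxa.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return non-negative scalar.
#' @export
bmntd <- function(x, y, D, weighted = TRUE) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (sum(x > 0) == 0 || sum(y > 0) == 0) stopf("empty community")
  if (inherits(D, "phylo")) D <- cophenetic_matrix(D)
  if (!is.null(names(x))) D <- align_distances(D, names(x))
  if (nrow(D) != length(x)) stopf("D dimension does not match community length")
  W <- rbind(x / sum(x), y / sum(y))
  bmntd_matrix_cpp(W, unname(as.matrix(D)), weighted)[1, 2]
}

#' Pairwise betaMNTD for all samples
#'
#' @param m abundance matrix.
#' @param D cophenetic matrix or tree covering the matrix taxa.
#' @param weighted abundance-weighted (default) or presence-based.
#' @return symmetric sample x sample matrix of betaMNTD values.
#' @export
bmntd_matrix <- function(m, D, weighted = TRUE) {
  counts <- as_counts(m)
  D <- align_distances(D, colnames(counts))
  W <- relative_abundance(counts)
  out <- bmntd_matrix_cpp(unname(W), unname(as.matrix(D)), weighted)
  dimnames(out) <- list(rownames(counts), rownames(counts))
  out
}

#' betaNTI for all sample pairs
#'
#' The null model shuffles taxon labels across the cophenetic matrix
#' (equivalently, across the tree tips); one label permutation per null round
#' is shared by all pairs. betaNTI is the z-score of observed betaMNTD against
#' the null distribution: |betaNTI| > 2 signals deterministic selection.
#' Pairs whose null distribution has zero spread (e.g., identical communities)
#' get `bnti = NA` and are flagged `degenerate`.
#'
#' @param m abundance matrix (>= 2 samples).
#' @param tree phylogeny (or precomputed cophenetic matrix) over the taxa.
#' @param n_null number of null permutations (default 999).
#' @param seed integer seed.
#' @param weighted abundance-weighted betaMNTD (default).
#' @return data.frame: sample_i, sample_j, bmntd_obs, null_mean, null_sd,
#'   bnti, degenerate.
#' @export
bnti_pairwise <- function(m, tree, n_null = 999, seed = NULL, weighted = TRUE) {
  counts <- as_counts(m)
  if (nrow(counts) < 2) stopf("need at least 2 samples")
  D <- align_distances(tree, colnames(counts))
  W <- relative_abundance(counts)
  n_taxa <- ncol(counts)
  perms <- local_seed(seed, {
    t(replicate(n_null, sample.int(n_taxa))) - 1L
  })
  res <- bnti_null_cpp(unname(W), unname(as.matrix(D)), perms, weighted)
  pairs <- which(upper.tri(diag(nrow(counts))), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  degenerate <- res$null_sd <= .Machine$double.eps^0.5
  bnti <- ifelse(degenerate, NA_real_,
                 (res$obs - res$null_mean) / res$null_sd)
  if (any(degenerate)) {
    warnf("%d pair(s) have a degenerate null distribution (sd = 0); bnti set to NA",
          sum(degenerate))
  }
  data.frame(
    sample_i = rownames(counts)[pairs[, 1]],
    sample_j = rownames(counts)[pairs[, 2]],
    bmntd_obs = res$obs, null_mean = res$null_mean, null_sd = res$null_sd,
    bnti = bnti, degenerate = degenerate,
    stringsAsFactors = FALSE
  )
}

#' Draw one Raup-Crick null community
#'
#' The null-assembly primitive behind [rc_bray()]: draw `rich` species without
#' replacement with probability proportional to metacommunity occupancy, seed
#' each with one read, then allocate the remaining `total - rich` reads
#' multinomially by metacommunity relative abundance among the drawn species.
#'
#' @param rich target richness (number of species).
#' @param total target total reads (>= rich).
#' @param occ_w per-taxon occupancy weights (e.g., number of samples
#'   containing the taxon).
#' @param abund_w per-taxon abundance weights (relative abundances in the
#'   metacommunity).
#' @return integer count vector over the metacommunity taxa, with exactly
#'   `rich` positive entries summing to `total`.
#' @export
draw_null_community <- function(rich, total, occ_w, abund_w) {
  if (total < rich) stopf("total must be >= richness")
  sp <- sample.int(length(occ_w), rich, prob = occ_w)
  out <- integer(length(occ_w))
  out[sp] <- 1L
  if (total > rich) {
    out[sp] <- out[sp] + rmultinom(1, total - rich, prob = abund_w[sp])[, 1]
  }
  out
}

#' Abundance-based Raup-Crick (RCbray) for all sample pairs
#'
#' For each pair, `n_null` pairs of null communities are assembled from the
#' metacommunity (occupancy-weighted species draws at observed richness, reads
#' allocated by metacommunity relative abundance, each drawn species seeded
#' with one read); Bray-Curtis is computed for each null pair and compared
#' with the observed value:
#' `rc = 2 * ((#(BC_null < BC_obs) + 0.5 #(BC_null = BC_obs)) / n_null - 0.5)`.
#' RC near +1 means the pair is more dissimilar than expected by chance
#' (dispersal limitation when selection is absent); near -1, more similar
#' (homogenizing dispersal).
#'
#' @param m abundance matrix (counts; >= 2 samples). Bray-Curtis is computed
#'   on counts, with totals fixed at the observed totals.
#' @param n_null null replicates per pair (default 999).
#' @param seed integer seed.
#' @param meta optional list with elements `occupancy` and `abundance`
#'   (per-taxon weights aligned with the columns of `m`) defining the
#'   metacommunity the nulls are assembled from; by default both are derived
#'   from `m` itself.
#' @return data.frame: sample_i, sample_j, bc_obs, rc (in \[-1, 1\]).
#' @export
rc_bray <- function(m, n_null = 999, seed = NULL, meta = NULL) {
  counts <- as_counts(m)
  if (nrow(counts) < 2) stopf("need at least 2 samples")
  # canonicalise orientation so results are exactly invariant to the input's
  # sample and taxon order (the null draws consume the RNG in canonical order)
  if (!is.null(rownames(counts)) && !is.null(colnames(counts))) {
    tord <- order(colnames(counts))
    counts <- counts[order(rownames(counts)), tord, drop = FALSE]
    if (!is.null(meta)) {
      meta$occupancy <- meta$occupancy[tord]
      meta$abundance <- meta$abundance[tord]
    }
  }
  totals <- rowSums(counts)
  if (any(totals == 0)) {
    stopf("sample(s) with zero total counts: %s",
          paste(rownames(counts)[totals == 0], collapse = ", "))
  }
  if (is.null(meta)) {
    occ_w <- colSums(counts > 0)
    abund_w <- colSums(counts)
  } else {
    if (length(meta$occupancy) != ncol(counts) ||
        length(meta$abundance) != ncol(counts)) {
      stopf("meta weights must align with the columns of m")
    }
    occ_w <- meta$occupancy
    abund_w <- meta$abundance
  }
  abund_w <- abund_w / sum(abund_w)
  present <- occ_w > 0
  rich <- rowSums(counts > 0)
  n <- nrow(counts)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  local_seed(seed, {
    rc <- bc_obs <- numeric(nrow(pairs))
    occ_p <- occ_w[present]
    ab_p <- abund_w[present]
    for (k in seq_len(nrow(pairs))) {
      a <- pairs[k, 1]; b <- pairs[k, 2]
      xa <- counts[a, present]; xb <- counts[b, present]
      bc_obs[k] <- sum(abs(xa - xb)) / sum(xa + xb)
      lt <- eq <- 0L
      for (r in seq_len(n_null)) {
        na_ <- draw_null_community(rich[a], totals[a], occ_p, ab_p)
        nb_ <- draw_null_community(rich[b], totals[b], occ_p, ab_p)
        bc_null <- sum(abs(na_ - nb_)) / sum(na_ + nb_)
        if (bc_null < bc_obs[k]) lt <- lt + 1L
        else if (bc_null == bc_obs[k]) eq <- eq + 1L
      }
      rc[k] <- 2 * ((lt + 0.5 * eq) / n_null - 0.5)
    }
    data.frame(
      sample_i = rownames(counts)[pairs[, 1]],
      sample_j = rownames(counts)[pairs[, 2]],
      bc_obs = bc_obs, rc = rc, stringsAsFactors = FALSE
    )
  })
}

#' Classify a sample pair into an assembly process
#'
#' Thresholds: betaNTI > 2 -> variable selection; betaNTI < -2 -> homogeneous
#' selection; otherwise RC > 0.95 -> dispersal limitation, RC < -0.95 ->
#' homogenizing dispersal, |RC| <= 0.95 -> undominated. `rc` may be NA when
#' |betaNTI| > 2 (it is not consulted there). Vectorised.
#'
#' @param bnti betaNTI value(s).
#' @param rc Raup-Crick value(s) in \[-1, 1\].
#' @return factor with the five process levels (NA where bnti is NA or rc is
#'   needed but missing).
#' @export
classify_process <- function(bnti, rc = NA_real_) {
  n <- max(length(bnti), length(rc))
  bnti <- rep_len(bnti, n)
  rc <- rep_len(rc, n)
  if (any(!is.na(rc) & abs(rc) > 1 + 1e-12)) stopf("rc must lie in [-1, 1]")
  out <- rep(NA_character_, n)
  out[!is.na(bnti) & bnti > 2] <- "variable_selection"
  out[!is.na(bnti) & bnti < -2] <- "homogeneous_selection"
  stoch <- !is.na(bnti) & abs(bnti) <= 2
  out[stoch & !is.na(rc) & rc > 0.95] <- "dispersal_limitation"
  out[stoch & !is.na(rc) & rc < -0.95] <- "homogenizing_dispersal"
  out[stoch & !is.na(rc) & abs(rc) <= 0.95] <- "undominated"
  factor(out, levels = PROCESS_LEVELS)
}

#' Summarise process fractions per group
#'
#' @param pairs data.frame with a `process` column (and optionally NA for
#'   degenerate pairs, which are excluded and counted separately).
#' @param grouping vector (or data.frame column name in `pairs`) identifying
#'   the group of each pair; NULL for a single pooled group.
#' @return data.frame: group, process, fraction (summing to 1 within group),
#'   n_pairs, n_excluded.
#' @export
summarize_processes <- function(pairs, grouping = NULL) {
  if (!"process" %in% names(pairs)) stopf("pairs must have a 'process' column")
  g <- if (is.null(grouping)) rep("all", nrow(pairs))
       else if (is.character(grouping) && length(grouping) == 1 &&
                grouping %in% names(pairs)) as.character(pairs[[grouping]])
       else as.character(grouping)
  out <- list()
  for (grp in unique(g)) {
    pr <- pairs$process[g == grp]
    excl <- sum(is.na(pr))
    pr <- pr[!is.na(pr)]
    if (length(pr) == 0) {
      warnf("group '%s' has no classified pairs; skipped", grp)
      next
    }
    tab <- table(factor(pr, levels = PROCESS_LEVELS))
    out[[grp]] <- data.frame(
      group = grp, process = names(tab),
      fraction = as.numeric(tab) / length(pr),
      n_pairs = length(pr), n_excluded = excl,
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full assembly-process analysis per group
#'
#' Runs [bnti_pairwise()] and [rc_bray()] within each group of samples (e.g.,
#' lake x fraction), classifies every pair and summarises process fractions.
#' Cross-group pairs are not formed.
#'
#' @param m abundance matrix.
#' @param tree phylogeny covering the taxa.
#' @param metadata sample metadata with `sample_id`.
#' @param group_by metadata columns defining the groups (NULL = one group).
#' @param n_null null replicates for both null models.
#' @param seed integer seed (each group gets a derived child seed).
#' @param weighted abundance-weighted betaMNTD.
#' @return list with `pairs` (per-pair table incl. `process` and `group`) and
#'   `summary` (from [summarize_processes()]).
#' @export
assembly_analysis <- function(m, tree, metadata, group_by = NULL,
                              n_null = 999, seed = NULL, weighted = TRUE) {
  counts <- as_counts(m)
  if (is.null(group_by)) {
    groups <- setNames(list(rownames(counts)), "all")
  } else {
    idx <- match(rownames(counts), metadata$sample_id)
    if (anyNA(idx)) stopf("sample(s) missing from metadata")
    gid <- do.call(paste, c(lapply(group_by, function(k) metadata[[k]][idx]),
                            sep = "|"))
    groups <- split(rownames(counts), gid)
  }
  all_pairs <- list()
  for (gi in seq_along(groups)) {
    ids <- groups[[gi]]
    if (length(ids) < 2) {
      warnf("group '%s' has fewer than 2 samples; skipped", names(groups)[gi])
      next
    }
    sub <- counts[ids, , drop = FALSE]
    sub <- sub[, colSums(sub) > 0, drop = FALSE]
    gseed <- child_seed(seed, gi)
    bn <- bnti_pairwise(sub, tree, n_null = n_null, seed = gseed,
                        weighted = weighted)
    rc <- rc_bray(sub, n_null = n_null, seed = child_seed(seed, gi + 1000L))
    stopifnot(identical(bn$sample_i, rc$sample_i),
              identical(bn$sample_j, rc$sample_j))
    bn$rc <- rc$rc
    bn$bc_obs <- rc$bc_obs
    bn$process <- classify_process(bn$bnti, bn$rc)
    bn$group <- names(groups)[gi]
    all_pairs[[names(groups)[gi]]] <- bn
  }
  pairs <- do.call(rbind, all_pairs)
  rownames(pairs) <- NULL
  list(pairs = pairs, summary = summarize_processes(pairs, grouping = "group"))
}
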