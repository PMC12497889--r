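# Compositional stability of a community time series: similarity of each time
# point to its predecessor, on depth-aggregated communities within a group
# (typically lake x fraction). The default index is 1 - Bray-Curtis on
# relative abundances, bounded in [0, 1]; 1 - Jaccard (presence-based) and
# Spearman rank correlation of shared-taxon abundances are available to probe
# sensitivity to the index definition.

#' Compositional stability series per group
#'
#' Counts are first summed over all samples sharing (group keys, time point) —
#' e.g., pooling depths within lake x fraction x month — then the stability of
#' each consecutive transition is computed on the aggregated communities.
#' Irregular sampling intervals are used as-is (no interpolation).
#'
#' @param m abundance matrix.
#' @param metadata sample metadata with `sample_id` and the key columns.
#' @param group_keys metadata columns defining one series each
#'   (default c("lake", "fraction")).
#' @param time_key metadata column holding the time point (default "date");
#'   must be orderable.
#' @param method "bray" (1 - Bray-Curtis, default), "jaccard" (1 - Jaccard) or
#'   "spearman" (rank correlation over the union of taxa, clamped to \[0, 1\]).
#' @return object of class `stability_series`: data.frame with columns
#'   `group`, `time_start`, `time_end`, `stability`, plus an `averages`
#'   attribute (named mean stability per group).
#' @export
stability_series <- function(m, metadata, group_keys = c("lake", "fraction"),
                             time_key = "date",
                             method = c("bray", "jaccard", "spearman")) {
  method <- match.arg(method)
  counts <- as_counts(m)
  keys <- c(group_keys, time_key)
  agg <- aggregate_samples(counts, metadata, keys)
  groups <- attr(agg, "groups")
  gid <- do.call(paste, c(lapply(group_keys, function(k) groups[[k]]),
                          sep = "|"))
  out <- list()
  for (grp in unique(gid)) {
    sel <- which(gid == grp)
    tp <- groups[[time_key]][sel]
    ord <- order(tp)
    sel <- sel[ord]; tp <- tp[ord]
    if (length(sel) < 2) {
      warnf("group '%s' has fewer than 2 time points; skipped", grp)
      next
    }
    sub <- relative_abundance(unclass(agg)[sel, , drop = FALSE])
    s <- vapply(seq_len(nrow(sub) - 1), function(t) {
      stability_index(sub[t, ], sub[t + 1, ], method)
    }, numeric(1))
    out[[grp]] <- data.frame(
      group = grp,
      time_start = tp[-length(tp)], time_end = tp[-1],
      stability = s, stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) stopf("no group had at least 2 time points")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  averages <- vapply(split(res$stability, res$group), mean, numeric(1))
  structure(res, class = c("stability_series", "data.frame"),
            averages = averages, method = method)
}

stability_index <- function(x, y, method) {
  switch(method,
    bray = 1 - bray_curtis(x, y, relative = FALSE),
    jaccard = {
      a <- x > 0; b <- y > 0
      sum(a & b) / sum(a | b)
    },
    spearman = {
      keep <- x > 0 | y > 0
      r <- suppressWarnings(cor(x[keep], y[keep], method = "spearman"))
      if (is.na(r)) r <- 1 # identical constant communities
      min(max(r, 0), 1)
    }
  )
}

#' Average stability index per group
#'
#' @param series a [stability_series()] result.
#' @return named numeric vector, mean of the per-transition stabilities.
#' @export
average_stability <- function(series) {
  if (!inherits(series, "stability_series")) stopf("series must be a stability_series")
  attr(series, "averages")
}

#' Map stability values back onto samples
#'
#' Each sample at time t receives the stability of its group's transition
#' ending at t; samples at the first time point receive the first transition's
#' value (convention "carry_back", the default) or NA ("drop_first").
#'
#' @param series a [stability_series()] result.
#' @param metadata sample metadata with `sample_id`, the group keys and time
#'   column used to build the series.
#' @param group_keys,time_key as in [stability_series()].
#' @param first_point "carry_back" or "drop_first".
#' @return data.frame: sample_id, stability.
#' @export
stability_at_samples <- function(series, metadata,
                                 group_keys = c("lake", "fraction"),
                                 time_key = "date",
                                 first_point = c("carry_back", "drop_first")) {
  first_point <- match.arg(first_point)
  gid <- do.call(paste, c(lapply(group_keys, function(k) metadata[[k]]), sep = "|"))
  tp <- metadata[[time_key]]
  s <- rep(NA_real_, nrow(metadata))
  for (i in seq_len(nrow(metadata))) {
    rows <- series$group == gid[i]
    if (!any(rows)) stopf("sample '%s' belongs to no stability group", metadata$sample_id[i])
    hit <- which(rows & series$time_end == tp[i])
    if (length(hit) == 1) {
      s[i] <- series$stability[hit]
    } else if (tp[i] == min(series$time_start[rows])) {
      if (first_point == "carry_back") {
        first <- which(rows)[which.min(series$time_start[rows])]
        s[i] <- series$stability[first]
      }
    } else if (length(hit) == 0) {
      stopf("sample '%s' (time %s) matches no transition in its group",
            metadata$sample_id[i], format(tp[i]))
    }
  }
  data.frame(sample_id = metadata$sample_id, stability = s,
             stringsAsFactors = FALSE)
}

#' Write stability outputs
#'
#' TSV of per-transition stabilities and a JSON summary of the per-group
#' average indices.
#'
#' @param series a [stability_series()] result.
#' @param prefix output path prefix.
#' @return named vector of paths, invisibly.
#' @export
write_stability <- function(series, prefix) {
  tsv <- paste0(prefix, "_series.tsv")
  json <- paste0(prefix, "_summary.json")
  df <- as.data.frame(series)
  df$time_start <- format(df$time_start)
  df$time_end <- format(df$time_end)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(method = attr(series, "method"),
                            average_index = as.list(attr(series, "averages"))),
                       json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(series = tsv, summary = json))
}
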