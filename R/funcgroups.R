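# Functional-group assignment for protistan taxa: autotrophs, mixotrophs,
# parasites, osmotrophs, phagotrophs, plus "unassigned" for taxa no map entry
# covers.

FUNCTIONAL_GROUPS <- c("autotroph", "mixotroph", "parasite", "osmotroph",
                       "phagotroph", "unassigned")

#' Read a functional-group map
#'
#' Two-column TSV: taxonomy label (any rank) and functional group, one of
#' autotroph, mixotroph, parasite, osmotroph, phagotroph.
#'
#' @param path TSV path.
#' @return named character vector (label -> group).
#' @export
read_functional_map <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stopf("functional map needs two columns: label, group")
  map <- setNames(tab[[2]], tab[[1]])
  validate_functional_map(map)
  map
}

validate_functional_map <- function(map) {
  bad <- setdiff(unique(map), FUNCTIONAL_GROUPS)
  if (length(bad) > 0) {
    stopf("illegal functional group name(s): %s (allowed: %s)",
          paste(bad, collapse = ", "), paste(FUNCTIONAL_GROUPS, collapse = ", "))
  }
  invisible(map)
}

#' Assign functional groups from taxonomy strings
#'
#' Each taxon's semicolon-separated taxonomy is matched against the map labels
#' rank by rank; the most specific (deepest) matching rank wins. Taxa with no
#' matching rank are "unassigned".
#'
#' @param taxonomy character vector of taxonomy strings
#'   (e.g. "Eukaryota;Alveolata;Ciliophora;..."), named by taxon id or aligned
#'   with the columns of `m`.
#' @param map named character vector from [read_functional_map()], labels to
#'   groups.
#' @param m optional abundance matrix; when given, per-sample relative
#'   abundance of each group (including unassigned) is also returned.
#' @return list with `groups` (per-taxon factor) and, when `m` is supplied,
#'   `sample_composition` (samples x groups matrix, rows summing to 1).
#' @export
assign_functional_groups <- function(taxonomy, map, m = NULL) {
  validate_functional_map(map)
  groups <- vapply(taxonomy, function(tax) {
    ranks <- trimws(strsplit(tax, ";", fixed = TRUE)[[1]])
    hit <- which(ranks %in% names(map))
    if (length(hit) == 0) "unassigned" else unname(map[[ranks[max(hit)]]])
  }, character(1), USE.NAMES = FALSE)
  groups <- factor(groups, levels = FUNCTIONAL_GROUPS)
  out <- list(groups = groups)
  if (!is.null(m)) {
    rel <- relative_abundance(m)
    if (ncol(rel) != length(groups)) {
      stopf("taxonomy length (%d) does not match number of taxa (%d)",
            length(groups), ncol(rel))
    }
    comp <- t(rowsum(t(rel), group = groups))
    missing <- setdiff(FUNCTIONAL_GROUPS, colnames(comp))
    if (length(missing) > 0) {
      comp <- cbind(comp, matrix(0, nrow(comp), length(missing),
                                 dimnames = list(NULL, missing)))
    }
    out$sample_composition <- comp[, FUNCTIONAL_GROUPS, drop = FALSE]
  }
  out
}
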