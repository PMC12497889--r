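# Independent oracles, deliberately naive: these re-derive the target
# quantities with plain nested loops / enumeration and never share code with
# the production implementations they check.

# betaMNTD by direct translation of the definition: for every present taxon
# in one community, scan all present taxa of the other for the minimum
# patristic distance; average with (re-normalised) abundance weights.
bmntd_bruteforce <- function(x, y, D, weighted = TRUE) {
  ix <- which(x > 0)
  iy <- which(y > 0)
  wx <- if (weighted) x[ix] / sum(x[ix]) else rep(1 / length(ix), length(ix))
  wy <- if (weighted) y[iy] / sum(y[iy]) else rep(1 / length(iy), length(iy))
  sx <- 0
  for (k in seq_along(ix)) {
    dmin <- Inf
    for (l in seq_along(iy)) dmin <- min(dmin, D[ix[k], iy[l]])
    sx <- sx + wx[k] * dmin
  }
  sy <- 0
  for (l in seq_along(iy)) {
    dmin <- Inf
    for (k in seq_along(ix)) dmin <- min(dmin, D[iy[l], ix[k]])
    sy <- sy + wy[l] * dmin
  }
  unname(0.5 * (sx + sy))
}

# All simple directed paths from `from` to `to` in a path-coefficient matrix
# P (P[to, from] != 0 marks an edge); returns the sum over paths of length
# >= 2 of the product of coefficients. Pure enumeration.
indirect_bruteforce <- function(P, from, to) {
  lvs <- rownames(P)
  total <- 0
  walk <- function(node, prod, len, visited) {
    for (nxt in lvs) {
      if (P[nxt, node] != 0 && !(nxt %in% visited)) {
        if (nxt == to) {
          if (len + 1 >= 2) total <<- total + prod * P[nxt, node]
        } else {
          walk(nxt, prod * P[nxt, node], len + 1, c(visited, nxt))
        }
      }
    }
  }
  walk(from, 1, 0, from)
  total
}

# small random abundance matrix with guaranteed nonempty samples
random_counts <- function(n_samples, n_taxa, max_count = 20) {
  m <- matrix(rpois(n_samples * n_taxa, 2), n_samples, n_taxa)
  for (s in seq_len(n_samples)) {
    if (sum(m[s, ]) == 0) m[s, sample(n_taxa, 1)] <- 1L
  }
  dimnames(m) <- list(sprintf("s%02d", seq_len(n_samples)),
                      sprintf("taxon_%04d", seq_len(n_taxa)))
  m
}
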