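# Partial least squares path modelling (mode A / reflective blocks).
# Latent variable scores are estimated by alternating an outer approximation
# (weighted sum of each block's standardized manifest variables) and an inner
# approximation (weighted sum of adjacent latent scores, with centroid, factor
# or path weighting), iterated to convergence; path coefficients are then OLS
# regressions among the latent scores, and GoF = sqrt(mean communality x
# mean R^2).

#' Specify a PLS path model
#'
#' @param blocks named list: latent variable -> character vector of manifest
#'   (column) names. Every manifest variable may appear in exactly one block.
#' @param paths data.frame or 2-column matrix of directed inner edges with
#'   columns `from`, `to` (both latent names). The inner model must be
#'   acyclic.
#' @param scheme inner weighting scheme: "centroid" (sign of score
#'   correlation, default), "factor" (correlation) or "path" (regression
#'   coefficients for predecessors, correlations for successors).
#' @param max_iter,tol outer-weight iteration controls.
#' @return a `plspm_spec` list.
#' @export
plspm_spec <- function(blocks, paths, scheme = c("centroid", "factor", "path"),
                       max_iter = 1000, tol = 1e-6) {
  scheme <- match.arg(scheme)
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stopf("blocks must be a named list")
  }
  if (any(lengths(blocks) == 0)) stopf("every block must be nonempty")
  mvs <- unlist(blocks)
  if (anyDuplicated(mvs)) {
    stopf("manifest variable(s) in more than one block: %s",
          paste(unique(mvs[duplicated(mvs)]), collapse = ", "))
  }
  paths <- as.data.frame(paths, stringsAsFactors = FALSE)
  names(paths)[1:2] <- c("from", "to")
  lvs <- names(blocks)
  bad <- setdiff(c(paths$from, paths$to), lvs)
  if (length(bad) > 0) stopf("unknown latent variable(s) in paths: %s",
                             paste(unique(bad), collapse = ", "))
  inner <- matrix(FALSE, length(lvs), length(lvs), dimnames = list(lvs, lvs))
  inner[cbind(paths$to, paths$from)] <- TRUE # row receives from column
  order <- topo_order(inner)
  structure(list(blocks = blocks, inner = inner, paths = paths,
                 scheme = scheme, max_iter = max_iter, tol = tol,
                 lv_order = order),
            class = "plspm_spec")
}

# Kahn topological sort; errors on cycles. inner[to, from] = TRUE.
topo_order <- function(inner) {
  lvs <- rownames(inner)
  indeg <- rowSums(inner)
  order <- character(0)
  active <- setNames(rep(TRUE, length(lvs)), lvs)
  while (any(active)) {
    ready <- names(which(active & indeg == 0))
    if (length(ready) == 0) stopf("inner model contains a cycle")
    v <- ready[1]
    order <- c(order, v)
    active[v] <- FALSE
    out <- lvs[inner[, v] & active]
    indeg[out] <- indeg[out] - 1
  }
  order
}

#' Fit a PLS path model
#'
#' @param data data.frame containing every manifest variable named in the
#'   spec's blocks.
#' @param spec a [plspm_spec()].
#' @param listwise drop rows with missing manifest values (default FALSE:
#'   missing values are an error).
#' @return object of class `plspm_fit`: list with `outer` (data.frame: mv,
#'   block, weight, loading, communality), `scores` (n x LV matrix, unit
#'   variance), `paths` (data.frame: from, to, coefficient), `path_matrix`,
#'   `r_squared` (named, endogenous LVs), `gof`, `iterations`, `converged`.
#' @export
fit_plspm <- function(data, spec, listwise = FALSE) {
  if (!inherits(spec, "plspm_spec")) stopf("spec must be a plspm_spec")
  mvs <- unlist(spec$blocks, use.names = FALSE)
  missing_cols <- setdiff(mvs, names(data))
  if (length(missing_cols) > 0) {
    stopf("data lacks manifest column(s): %s", paste(missing_cols, collapse = ", "))
  }
  X <- as.matrix(data[, mvs, drop = FALSE])
  if (!is.numeric(X)) stopf("manifest variables must be numeric")
  if (anyNA(X)) {
    if (!listwise) stopf("missing values in manifest variables (set listwise = TRUE to drop rows)")
    X <- X[stats::complete.cases(X), , drop = FALSE]
  }
  n <- nrow(X)
  if (n < 3) stopf("need at least 3 complete rows")
  if (n <= length(mvs)) {
    warnf("n (%d) does not exceed the number of manifest variables (%d)", n, length(mvs))
  }
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    stopf("constant manifest column(s): %s", paste(mvs[sds == 0], collapse = ", "))
  }
  X <- scale(X)
  lvs <- names(spec$blocks)
  K <- length(lvs)
  block_idx <- lapply(spec$blocks, function(b) match(b, mvs))
  adj <- spec$inner | t(spec$inner)
  w <- lapply(block_idx, function(ix) rep(1, length(ix)))
  Y <- sapply(seq_len(K), function(k) {
    y <- X[, block_idx[[k]], drop = FALSE] %*% w[[k]]
    as.numeric(scale(y))
  })
  colnames(Y) <- lvs
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    R <- cor(Y)
    E <- matrix(0, K, K, dimnames = list(lvs, lvs))
    for (k in seq_len(K)) {
      nb <- which(adj[k, ])
      if (length(nb) == 0) next
      E[k, nb] <- switch(spec$scheme,
        centroid = sign(R[k, nb]),
        factor = R[k, nb],
        path = {
          preds <- which(spec$inner[k, ])  # LVs pointing into k
          succs <- setdiff(nb, preds)
          e <- numeric(length(nb))
          names(e) <- lvs[nb]
          if (length(preds) > 0) {
            b <- solve(R[preds, preds, drop = FALSE], R[preds, k])
            e[lvs[preds]] <- b
          }
          if (length(succs) > 0) e[lvs[succs]] <- R[k, succs]
          e
        })
    }
    Z <- Y %*% t(E)
    w_new <- w
    Y_new <- Y
    for (k in seq_len(K)) {
      if (all(E[k, ] == 0)) next # isolated LV keeps its initial weights
      wk <- as.numeric(crossprod(X[, block_idx[[k]], drop = FALSE], Z[, k])) / (n - 1)
      # damped update: same fixed points, but suppresses the sign-flip
      # 2-cycles the centroid scheme can enter when an LV correlation ~ 0;
      # match the new direction to the old one first so the average is stable
      wo <- w[[k]]
      if (sum(wk * wo) < 0) wk <- -wk
      wk <- 0.5 * (wk / sqrt(sum(wk^2)) + wo / sqrt(sum(wo^2)))
      yk <- X[, block_idx[[k]], drop = FALSE] %*% wk
      w_new[[k]] <- wk
      Y_new[, k] <- as.numeric(scale(yk))
    }
    delta <- max(unlist(Map(function(a, b) {
      max(abs(a / sqrt(sum(a^2)) - b / sqrt(sum(b^2))))
    }, w_new, w)))
    w <- w_new
    Y <- Y_new
    if (delta < spec$tol) {
      converged <- TRUE
      break
    }
    if (iter >= spec$max_iter) break
  }
  if (!converged) {
    stop(structure(class = c("plspm_fit_error", "error", "condition"),
                   list(message = sprintf(
                     "PLS-PM outer weights did not converge in %d iterations (last delta %.3g)",
                     spec$max_iter, delta), call = NULL)))
  }
  # orient every LV with its block once (majority-positive loadings), for a
  # deterministic sign convention that does not disturb the iteration
  for (k in seq_len(K)) {
    if (sum(cor(X[, block_idx[[k]], drop = FALSE], Y[, k])) < 0) {
      Y[, k] <- -Y[, k]
      w[[k]] <- -w[[k]]
    }
  }
  loadings <- unlist(lapply(seq_len(K), function(k) {
    as.numeric(cor(X[, block_idx[[k]], drop = FALSE], Y[, k]))
  }))
  outer <- data.frame(
    mv = mvs[unlist(block_idx)],
    block = rep(lvs, lengths(block_idx)),
    weight = unlist(w),
    loading = loadings,
    communality = loadings^2,
    stringsAsFactors = FALSE
  )
  path_matrix <- matrix(0, K, K, dimnames = list(lvs, lvs))
  r_squared <- c()
  for (k in seq_len(K)) {
    preds <- which(spec$inner[k, ])
    if (length(preds) == 0) next
    fitk <- lm(Y[, k] ~ Y[, preds, drop = FALSE])
    path_matrix[k, preds] <- coef(fitk)[-1]
    r_squared[lvs[k]] <- summary(fitk)$r.squared
  }
  paths <- spec$paths
  paths$coefficient <- path_matrix[cbind(paths$to, paths$from)]
  gof <- sqrt(mean(outer$communality) * mean(r_squared))
  structure(list(outer = outer, scores = Y, paths = paths,
                 path_matrix = path_matrix, r_squared = r_squared, gof = gof,
                 spec = spec, n = n, iterations = iter, converged = converged),
            class = "plspm_fit")
}

#' @export
print.plspm_fit <- function(x, ...) {
  cat(sprintf("PLS path model: %d latent variables, %d manifest variables, n = %d\n",
              length(x$spec$blocks), nrow(x$outer), x$n))
  cat(sprintf("  GoF = %.4f; R^2: %s\n", x$gof,
              paste(sprintf("%s %.3f", names(x$r_squared), x$r_squared),
                    collapse = ", ")))
  print(x$paths, row.names = FALSE)
  invisible(x)
}

#' Bootstrap significance of path coefficients
#'
#' Resamples rows with replacement, refits the model and reports the
#' percentile standard error and a two-sided sign-crossing p-value per path:
#' `p = min(1, 2 min(P(b* <= 0), P(b* >= 0)))`. Paths with p < `alpha` are
#' flagged significant (the study convention is alpha = 0.1).
#'
#' Each refit orients every latent variable by its own block
#' (majority-positive loadings), which keeps path signs stable when a real
#' signal is present while letting null paths straddle zero; this makes the
#' sign-crossing test calibrate. `align = "full"` additionally flips each
#' bootstrap latent variable to match the full-data outer weights (via the
#' weight-vector dot product) — useful when a block's loadings are mixed-sign
#' and its orientation is ambiguous, but anti-conservative for null paths, so
#' it is not the default.
#'
#' @param data,spec as in [fit_plspm()].
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param alpha significance level (default 0.1).
#' @param align "none" (default) or "full" (align signs to the full-data
#'   solution).
#' @return data.frame: from, to, coefficient, se, p_value, significant;
#'   attribute `n_failed` counts non-converged replicates.
#' @export
bootstrap_paths <- function(data, spec, n_boot = 1000, seed = NULL, alpha = 0.1,
                            align = c("none", "full")) {
  align <- match.arg(align)
  full <- fit_plspm(data, spec)
  mvs <- unlist(spec$blocks, use.names = FALSE)
  lvs <- names(spec$blocks)
  w_full <- split(full$outer$weight, factor(full$outer$block, levels = lvs))
  np <- nrow(full$paths)
  local_seed(seed, {
    B <- matrix(NA_real_, n_boot, np)
    failed <- 0L
    n <- full$n
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, replace = TRUE)
      fb <- tryCatch(fit_plspm(data[idx, , drop = FALSE], spec),
                     error = function(e) NULL)
      if (is.null(fb)) {
        failed <- failed + 1L
        next
      }
      if (align == "full") {
        w_b <- split(fb$outer$weight, factor(fb$outer$block, levels = lvs))
        flip <- vapply(lvs, function(l) {
          if (sum(w_b[[l]] * w_full[[l]]) < 0) -1 else 1
        }, numeric(1))
        B[b, ] <- fb$paths$coefficient *
          flip[fb$paths$from] * flip[fb$paths$to]
      } else {
        B[b, ] <- fb$paths$coefficient
      }
    }
    if (failed > 0.1 * n_boot) {
      warnf("%d of %d bootstrap replicates failed to converge", failed, n_boot)
    }
    p <- vapply(seq_len(np), function(j) {
      bj <- B[, j][!is.na(B[, j])]
      if (length(bj) == 0) return(NA_real_)
      min(1, 2 * min(mean(bj <= 0), mean(bj >= 0)))
    }, numeric(1))
    out <- data.frame(full$paths,
                      se = apply(B, 2, sd, na.rm = TRUE),
                      p_value = p,
                      significant = !is.na(p) & p < alpha,
                      stringsAsFactors = FALSE)
    attr(out, "n_failed") <- failed
    out
  })
}

#' Direct, indirect and total effects among latent variables
#'
#' Indirect effect = sum over all directed paths of length >= 2 of the product
#' of path coefficients along the path; total = direct + indirect. Computed by
#' powers of the path matrix (finite because the inner model is acyclic).
#'
#' @param fit a `plspm_fit`.
#' @return data.frame: from, to, direct, indirect, total (pairs with any
#'   nonzero effect).
#' @export
indirect_effects <- function(fit) {
  P <- fit$path_matrix # P[to, from]
  K <- nrow(P)
  indirect <- matrix(0, K, K, dimnames = dimnames(P))
  Pk <- P
  for (step in 2:max(2, K - 1)) {
    Pk <- Pk %*% P
    if (all(Pk == 0)) break
    indirect <- indirect + Pk
  }
  total <- P + indirect
  nz <- which(total != 0 | fit$spec$inner, arr.ind = TRUE)
  out <- data.frame(
    from = colnames(P)[nz[, 2]],
    to = rownames(P)[nz[, 1]],
    direct = P[nz],
    indirect = indirect[nz],
    stringsAsFactors = FALSE
  )
  out$total <- out$direct + out$indirect
  out[order(out$from, out$to), , drop = FALSE]
}

#' Default latent-block template for the lake stability path model
#'
#' A reconstruction of a typical environmental-driver layout (editable):
#' salinity {salinity, conductivity}; nutrients {NO3, PO4, NH3, SO4, DOC};
#' physicochemical {temperature, DO, pH, fDOM}; particles {turbidity};
#' richness {richness}; stability {stability}. Every driver points at both
#' richness and stability, and richness points at stability, so drivers can
#' act directly or indirectly through richness.
#'
#' @return list with `blocks` and `paths` ready for [plspm_spec()].
#' @export
default_lake_blocks <- function() {
  blocks <- list(
    salinity = c("salinity", "conductivity"),
    nutrients = c("NO3", "PO4", "NH3", "SO4", "DOC"),
    physicochemical = c("temperature", "DO", "pH", "fDOM"),
    particles = "turbidity",
    richness = "richness",
    stability = "stability"
  )
  drivers <- c("salinity", "nutrients", "physicochemical", "particles")
  paths <- rbind(
    data.frame(from = drivers, to = "richness", stringsAsFactors = FALSE),
    data.frame(from = c(drivers, "richness"), to = "stability",
               stringsAsFactors = FALSE)
  )
  list(blocks = blocks, paths = paths)
}

#' Export a fitted path model as a DOT graph
#'
#' @param fit a `plspm_fit`.
#' @param boot optional [bootstrap_paths()] table; when given, only paths
#'   flagged significant are drawn solid (others dashed).
#' @return a character scalar of DOT source.
#' @export
plspm_dot <- function(fit, boot = NULL) {
  edges <- if (is.null(boot)) {
    cbind(fit$paths, significant = TRUE)
  } else {
    boot
  }
  lines <- c("digraph plspm {", "  rankdir=LR;")
  for (lv in names(fit$spec$blocks)) {
    lines <- c(lines, sprintf('  "%s" [shape=ellipse];', lv))
  }
  for (i in seq_len(nrow(edges))) {
    lines <- c(lines, sprintf(
      '  "%s" -> "%s" [label="%.3f"%s%s];',
      edges$from[i], edges$to[i], edges$coefficient[i],
      if (edges$coefficient[i] < 0) ", color=red" else ", color=blue",
      if (!edges$significant[i]) ", style=dashed" else ""
    ))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Write path-model outputs
#'
#' Path table TSV (from, to, coefficient, p, significant), effects table TSV
#' (direct, indirect, total) and a JSON summary (GoF, R^2, communalities).
#'
#' @param fit a `plspm_fit`.
#' @param boot optional [bootstrap_paths()] table.
#' @param prefix output path prefix.
#' @return named vector of paths, invisibly.
#' @export
write_plspm <- function(fit, boot = NULL, prefix) {
  paths_tsv <- paste0(prefix, "_paths.tsv")
  eff_tsv <- paste0(prefix, "_effects.tsv")
  json <- paste0(prefix, "_summary.json")
  write.table(if (is.null(boot)) fit$paths else boot, paths_tsv,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(indirect_effects(fit), eff_tsv, sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(list(
    gof = fit$gof,
    r_squared = as.list(fit$r_squared),
    communality = setNames(as.list(fit$outer$communality), fit$outer$mv),
    n = fit$n, iterations = fit$iterations, scheme = fit$spec$scheme
  ), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths = paths_tsv, effects = eff_tsv, summary = json))
}
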