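# Sloan neutral community model: detection frequency of a taxon across local
# communities is predicted from its metacommunity mean relative abundance p
# through the stationary beta distribution of local abundance,
#   freq(p) = 1 - pbeta(d; N m p, N m (1 - p)),
# where N is community size, m the immigration rate and d the detection
# limit. Nm is estimated by bounded least squares on the occupancy-abundance
# cloud; fit quality is the generalized R^2 (may be negative).

#' Neutral-model predicted detection frequency (threshold form)
#'
#' The classic approximation: a taxon is detected when its local relative
#' abundance exceeds the detection limit d, so
#' `freq = 1 - pbeta(d, Nm p, Nm (1 - p))`.
#'
#' @param p metacommunity relative abundance(s), strictly inside (0, 1).
#' @param Nm product of community size and immigration rate (> 0).
#' @param d detection limit as a relative abundance in (0, 1); typically 1/N.
#' @return predicted occurrence frequency in \[0, 1\], non-decreasing in `p`.
#' @seealso [predicted_frequency_reads()] for the finite-read form.
#' @export
predicted_frequency <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stopf("p must be strictly inside (0, 1)")
  if (!is.numeric(Nm) || Nm <= 0) stopf("Nm must be > 0")
  if (d <= 0 || d >= 1) stopf("d must be in (0, 1)")
  1 - pbeta(d, Nm * p, Nm * (1 - p))
}

#' Neutral-model predicted detection frequency under finite read sampling
#'
#' When a community with beta-distributed true relative abundance x is
#' observed through N sequencing reads, the probability of detecting a taxon
#' (at least one read) is the beta-binomial zero-class complement
#' `1 - B(a, b + N) / B(a, b)` with `a = Nm p`, `b = Nm (1 - p)`. Unlike the
#' sharp-threshold approximation ([predicted_frequency()]), this accounts for
#' taxa below 1/N that are still sampled occasionally, which otherwise
#' inflates the apparent immigration rate of rare taxa.
#'
#' @param p metacommunity relative abundance(s), strictly inside (0, 1).
#' @param Nm product of community size and immigration rate (> 0).
#' @param N number of reads per sample.
#' @return predicted occurrence frequency in \[0, 1\].
#' @export
predicted_frequency_reads <- function(p, Nm, N) {
  if (any(p <= 0 | p >= 1)) stopf("p must be strictly inside (0, 1)")
  if (!is.numeric(Nm) || Nm <= 0) stopf("Nm must be > 0")
  if (!is.numeric(N) || N < 1) stopf("N must be >= 1")
  a <- Nm * p
  b <- Nm * (1 - p)
  1 - exp(lbeta(a, b + N) - lbeta(a, b))
}

# Least-squares profile over log(Nm): returns list(Nm, sse). Multi-start
# Brent over [1e-3, 1e7] to dodge flat shoulders of the profile.
fit_Nm <- function(p, freq, d, N, detection = "reads", n_starts = 3) {
  sse <- function(logNm) {
    Nm <- exp(logNm)
    pred <- if (detection == "reads") {
      predicted_frequency_reads(p, Nm, N)
    } else {
      1 - pbeta(d, Nm * p, Nm * (1 - p))
    }
    sum((freq - pred)^2)
  }
  lo <- log(1e-3); hi <- log(1e7)
  cuts <- seq(lo, hi, length.out = n_starts + 1)
  best <- NULL
  for (k in seq_len(n_starts)) {
    o <- optim(par = mean(cuts[k:(k + 1)]), fn = sse, method = "Brent",
               lower = cuts[k], upper = cuts[k + 1])
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value)) {
    stop(structure(class = c("ncm_fit_error", "error", "condition"),
                   list(message = "NCM optimizer failed to produce a finite SSE",
                        call = NULL)))
  }
  list(Nm = exp(best$par), sse = best$value)
}

#' Fit the Sloan neutral community model
#'
#' Estimates Nm by bounded nonlinear least squares of observed occurrence
#' frequencies against the model's predicted detection curve, with N taken as
#' the mean sample read total and detection limit d = 1/N (both overridable).
#' The default detection model, "reads" ([predicted_frequency_reads()]),
#' integrates the binomial read-sampling process exactly and recovers the
#' generating m from neutral simulations without bias; "threshold" is the
#' classic sharp-cutoff approximation ([predicted_frequency()]). Uncertainty
#' comes from a taxon-resampling bootstrap (percentile 2.5/97.5 intervals for
#' m and R^2). Taxa never observed (p = 0 or frequency = 0) are excluded:
#' their beta parameters are undefined.
#'
#' @param m abundance matrix (>= 10 samples recommended; a warning is issued
#'   below 10 samples or 20 informative taxa).
#' @param n_bootstrap bootstrap replicates (default 1000).
#' @param seed integer seed for the bootstrap.
#' @param N community size; default mean sample total.
#' @param d detection limit; default 1/N (used by `detection = "threshold"`).
#' @param detection "reads" (finite-read detection, default) or "threshold".
#' @param bootstrap_unit resample "taxa" (the points being fitted; default) or
#'   "samples".
#' @return an object of class `ncm_fit`: list with elements `Nm`, `m`, `N`,
#'   `d`, `r_squared`, `ci_m`, `ci_r_squared`, `n_bootstrap`, and `taxa`
#'   (data.frame: taxon, p, frequency, predicted).
#' @export
fit_ncm <- function(m, n_bootstrap = 1000, seed = NULL, N = NULL, d = NULL,
                    detection = c("reads", "threshold"),
                    bootstrap_unit = c("taxa", "samples")) {
  bootstrap_unit <- match.arg(bootstrap_unit)
  detection <- match.arg(detection)
  counts <- as_counts(m)
  n_samples <- nrow(counts)
  if (n_samples < 2) stopf("need at least 2 samples")
  if (is.null(N)) N <- mean(rowSums(counts))
  if (is.null(d)) d <- 1 / N
  oa <- occupancy_abundance(counts)
  keep <- oa$p > 0 & oa$frequency > 0 & oa$p < 1
  oa <- oa[keep, , drop = FALSE]
  if (n_samples < 10 || nrow(oa) < 20) {
    warnf("NCM fit on %d samples and %d informative taxa; estimates may be unstable",
          n_samples, nrow(oa))
  }
  if (length(unique(oa$p)) < 3) stopf("fewer than 3 distinct abundance values")
  fit <- fit_Nm(oa$p, oa$frequency, d, N, detection)
  sst <- sum((oa$frequency - mean(oa$frequency))^2)
  r2 <- 1 - fit$sse / sst
  boot <- local_seed(seed, {
    res <- matrix(NA_real_, n_bootstrap, 2)
    for (b in seq_len(n_bootstrap)) {
      if (bootstrap_unit == "taxa") {
        idx <- sample.int(nrow(oa), replace = TRUE)
        pb <- oa$p[idx]; fb <- oa$frequency[idx]
        db <- d
      } else {
        sidx <- sample.int(n_samples, replace = TRUE)
        cb <- counts[sidx, , drop = FALSE]
        rownames(cb) <- sprintf("bs_%05d", seq_len(n_samples))
        ob <- occupancy_abundance(cb)
        ob <- ob[ob$p > 0 & ob$frequency > 0 & ob$p < 1, , drop = FALSE]
        pb <- ob$p; fb <- ob$frequency
        db <- 1 / mean(rowSums(cb))
      }
      if (length(unique(pb)) < 3) next
      fb_fit <- fit_Nm(pb, fb, db, N, detection, n_starts = 1)
      sst_b <- sum((fb - mean(fb))^2)
      res[b, ] <- c(fb_fit$Nm / N, 1 - fb_fit$sse / sst_b)
    }
    res
  })
  ci_m <- unname(quantile(boot[, 1], c(0.025, 0.975), na.rm = TRUE))
  ci_r2 <- unname(quantile(boot[, 2], c(0.025, 0.975), na.rm = TRUE))
  predicted <- if (detection == "reads") {
    predicted_frequency_reads(oa$p, fit$Nm, N)
  } else {
    predicted_frequency(oa$p, fit$Nm, d)
  }
  structure(list(
    Nm = fit$Nm, m = fit$Nm / N, N = N, d = d, detection = detection,
    r_squared = r2, ci_m = ci_m, ci_r_squared = ci_r2,
    n_bootstrap = n_bootstrap, n_samples = n_samples,
    taxa = data.frame(oa, predicted = predicted)
  ), class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan neutral community model fit (%d taxa, %d samples)\n",
              nrow(x$taxa), x$n_samples))
  cat(sprintf("  Nm = %.1f  (N = %.1f, m = %.5f [%.5f, %.5f])\n",
              x$Nm, x$N, x$m, x$ci_m[1], x$ci_m[2]))
  cat(sprintf("  R^2 = %.4f [%.4f, %.4f], detection limit d = %.2e\n",
              x$r_squared, x$ci_r_squared[1], x$ci_r_squared[2], x$d))
  invisible(x)
}

#' Partition taxa against the neutral prediction
#'
#' Builds a Wilson score confidence band (at `level`, with n = number of
#' samples) around the fitted frequency curve and labels each taxon "above",
#' "neutral" or "below" according to where its observed frequency falls.
#'
#' @param fit an `ncm_fit`.
#' @param level band confidence level (default 0.95).
#' @return the fit's `taxa` data.frame with added columns `band_lo`,
#'   `band_hi`, `partition`.
#' @export
partition_taxa <- function(fit, level = 0.95) {
  if (!inherits(fit, "ncm_fit")) stopf("fit must be an ncm_fit")
  z <- qnorm(1 - (1 - level) / 2)
  n <- fit$n_samples
  phat <- fit$taxa$predicted
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  lo <- pmax(0, centre - half)
  hi <- pmin(1, centre + half)
  obs <- fit$taxa$frequency
  part <- ifelse(obs > hi, "above", ifelse(obs < lo, "below", "neutral"))
  data.frame(fit$taxa, band_lo = lo, band_hi = hi,
             partition = factor(part, levels = c("below", "neutral", "above")))
}

#' Write NCM outputs
#'
#' Per-taxon TSV (p, observed and predicted frequency, band, partition) and a
#' JSON summary (m, Nm, N, d, R^2, CIs, n_taxa, seed).
#'
#' @param fit an `ncm_fit`.
#' @param prefix output path prefix; writes `<prefix>_taxa.tsv` and
#'   `<prefix>_summary.json`.
#' @param level band level for [partition_taxa()].
#' @param seed seed to record in the summary.
#' @return named vector of the two paths, invisibly.
#' @export
write_ncm <- function(fit, prefix, level = 0.95, seed = NULL) {
  taxa <- partition_taxa(fit, level = level)
  tsv <- paste0(prefix, "_taxa.tsv")
  json <- paste0(prefix, "_summary.json")
  write.table(taxa, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(
    m = fit$m, Nm = fit$Nm, N = fit$N, d = fit$d,
    r_squared = fit$r_squared,
    ci_m = fit$ci_m, ci_r_squared = fit$ci_r_squared,
    n_taxa = nrow(fit$taxa), n_samples = fit$n_samples,
    n_bootstrap = fit$n_bootstrap, seed = seed,
    partition_counts = as.list(table(taxa$partition))
  ), json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(taxa = tsv, summary = json))
}
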