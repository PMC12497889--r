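# Seeded generators for communities with known assembly structure: a Sloan
# neutral metacommunity sampled to finite read depth, selection along an
# environmental gradient with phylogenetically conserved niches, and
# lake-style monthly time series across depths and size fractions. Every
# generator is a pure function of (arguments, seed).

#' Simulate a pure-birth (Yule) phylogeny
#'
#' Ultrametric tree with all branch lengths > 0 and tips labelled
#' `taxon_0001`, `taxon_0002`, ...
#'
#' @param n_taxa number of tips (>= 2).
#' @param seed integer seed.
#' @param birth speciation rate of the pure-birth process.
#' @return an [ape::phylo] object.
#' @export
simulate_tree <- function(n_taxa, seed = NULL, birth = 1) {
  if (!is_count(n_taxa) || n_taxa < 2) stopf("n_taxa must be an integer >= 2")
  local_seed(seed, {
    tree <- ape::rphylo(n_taxa, birth = birth, death = 0)
    tree$tip.label <- sprintf("taxon_%04d", seq_len(n_taxa))
    tree
  })
}

#' Metacommunity relative abundances
#'
#' Long-tailed species-abundance distributions used as the source pool for
#' the neutral sampler: "lognormal" draws abundances from
#' lognormal(meanlog, sdlog) and normalises; "logseries" uses the ranked
#' Fisher series p_k proportional to x^k / k.
#'
#' @param n_taxa number of taxa.
#' @param distribution "lognormal" or "logseries".
#' @param sdlog lognormal shape (default 1.5).
#' @param x logseries parameter in (0, 1).
#' @param seed integer seed (lognormal only; logseries is deterministic).
#' @return numeric vector summing to 1.
#' @export
metacommunity_abundances <- function(n_taxa, distribution = c("lognormal", "logseries"),
                                     sdlog = 1.5, x = 0.99, seed = NULL) {
  distribution <- match.arg(distribution)
  if (!is_count(n_taxa)) stopf("n_taxa must be a positive integer")
  p <- switch(distribution,
    lognormal = local_seed(seed, rlnorm(n_taxa, meanlog = 0, sdlog = sdlog)),
    logseries = {
      if (x <= 0 || x >= 1) stopf("logseries x must be in (0, 1)")
      k <- seq_len(n_taxa)
      x^k / k
    }
  )
  p / sum(p)
}

#' Simulate communities under the Sloan neutral model
#'
#' For each sample, each taxon's local relative abundance is drawn from the
#' stationary distribution of the neutral model, Beta(N m p_i, N m (1 - p_i)),
#' the vector is renormalised across taxa, and N reads are drawn
#' multinomially. This is exactly the distribution [fit_ncm()] assumes, so
#' parameter-recovery tests against it are sharp.
#'
#' @param n_samples number of local communities.
#' @param N community size (reads per sample).
#' @param m immigration rate in (0, 1]: the probability that a death is
#'   replaced from the metacommunity rather than by local reproduction.
#' @param p metacommunity relative abundances (sums to 1), or a distribution
#'   name passed to [metacommunity_abundances()] ("lognormal"/"logseries"),
#'   in which case `n_taxa` is required.
#' @param n_taxa number of taxa when `p` is auto-generated.
#' @param seed integer seed.
#' @return an [abundance_matrix()] with rows summing to N, carrying the
#'   metacommunity vector as attribute `p`.
#' @export
simulate_neutral <- function(n_samples, N, m, p = "lognormal", n_taxa = NULL,
                             seed = NULL) {
  if (!is_count(n_samples)) stopf("n_samples must be a positive integer")
  if (!is_count(N)) stopf("N must be a positive integer")
  if (!is.numeric(m) || length(m) != 1 || m <= 0 || m > 1) {
    stopf("m must be in (0, 1]")
  }
  local_seed(seed, {
    if (is.character(p)) {
      if (is.null(n_taxa)) stopf("n_taxa is required when p is auto-generated")
      p <- metacommunity_abundances(n_taxa, distribution = p)
    }
    if (abs(sum(p) - 1) > 1e-12) stopf("p must sum to 1 (within 1e-12)")
    if (any(p <= 0)) stopf("p must be strictly positive")
    n_taxa <- length(p)
    counts <- matrix(0L, n_samples, n_taxa)
    a <- N * m * p
    b <- N * m * (1 - p)
    for (s in seq_len(n_samples)) {
      x <- rbeta(n_taxa, a, b)
      if (sum(x) == 0) x <- p # rbeta underflow guard for extreme shapes
      counts[s, ] <- rmultinom(1, N, prob = x / sum(x))
    }
    out <- abundance_matrix(counts,
                            sample_ids = sprintf("sample_%03d", seq_len(n_samples)),
                            taxon_ids = sprintf("taxon_%04d", seq_len(n_taxa)))
    attr(out, "p") <- p
    out
  })
}

#' Simulate selection-structured communities along an environmental gradient
#'
#' Niche optima (traits) evolve by Brownian motion on the tree, so they carry
#' phylogenetic signal; traits are then rescaled linearly to span the range of
#' `env` so that the niche breadth `sigma` is expressed in environmental
#' units. The fitness of taxon i in sample j is a Gaussian niche kernel
#' `exp(-(trait_i - env_j)^2 / (2 sigma^2))`; sample counts are multinomial
#' with probabilities proportional to base abundance x fitness.
#'
#' @param tree phylogeny over the taxa (tip labels become taxon ids).
#' @param env numeric environmental value (e.g., salinity) per sample.
#' @param sigma niche breadth (> 0), in units of `env`.
#' @param trait_rate Brownian-motion variance per unit branch length.
#' @param N reads per sample.
#' @param base_p base (selection-free) relative abundances; defaults to a
#'   lognormal metacommunity.
#' @param seed integer seed.
#' @return an [abundance_matrix()] (samples x taxa) with attribute `traits`.
#' @export
simulate_selection <- function(tree, env, sigma, trait_rate = 1, N = 10000,
                               base_p = NULL, seed = NULL) {
  if (!inherits(tree, "phylo")) stopf("tree must be a 'phylo' object")
  n_taxa <- length(tree$tip.label)
  if (n_taxa < 2) stopf("tree must have at least 2 tips")
  if (!is.numeric(sigma) || sigma <= 0) stopf("sigma must be > 0")
  if (!is.numeric(env) || length(env) < 1) stopf("env must be numeric")
  local_seed(seed, {
    traits <- ape::rTraitCont(tree, model = "BM", sigma = sqrt(trait_rate))
    if (diff(range(env)) > 0 && diff(range(traits)) > 0) {
      traits <- (traits - min(traits)) / diff(range(traits)) *
        diff(range(env)) + min(env)
    }
    if (is.null(base_p)) base_p <- metacommunity_abundances(n_taxa)
    if (length(base_p) != n_taxa) stopf("base_p length must match tree tips")
    counts <- matrix(0L, length(env), n_taxa)
    for (j in seq_along(env)) {
      fitness <- exp(-(traits - env[j])^2 / (2 * sigma^2))
      w <- base_p * fitness
      if (sum(w) == 0) w <- base_p
      counts[j, ] <- rmultinom(1, N, prob = w / sum(w))
    }
    out <- abundance_matrix(counts,
                            sample_ids = sprintf("sample_%03d", seq_along(env)),
                            taxon_ids = tree$tip.label)
    attr(out, "traits") <- traits
    out
  })
}

#' Describe a multi-lake monthly sampling campaign
#'
#' @param lakes data.frame with columns `name`, `regime` ("gradient" for a
#'   seasonally salty lake, "stable" otherwise) and optionally `trophic`.
#' @param months strictly increasing vector of sampling dates (>= 2).
#' @param depths_m numeric vector of sampling depths in meters (>= 2 depths).
#' @param fractions size fractions, subset of c("PA", "FL").
#' @return a `lake_scenario` list.
#' @export
lake_scenario <- function(lakes, months, depths_m = c(2, 15),
                          fractions = c("PA", "FL")) {
  if (!is.data.frame(lakes) || !all(c("name", "regime") %in% names(lakes))) {
    stopf("lakes must be a data.frame with columns 'name' and 'regime'")
  }
  bad <- setdiff(lakes$regime, c("gradient", "stable"))
  if (length(bad) > 0) stopf("unknown regime(s): %s", paste(bad, collapse = ", "))
  months <- as.Date(months)
  if (length(months) < 2) stopf("need at least 2 time points")
  if (any(diff(months) <= 0)) stopf("dates must be strictly increasing")
  if (length(depths_m) < 2) stopf("need at least 2 depths")
  bad <- setdiff(fractions, c("PA", "FL"))
  if (length(bad) > 0) stopf("fractions must be 'PA' and/or 'FL'")
  structure(list(lakes = lakes, months = months, depths_m = sort(depths_m),
                 fractions = fractions),
            class = "lake_scenario")
}

#' Simulate a lake community time series with metadata
#'
#' One community per (lake, month, depth, fraction). Latent log abundances
#' follow a random walk whose step size is `turnover`; in "gradient" lakes an
#' additional salinity-coupled shift (also scaled by `turnover`) perturbs a
#' salt-sensitive subset of taxa, so seasonally salty lakes turn over faster.
#' Reads are apportioned deterministically (largest remainder) from the latent
#' composition, so with `turnover = 0` consecutive communities are identical
#' and the stability index is exactly 1. Metadata carries the sonde and
#' chemistry variables used by the path model (salinity, temperature, DO, pH,
#' fDOM, turbidity, conductivity, nutrient ions, DOC).
#'
#' @param scenario a [lake_scenario()].
#' @param n_taxa taxa in the regional pool.
#' @param N reads per community.
#' @param turnover month-to-month drift scale (>= 0); 0 freezes composition.
#' @param salinity_amplitude seasonal salinity amplitude (PSU) in "gradient"
#'   lakes; "stable" lakes stay near freshwater baseline.
#' @param seed integer seed.
#' @return list with `counts` ([abundance_matrix()]) and `metadata`
#'   (data.frame, one row per sample, aligned by `sample_id`).
#' @export
simulate_lake_timeseries <- function(scenario, n_taxa = 120, N = 5000,
                                     turnover = 0.15, salinity_amplitude = 8,
                                     seed = NULL) {
  if (!inherits(scenario, "lake_scenario")) stopf("scenario must be a lake_scenario")
  if (turnover < 0) stopf("turnover must be >= 0")
  local_seed(seed, {
    months <- scenario$months
    n_m <- length(months)
    doy <- as.integer(format(months, "%j"))
    season <- cos(2 * pi * (doy - 200) / 365.25) # peaks near mid-July
    rows <- list()
    meta <- list()
    for (li in seq_len(nrow(scenario$lakes))) {
      lake <- scenario$lakes$name[li]
      regime <- scenario$lakes$regime[li]
      gradient <- regime == "gradient"
      sal_base <- if (gradient) 4 else 0.2
      salinity <- sal_base + (if (gradient) salinity_amplitude * pmax(season, 0) else 0) +
        abs(rnorm(n_m, 0, 0.05))
      temperature <- 12 + 9 * season + rnorm(n_m, 0, 0.5)
      # independent month-level driver processes: nutrients, organic matter and
      # particles fluctuate on their own, so the latent driver blocks are not
      # collinear copies of one seasonal sinusoid
      no3 <- pmax(0.01, 0.8 + 0.3 * cumsum(rnorm(n_m, 0, 0.2)) / sqrt(seq_len(n_m)))
      po4 <- pmax(0.001, 0.05 + rnorm(n_m, 0, 0.012))
      nh3 <- pmax(0.001, 0.04 + rnorm(n_m, 0, 0.01))
      doc <- pmax(0.2, 1.5 + 0.4 * rnorm(n_m))
      fdom <- pmax(0.5, 8 + 1.5 * rnorm(n_m))
      turb <- pmax(0.1, 2 + 0.8 * rnorm(n_m))
      # salt-sensitive loading: half the taxa respond to salinity anomalies
      sal_load <- c(rnorm(ceiling(n_taxa / 2)), rep(0, floor(n_taxa / 2)))
      eta <- rnorm(n_taxa, 0, 1.5) # lake-specific baseline log abundance
      frac_off <- lapply(scenario$fractions, function(f) rnorm(n_taxa, 0, 0.8))
      names(frac_off) <- scenario$fractions
      depth_off <- lapply(scenario$depths_m, function(d) rnorm(n_taxa, 0, 0.3))
      names(depth_off) <- as.character(scenario$depths_m)
      for (t in seq_len(n_m)) {
        if (t > 1) {
          step <- rnorm(n_taxa, 0, 1)
          # salinity enters twice, in raw PSU: salt-sensitive taxa track the
          # level (niche shift proportional to the month's change), and the
          # whole community drifts faster under osmotic stress, so stability
          # dips in the salty summer months of "gradient" lakes
          dsal <- salinity[t] - salinity[t - 1]
          stress <- 1 + 0.08 * salinity[t]
          eta <- eta + turnover * (step * stress + dsal * sal_load)
        }
        for (f in scenario$fractions) {
          for (d in scenario$depths_m) {
            lam <- exp(eta + frac_off[[f]] + depth_off[[as.character(d)]])
            prob <- lam / sum(lam)
            id <- sprintf("%s_%s_d%02d_%s", lake, format(months[t], "%Y%m"), d, f)
            rows[[id]] <- apportion_reads(prob, N)
            meta[[id]] <- data.frame(
              sample_id = id, lake = lake, fraction = f, depth = d,
              date = months[t],
              salinity = round(salinity[t], 3),
              temperature = round(temperature[t] - 0.15 * d, 2),
              DO = round(10 - 0.25 * season[t] * d / max(scenario$depths_m) * 10 +
                           rnorm(1, 0, 0.2), 2),
              pH = round(8 - 0.02 * salinity[t] + rnorm(1, 0, 0.05), 2),
              fDOM = round(fdom[t] + rnorm(1, 0, 0.2), 2),
              turbidity = round(pmax(0.1, turb[t] + rnorm(1, 0, 0.2)), 2),
              conductivity = round(250 + 1400 * salinity[t] + rnorm(1, 0, 10), 1),
              NO3 = round(no3[t] + abs(rnorm(1, 0, 0.02)), 3),
              PO4 = round(po4[t] + abs(rnorm(1, 0, 0.003)), 4),
              NH3 = round(nh3[t] + abs(rnorm(1, 0, 0.005)), 4),
              SO4 = round(10 + 60 * salinity[t] / 30 + rnorm(1, 0, 0.5), 2),
              DOC = round(doc[t] + abs(rnorm(1, 0, 0.05)), 3),
              stringsAsFactors = FALSE
            )
          }
        }
      }
    }
    counts <- do.call(rbind, rows)
    rownames(counts) <- names(rows)
    colnames(counts) <- sprintf("taxon_%04d", seq_len(n_taxa))
    metadata <- do.call(rbind, meta)
    rownames(metadata) <- NULL
    list(counts = abundance_matrix(counts), metadata = metadata)
  })
}

# Largest-remainder apportionment of N reads to probabilities `prob`:
# deterministic, sums exactly to N.
apportion_reads <- function(prob, N) {
  raw <- prob * N
  base <- floor(raw)
  rem <- N - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}
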