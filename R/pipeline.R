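# Config-driven pipeline: simulate (or load) -> NCM -> null models ->
# stability -> PLS-PM, with per-stage outputs under a run directory and a
# JSON run manifest (config snapshot, per-stage seeds, checksums, row counts,
# warnings) written last.

pipeline_schema <- list(
  seed = NULL, out_dir = NULL,
  simulate = c("n_taxa", "reads_per_sample", "turnover", "salinity_amplitude",
               "lakes", "months", "start_date", "depths_m", "fractions"),
  inputs = c("abundance", "tree", "metadata"),
  ncm = c("enabled", "n_bootstrap", "group_by"),
  nullmodels = c("enabled", "n_null", "group_by", "weighted"),
  stability = c("enabled", "method", "group_keys", "time_key"),
  plspm = c("enabled", "n_bootstrap", "per_lake", "scheme", "alpha")
)

validate_config <- function(config) {
  errors <- character(0)
  unknown <- setdiff(names(config), names(pipeline_schema))
  if (length(unknown) > 0) {
    errors <- c(errors, sprintf("unknown config key(s): %s",
                                paste(unknown, collapse = ", ")))
  }
  for (section in intersect(names(config), names(pipeline_schema))) {
    allowed <- pipeline_schema[[section]]
    if (is.null(allowed) || !is.list(config[[section]])) next
    bad <- setdiff(names(config[[section]]), allowed)
    if (length(bad) > 0) {
      errors <- c(errors, sprintf("unknown key(s) in '%s': %s", section,
                                  paste(bad, collapse = ", ")))
    }
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    errors <- c(errors, "config needs either a 'simulate' or an 'inputs' section")
  }
  if (length(errors) > 0) {
    stopf("invalid configuration:\n  - %s", paste(errors, collapse = "\n  - "))
  }
  invisible(config)
}

#' Run the full community-assembly pipeline
#'
#' Executes, in dependency order: data simulation (or loading), the Sloan
#' neutral-model fit, betaNTI/RCbray null models with process classification,
#' the compositional stability series, and per-lake PLS path models linking
#' environment and richness to stability. Any analysis stage can be disabled
#' with `enabled: false` in its config section. All outputs are plain TSV/JSON
#' under `out_dir`; the run manifest is written last.
#'
#' @param config path to a YAML config file, or an equivalent named list. See
#'   the packaged demo: `system.file("extdata", "demo_config.yaml",
#'   package = "lakeassembly")`.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param seed root seed (overrides the config's `seed`); per-stage seeds are
#'   derived deterministically from it.
#' @return the run manifest, invisibly (also written to
#'   `<out_dir>/manifest.json`).
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) stopf("no output directory given (config out_dir or argument)")
  if (is.null(seed)) seed <- config$seed
  if (is.null(seed)) seed <- 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  warnings_log <- character(0)
  manifest <- list(config = config, seed = seed,
                   version = as.character(utils::packageVersion("lakeassembly")),
                   stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }
  run_stage <- function(stage, expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, conditionMessage(w)))
      invokeRestart("muffleWarning")
    })
  }

  # --- data ---------------------------------------------------------------
  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  data_seed <- child_seed(seed, 1L)
  if (!is.null(config$simulate)) {
    sim <- config$simulate
    lakes <- do.call(rbind, lapply(sim$lakes, function(l) {
      data.frame(name = l$name, regime = l$regime, stringsAsFactors = FALSE)
    }))
    n_months <- if (is.null(sim$months)) 12L else as.integer(sim$months)
    start <- as.Date(if (is.null(sim$start_date)) "2021-05-01" else sim$start_date)
    months <- seq(start, by = "month", length.out = n_months)
    scenario <- lake_scenario(
      lakes, months,
      depths_m = if (is.null(sim$depths_m)) c(2, 15) else unlist(sim$depths_m),
      fractions = if (is.null(sim$fractions)) c("PA", "FL") else unlist(sim$fractions)
    )
    ts <- run_stage("simulate", simulate_lake_timeseries(
      scenario,
      n_taxa = if (is.null(sim$n_taxa)) 120 else sim$n_taxa,
      N = if (is.null(sim$reads_per_sample)) 5000 else sim$reads_per_sample,
      turnover = if (is.null(sim$turnover)) 0.15 else sim$turnover,
      salinity_amplitude = if (is.null(sim$salinity_amplitude)) 8 else sim$salinity_amplitude,
      seed = data_seed
    ))
    counts <- ts$counts
    metadata <- ts$metadata
    tree <- simulate_tree(ncol(counts), seed = child_seed(seed, 2L))
  } else {
    counts <- read_abundance(config$inputs$abundance)
    metadata <- read_metadata(config$inputs$metadata)
    tree <- ape::read.tree(config$inputs$tree)
  }
  counts_path <- file.path(data_dir, "counts.tsv")
  meta_path <- file.path(data_dir, "metadata.csv")
  tree_path <- file.path(data_dir, "tree.nwk")
  write_abundance(counts, counts_path)
  write_metadata(metadata, meta_path)
  ape::write.tree(tree, tree_path)
  note("data", seed = data_seed,
       outputs = c(counts_path, meta_path, tree_path),
       n_samples = nrow(counts), n_taxa = ncol(counts),
       checksums = as.list(tools::md5sum(c(counts_path, meta_path, tree_path))))

  enabled <- function(section) {
    s <- config[[section]]
    is.null(s) || is.null(s$enabled) || isTRUE(s$enabled)
  }

  # --- ncm ----------------------------------------------------------------
  if (enabled("ncm")) {
    ncm_dir <- file.path(out_dir, "ncm")
    dir.create(ncm_dir, showWarnings = FALSE)
    ncm_seed <- child_seed(seed, 3L)
    nb <- config$ncm$n_bootstrap
    if (is.null(nb)) nb <- 1000L
    fit <- run_stage("ncm", fit_ncm(counts, n_bootstrap = nb, seed = ncm_seed))
    paths <- write_ncm(fit, file.path(ncm_dir, "ncm"), seed = ncm_seed)
    note("ncm", seed = ncm_seed, outputs = unname(paths),
         m = fit$m, r_squared = fit$r_squared, n_taxa = nrow(fit$taxa))
  }

  # --- null models ----------------------------------------------------------
  if (enabled("nullmodels")) {
    nm_dir <- file.path(out_dir, "nullmodels")
    dir.create(nm_dir, showWarnings = FALSE)
    nm <- config$nullmodels
    nm_seed <- child_seed(seed, 4L)
    n_null <- if (is.null(nm$n_null)) 999L else as.integer(nm$n_null)
    group_by <- if (is.null(nm$group_by)) c("lake", "fraction") else unlist(nm$group_by)
    res <- run_stage("nullmodels", assembly_analysis(
      counts, tree, metadata, group_by = group_by, n_null = n_null,
      seed = nm_seed,
      weighted = if (is.null(nm$weighted)) TRUE else isTRUE(nm$weighted)
    ))
    pairs_path <- file.path(nm_dir, "pairs.tsv")
    summary_path <- file.path(nm_dir, "process_summary.tsv")
    write.table(res$pairs, pairs_path, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$summary, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(seed = nm_seed, n_null = n_null,
                              group_by = group_by),
                         file.path(nm_dir, "run_settings.json"),
                         auto_unbox = TRUE, digits = NA)
    note("nullmodels", seed = nm_seed,
         outputs = c(pairs_path, summary_path), n_pairs = nrow(res$pairs))
  }

  # --- stability ------------------------------------------------------------
  stab_samples <- NULL
  if (enabled("stability")) {
    st_dir <- file.path(out_dir, "stability")
    dir.create(st_dir, showWarnings = FALSE)
    st <- config$stability
    method <- if (is.null(st$method)) "bray" else st$method
    group_keys <- if (is.null(st$group_keys)) c("lake", "fraction") else unlist(st$group_keys)
    time_key <- if (is.null(st$time_key)) "date" else st$time_key
    series <- run_stage("stability", stability_series(
      counts, metadata, group_keys = group_keys, time_key = time_key,
      method = method))
    paths <- write_stability(series, file.path(st_dir, "stability"))
    stab_samples <- stability_at_samples(series, metadata,
                                         group_keys = group_keys,
                                         time_key = time_key)
    note("stability", outputs = unname(paths),
         n_transitions = nrow(series),
         average_index = as.list(average_stability(series)))
  }

  # --- plspm ----------------------------------------------------------------
  if (enabled("plspm") && !is.null(stab_samples)) {
    pl_dir <- file.path(out_dir, "plspm")
    dir.create(pl_dir, showWarnings = FALSE)
    pl <- config$plspm
    template <- default_lake_blocks()
    spec <- plspm_spec(template$blocks, template$paths,
                       scheme = if (is.null(pl$scheme)) "centroid" else pl$scheme)
    df <- metadata
    df$richness <- richness(counts)[match(df$sample_id, rownames(counts))]
    df$stability <- stab_samples$stability[match(df$sample_id, stab_samples$sample_id)]
    nb <- if (is.null(pl$n_bootstrap)) 1000L else as.integer(pl$n_bootstrap)
    alpha <- if (is.null(pl$alpha)) 0.1 else pl$alpha
    per_lake <- if (is.null(pl$per_lake)) TRUE else isTRUE(pl$per_lake)
    lakes <- if (per_lake) unique(df$lake) else "all"
    pl_summary <- list()
    for (li in seq_along(lakes)) {
      sub <- if (per_lake) df[df$lake == lakes[li], , drop = FALSE] else df
      pl_seed <- child_seed(seed, 5L + li)
      fit <- run_stage("plspm", fit_plspm(sub, spec))
      boot <- run_stage("plspm", bootstrap_paths(sub, spec, n_boot = nb,
                                                 seed = pl_seed, alpha = alpha))
      paths <- write_plspm(fit, boot, file.path(pl_dir, lakes[li]))
      writeLines(plspm_dot(fit, boot), file.path(pl_dir, paste0(lakes[li], ".dot")))
      pl_summary[[lakes[li]]] <- list(gof = fit$gof, seed = pl_seed,
                                      outputs = unname(paths))
    }
    note("plspm", models = pl_summary, n_bootstrap = nb, alpha = alpha)
  }

  manifest$warnings <- warnings_log
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
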