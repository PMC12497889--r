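#' Read an abundance table from TSV or BIOM v1
#'
#' TSV layout: one header row of taxon ids, one id column of sample ids
#' (samples as rows). Tables written taxa-as-rows (the QIIME "#OTU ID"
#' convention, which BIOM shares) are transposed automatically when
#' `orientation = "auto"`: a first header cell of `#OTU ID`, `OTU ID`,
#' `taxon` or `taxon_id` marks taxa-as-rows.
#'
#' @param path file path.
#' @param format "auto" (by extension), "tsv" or "biom" (BIOM v1 JSON).
#' @param orientation "auto", "samples_rows" or "taxa_rows" (TSV only;
#'   BIOM v1 is taxa x samples by definition).
#' @return an [abundance_matrix()].
#' @export
read_abundance <- function(path, format = c("auto", "tsv", "biom"),
                           orientation = c("auto", "samples_rows", "taxa_rows")) {
  format <- match.arg(format)
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("reading BIOM requires the 'biomformat' package")
    }
    b <- biomformat::read_biom(path)
    m <- as(biomformat::biom_data(b), "matrix") # taxa x samples
    return(validate_counts_table(t(m), path))
  }
  first <- readLines(path, n = 1L)
  corner <- sub("\t.*$", "", first)
  taxa_rows <- switch(orientation,
    samples_rows = FALSE,
    taxa_rows = TRUE,
    auto = tolower(corner) %in% c("#otu id", "otu id", "otu_id", "taxon", "taxon_id")
  )
  tab <- read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                    check.names = FALSE, comment.char = "", quote = "")
  m <- as.matrix(tab)
  if (taxa_rows) m <- t(m)
  validate_counts_table(m, path)
}

validate_counts_table <- function(m, path) {
  if (!is.numeric(m)) {
    bad <- which(!apply(m, 2, function(col) all(grepl("^\\s*-?[0-9.eE+-]+\\s*$", col))))
    stopf("non-numeric cell(s) in %s (e.g. column '%s')", path,
          colnames(m)[bad[1]])
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    stopf("negative count in %s at row '%s', column '%s'", path,
          rownames(m)[neg[1, 1]], colnames(m)[neg[1, 2]])
  }
  if (any(m != round(m))) {
    warnf("non-integer abundances in %s were rounded", path)
    m <- round(m)
  }
  abundance_matrix(m)
}

#' Write an abundance table
#'
#' TSV is written samples-as-rows with a `sample_id` id column; BIOM v1 JSON
#' follows the format's taxa-as-rows convention.
#'
#' @param m abundance matrix.
#' @param path output path.
#' @param format "tsv" or "biom".
#' @return `path`, invisibly.
#' @export
write_abundance <- function(m, path, format = c("tsv", "biom")) {
  format <- match.arg(format)
  m <- as_counts(m)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      stopf("writing BIOM requires the 'biomformat' package")
    }
    b <- biomformat::make_biom(t(m))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata
#'
#' CSV with one row per sample. Requires a `sample_id` column; a `date`
#' column, when present, must be ISO-8601 (YYYY-MM-DD) and is parsed to Date.
#' A `fraction` column, when present, must contain only "PA"
#' (particle-associated) or "FL" (free-living).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  md <- read.table(path, header = TRUE, sep = ",", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(md)) stopf("metadata lacks a 'sample_id' column")
  if (anyDuplicated(md$sample_id)) stopf("duplicate sample_id in metadata")
  if ("date" %in% names(md)) {
    d <- as.Date(md$date, format = "%Y-%m-%d")
    if (anyNA(d) && !anyNA(md$date)) stopf("dates must be ISO-8601 (YYYY-MM-DD)")
    md$date <- d
  }
  if ("fraction" %in% names(md)) {
    bad <- setdiff(unique(md$fraction), c("PA", "FL"))
    if (length(bad) > 0) stopf("invalid fraction value(s): %s", paste(bad, collapse = ", "))
  }
  md
}

#' Write sample metadata as CSV with ISO-8601 dates
#' @param metadata data.frame with a `sample_id` column.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  md <- metadata
  if ("date" %in% names(md)) md$date <- format(as.Date(md$date), "%Y-%m-%d")
  write.table(md, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
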