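#' Read and write band tables as tab-delimited text
#'
#' The band-table schema is one row per blot x lane x protein with columns
#' `blot_id`, `lane_id`, `animal_id`, `group`, `protein`, `raw_density`
#' (plus any extras, e.g. `background_level`, which round-trip untouched).
#' Reading validates the schema and the strict positivity of densities;
#' `read_band_table(write_band_table(x))` returns the same table.
#'
#' @param path file path.
#' @param x a band-table data frame.
#' @return `read_band_table()` returns a `band_table`; `write_band_table()`
#'   returns `path` invisibly.
#' @export
read_band_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("blot_id", "lane_id", "animal_id", "group", "protein", "raw_density")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("band table lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(tab) > 0L) {
    if (!is.numeric(tab$raw_density)) stop("`raw_density` must be numeric")
    bad <- which(!is.finite(tab$raw_density) | tab$raw_density <= 0)
    if (length(bad) > 0L) {
      stop("non-positive or non-finite raw_density in row(s): ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  for (col in need[1:5]) tab[[col]] <- as.character(tab[[col]])
  class(tab) <- c("band_table", "data.frame")
  tab
}

#' @rdname read_band_table
#' @export
write_band_table <- function(x, path) {
  write_tsv(x, path)
}

# deterministic TSV writer (no quoting, no row names, C locale numbers)
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write ROI tables
#'
#' ROI tables are tab-delimited with columns `blot_id`, `protein`,
#' `lane_id`, `x0`, `y0`, `width`, `height` (0-based pixel coordinates,
#' half-open extents).
#'
#' @param path file path.
#' @param rois ROI data frame.
#' @export
read_roi_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("blot_id", "protein", "lane_id", "x0", "y0", "width", "height")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) {
    stop("ROI table lacks column(s): ", paste(miss, collapse = ", "))
  }
  tab
}

#' @rdname read_roi_table
#' @export
write_roi_table <- function(rois, path) {
  write_tsv(rois, path)
}

#' Write a study-result bundle to a directory
#'
#' Writes tab-delimited tables (`band_table.tsv`, `normalized.tsv`,
#' `group_summaries.tsv`, `indices.tsv`, `index_summaries.tsv`,
#' `comparisons.tsv`, `comparison_table.tsv`, `qc.tsv`) and a
#' `provenance.yaml` recording seed, Monte-Carlo settings and normalization
#' steps. Output bytes depend only on the bundle, so identical config + seed
#' gives byte-identical files.
#'
#' @param bundle a [run_study()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$band_table, file.path(dir, "band_table.tsv"))
  write_tsv(bundle$normalized, file.path(dir, "normalized.tsv"))
  write_tsv(bundle$summaries, file.path(dir, "group_summaries.tsv"))
  write_tsv(bundle$indices, file.path(dir, "indices.tsv"))
  write_tsv(bundle$index_summaries, file.path(dir, "index_summaries.tsv"))
  cmp <- bundle$comparisons
  cmp$stars <- significance_stars(cmp$p_empirical)
  write_tsv(cmp, file.path(dir, "comparisons.tsv"))
  write_tsv(bundle$comparison_table, file.path(dir, "comparison_table.tsv"))
  qc <- if (is.null(bundle$qc$comparisons)) {
    data.frame(pass = bundle$qc$pass)
  } else {
    data.frame(bundle$qc$comparisons, pass = bundle$qc$pass)
  }
  write_tsv(qc, file.path(dir, "qc.tsv"))
  yaml::write_yaml(bundle$provenance, file.path(dir, "provenance.yaml"))
  invisible(dir)
}
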