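#' Read a prey count table and its sample metadata
#'
#' Count tables are tab-separated, UTF-8, with a first column of prey
#' identifiers and one column per sample; the metadata file maps each
#' `sample_id` to its bait, condition and replicate. This matches the layout
#' of upstream Y2H-NGIS quantification pipelines.
#'
#' @param path Path to the TSV count table.
#' @param meta_path Path to the TSV metadata table (`sample_id`, `bait`,
#'   `condition`, `replicate`).
#' @param normalized_by Normalization recorded for the values (default
#'   `"none"`, i.e. raw integer counts).
#' @return A [y2h_counts] object; samples ordered as in the metadata file.
#' @export
read_counts <- function(path, meta_path, normalized_by = "none") {
  if (!file.exists(path)) abort(paste0("count file not found: ", path))
  if (!file.exists(meta_path)) {
    abort(paste0("metadata file not found: ", meta_path))
  }
  counts <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE, progress = FALSE)
  y2h_counts(counts, meta, normalized_by = normalized_by)
}

#' Write a prey count table (and optionally its metadata) to TSV
#'
#' @param x A [y2h_counts] object.
#' @param path Output TSV path for the counts.
#' @param meta_path Optional output TSV path for the sample metadata.
#' @return `x`, invisibly.
#' @export
write_counts <- function(x, path, meta_path = NULL) {
  readr::write_tsv(as_tibble(as.data.frame(x)), path, progress = FALSE)
  if (!is.null(meta_path)) {
    readr::write_tsv(sample_meta(x), meta_path, progress = FALSE)
  }
  invisible(x)
}

#' Read a long-format fusion-read table
#'
#' One row per (prey, sample) giving the number of in-frame fusion reads
#' (`inframe_reads`) out of the total fusion reads (`fusion_reads`) spanning
#' the prey-vector junction. Preys absent from the table are treated as
#' having no fusion reads downstream.
#'
#' @param path Path to a TSV with columns `prey`, `sample_id`,
#'   `inframe_reads`, `fusion_reads`.
#' @return A validated tibble.
#' @export
read_fusion <- function(path) {
  if (!file.exists(path)) abort(paste0("fusion file not found: ", path))
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_fusion(x)
}

validate_fusion <- function(x) {
  x <- as_tibble(x)
  need <- c("prey", "sample_id", "inframe_reads", "fusion_reads")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    abort(paste0("fusion table lacks columns: ", paste(miss, collapse = ", ")))
  }
  x <- x[, need]
  x$prey <- as.character(x$prey)
  x$sample_id <- as.character(x$sample_id)
  y <- x$inframe_reads
  f <- x$fusion_reads
  if (anyNA(y) || anyNA(f) || any(y != round(y)) || any(f != round(f))) {
    abort("fusion read counts must be non-missing integers")
  }
  if (any(y < 0) || any(f < 0)) abort("fusion read counts must be >= 0")
  if (any(y > f)) {
    bad <- which(y > f)[1]
    abort(paste0(
      "in-frame reads exceed total fusion reads for prey '", x$prey[bad],
      "', sample '", x$sample_id[bad], "'"
    ))
  }
  x
}

#' Write a fusion-read table to TSV
#'
#' @param x A fusion tibble as returned by [read_fusion()].
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_fusion <- function(x, path) {
  readr::write_tsv(validate_fusion(x), path, progress = FALSE)
  invisible(x)
}

#' Write a score table to TSV
#'
#' Rows are ordered by bait and then by descending Borda ensemble (prey
#' identifier as final tie-break), so output files are deterministic.
#'
#' @param x A score table from [compute_scores()] (or any tibble with
#'   `bait`, `prey`, `enrichment`, `specificity`, `inframe`, `borda`).
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_scores <- function(x, path) {
  cols <- c("bait", "prey", "enrichment", "specificity", "inframe", "borda")
  keep <- intersect(cols, names(x))
  out <- as_tibble(as.data.frame(x))[, keep]
  if ("borda" %in% keep) {
    out <- arrange(out, .data$bait, dplyr::desc(.data$borda), .data$prey)
  } else {
    out <- arrange(out, .data$bait, .data$prey)
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(x)
}

#' Read a score table written by [write_scores()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) abort(paste0("score file not found: ", path))
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
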