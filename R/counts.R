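#' Prey count table with sample metadata
#'
#' The central container of the package: a tibble whose first column `prey`
#' holds unique prey identifiers and whose remaining columns hold one sample
#' each (non-negative counts). Per-sample metadata (bait, condition,
#' replicate) travels alongside as the `meta` attribute, so that grouping by
#' bait and condition is always unambiguous rather than encoded in column
#' names.
#'
#' @param counts A data frame with a `prey` character column followed by one
#'   numeric column per sample.
#' @param meta A data frame with columns `sample_id`, `bait`, `condition`
#'   (`"selected"` or `"non_selected"`) and `replicate` (positive integer).
#'   An optional logical `pseudo` column flags duplicated pseudo-replicates.
#'   Sample order of the container follows the metadata row order.
#' @param normalized_by Which normalization produced the values: `"none"`
#'   (raw integer counts) or one of `"library_size"`, `"tpm"`,
#'   `"median_of_ratios"`, `"ruvs"`.
#'
#' @return A `y2h_counts` tibble.
#' @export
y2h_counts <- function(counts, meta, normalized_by = "none") {
  counts <- as_tibble(counts)
  meta <- as_tibble(meta)
  normalized_by <- match.arg(
    normalized_by,
    c("none", "library_size", "tpm", "median_of_ratios", "ruvs")
  )
  need <- c("sample_id", "bait", "condition", "replicate")
  if (!all(need %in% names(meta))) {
    abort(paste0(
      "metadata must have columns ",
      paste(need, collapse = ", ")
    ))
  }
  if (!"pseudo" %in% names(meta)) meta$pseudo <- FALSE
  meta <- meta[, c(need, "pseudo")]
  meta$sample_id <- as.character(meta$sample_id)
  meta$bait <- as.character(meta$bait)
  meta$replicate <- as.integer(meta$replicate)
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicated sample_id in metadata")
  }
  bad_cond <- setdiff(unique(meta$condition), c("selected", "non_selected"))
  if (length(bad_cond)) {
    abort(paste0(
      "condition must be 'selected' or 'non_selected', found: ",
      paste(bad_cond, collapse = ", ")
    ))
  }
  if (any(meta$replicate < 1L)) abort("replicate indices must be positive")
  if (names(counts)[1] != "prey") {
    names(counts)[1] <- "prey"
  }
  counts$prey <- as.character(counts$prey)
  if (anyDuplicated(counts$prey)) abort("prey identifiers must be unique")
  missing_samples <- setdiff(meta$sample_id, names(counts)[-1])
  if (length(missing_samples)) {
    abort(paste0(
      "samples in metadata but not in count table: ",
      paste(missing_samples, collapse = ", ")
    ))
  }
  orphan <- setdiff(names(counts)[-1], meta$sample_id)
  if (length(orphan)) {
    abort(paste0(
      "sample missing from metadata: ",
      paste(orphan, collapse = ", ")
    ))
  }
  counts <- counts[, c("prey", meta$sample_id)]
  m <- as.matrix(counts[, -1])
  if (!is.numeric(m)) abort("counts must be numeric")
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort(paste0(
      "non-numeric or missing count at prey '", counts$prey[bad[1]],
      "', sample '", meta$sample_id[bad[2]], "'"
    ))
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(paste0(
      "negative count at prey '", counts$prey[bad[1]],
      "', sample '", meta$sample_id[bad[2]], "'"
    ))
  }
  if (normalized_by == "none" && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    abort(paste0(
      "raw counts must be integers; fractional value at prey '",
      counts$prey[bad[1]], "', sample '", meta$sample_id[bad[2]], "'"
    ))
  }
  structure(
    counts,
    meta = meta,
    normalized_by = normalized_by,
    class = c("y2h_counts", class(tibble()))
  )
}

#' Extract sample metadata from a count container
#'
#' @param x A [y2h_counts] object.
#' @return A tibble with one row per sample.
#' @export
sample_meta <- function(x) {
  attr(x, "meta", exact = TRUE)
}

#' Extract the numeric prey-by-sample matrix
#'
#' @param x A [y2h_counts] object.
#' @return A numeric matrix with prey identifiers as row names.
#' @export
count_matrix <- function(x) {
  m <- as.matrix(as.data.frame(x)[, -1, drop = FALSE])
  rownames(m) <- x$prey
  m
}

#' Which normalization produced these counts?
#'
#' @param x A [y2h_counts] object.
#' @return A string, `"none"` for raw counts.
#' @export
normalized_by <- function(x) {
  attr(x, "normalized_by", exact = TRUE) %||% "none"
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.y2h_counts <- function(x, ...) {
  meta <- sample_meta(x)
  cat(
    "<y2h_counts> ", nrow(x), " preys x ", nrow(meta), " samples (",
    length(unique(meta$bait)), " baits; normalization: ",
    normalized_by(x), ")\n",
    sep = ""
  )
  NextMethod()
}

# rebuild the container around a modified matrix, keeping metadata
replace_counts <- function(x, m, normalized_by) {
  out <- tibble(prey = x$prey)
  out <- bind_cols(out, as_tibble(m, .name_repair = "minimal"))
  names(out) <- c("prey", sample_meta(x)$sample_id)
  y2h_counts(out, sample_meta(x), normalized_by = normalized_by)
}
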