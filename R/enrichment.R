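#' Differential enrichment of preys under selection
#'
#' For each bait, fits per-prey negative binomial Wald contrasts of the
#' selected against the non-selected samples of that bait. Raw counts enter
#' the model with per-sample size factors as offsets; counts are never
#' pre-divided. Per-prey dispersions are estimated by method of moments and
#' moderated toward a parametric mean-dispersion trend (floor `1e-8`).
#' Preys with zero counts everywhere get `log2fc = 0` and a missing
#' p-value.
#'
#' @param x A [y2h_counts] object. If it holds normalized (non-integer)
#'   values they are rounded to the nearest integer with a warning and unit
#'   size factors are used.
#' @param baits Baits to fit (default: all baits in the metadata).
#' @param size_factor_method Normalization whose size factors act as
#'   offsets, `"library_size"` (default) or `"median_of_ratios"`.
#' @param size_factors Optional explicit named per-sample size factors,
#'   overriding `size_factor_method`.
#' @return A tibble with one row per (bait, prey): `bait`, `prey`,
#'   `log2fc` (selected over non-selected), `pvalue` (Wald), `base_mean`,
#'   `dispersion`.
#' @export
fit_enrichment <- function(x, baits = NULL,
                           size_factor_method = "library_size",
                           size_factors = NULL) {
  prep <- prepare_nb_input(x, size_factor_method, size_factors)
  meta <- sample_meta(x)
  if (is.null(baits)) baits <- unique(meta$bait)
  miss <- setdiff(baits, meta$bait)
  if (length(miss)) {
    abort(paste0("bait not in metadata: ", paste(miss, collapse = ", ")))
  }
  map_dfr(baits, function(b) {
    idx_s <- which(meta$bait == b & meta$condition == "selected")
    idx_n <- which(meta$bait == b & meta$condition == "non_selected")
    if (length(idx_s) < 2 || length(idx_n) < 2) {
      abort(paste0(
        "bait '", b, "' needs >= 2 replicates per condition; ",
        "see make_pseudo_replicates() for singleton groups"
      ))
    }
    check_library(prep$z, c(idx_s, idx_n), b)
    mutate(nb_wald(prep$z, prep$sf, idx_s, idx_n), bait = b, .before = 1)
  })
}

#' Pairwise specificity contrasts between selected baits
#'
#' Fits, for every ordered pair of baits (i, j), the per-prey negative
#' binomial Wald contrast of prey counts with bait i over bait j, both
#' restricted to selected samples. Only unordered pairs are fit; the
#' reverse direction is filled in by antisymmetry of the log fold-change
#' (the p-value is shared). Same dispersion-moderation contract as
#' [fit_enrichment()].
#'
#' @inheritParams fit_enrichment
#' @return A tibble with one row per ordered (bait, bait_other, prey):
#'   `bait`, `bait_other`, `prey`, `log2fc`, `pvalue`, `base_mean`,
#'   `dispersion`.
#' @export
fit_specificity_pairs <- function(x, baits = NULL,
                                  size_factor_method = "library_size",
                                  size_factors = NULL) {
  prep <- prepare_nb_input(x, size_factor_method, size_factors)
  meta <- sample_meta(x)
  if (is.null(baits)) baits <- unique(meta$bait)
  if (length(baits) < 2) {
    abort("specificity contrasts need at least 2 selected baits")
  }
  pairs <- utils::combn(baits, 2, simplify = FALSE)
  map_dfr(pairs, function(pr) {
    i <- pr[1]
    j <- pr[2]
    idx_i <- which(meta$bait == i & meta$condition == "selected")
    idx_j <- which(meta$bait == j & meta$condition == "selected")
    if (length(idx_i) < 2 || length(idx_j) < 2) {
      abort(paste0(
        "baits '", i, "'/'", j, "' need >= 2 selected replicates"
      ))
    }
    fit <- nb_wald(prep$z, prep$sf, idx_i, idx_j)
    bind_rows(
      mutate(fit, bait = i, bait_other = j, .before = 1),
      mutate(fit,
        bait = j, bait_other = i, log2fc = -.data$log2fc,
        .before = 1
      )
    )
  })
}

prepare_nb_input <- function(x, size_factor_method, size_factors) {
  z <- count_matrix(x)
  if (normalized_by(x) != "none") {
    if (any(z != round(z))) {
      warn(paste0(
        "counts are ", normalized_by(x), "-normalized; rounding to ",
        "integers and using unit size factors"
      ))
    }
    z <- round(z)
    sf <- setNames(rep(1, ncol(z)), colnames(z))
  } else if (!is.null(size_factors)) {
    sf <- size_factors[colnames(z)]
    if (anyNA(sf)) abort("size_factors must name every sample")
  } else {
    sf <- size_factors(x, method = size_factor_method)
  }
  list(z = z, sf = sf)
}

check_library <- function(z, cols, bait) {
  tot <- colSums(z[, cols, drop = FALSE])
  if (any(tot == 0)) {
    abort(paste0(
      "all-zero library in samples of bait '", bait, "': ",
      paste(colnames(z)[cols][tot == 0], collapse = ", ")
    ))
  }
}

#' Duplicate singleton samples into pseudo-replicates
#'
#' Bait-condition groups with exactly one sample are duplicated so that
#' dispersion estimation has the replicates it formally needs; the copies
#' are flagged `pseudo = TRUE` in the metadata and receive replicate
#' index 2. Groups that already have two or more samples are untouched.
#' Because the duplicated counts are identical, the gene-wise dispersion of
#' such groups collapses to the moderation floor, which is the intended
#' conservative behaviour when true replicate variability is unobservable.
#'
#' @param x A [y2h_counts] object.
#' @return A [y2h_counts] with pseudo-replicates appended.
#' @export
make_pseudo_replicates <- function(x) {
  meta <- sample_meta(x)
  tab <- count(meta, .data$bait, .data$condition)
  singles <- tab[tab$n == 1, ]
  if (nrow(singles) == 0) {
    return(x)
  }
  counts <- as_tibble(as.data.frame(x))
  for (r in seq_len(nrow(singles))) {
    id <- meta$sample_id[meta$bait == singles$bait[r] &
      meta$condition == singles$condition[r]]
    new_id <- paste0(id, "_pseudo")
    counts[[new_id]] <- counts[[id]]
    meta <- bind_rows(meta, tibble(
      sample_id = new_id, bait = singles$bait[r],
      condition = singles$condition[r], replicate = 2L, pseudo = TRUE
    ))
  }
  y2h_counts(counts, meta, normalized_by = normalized_by(x))
}
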