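#' Normalize a prey count table
#'
#' Dispatches to one of the four supported methods. Library size and TPM
#' rescale each sample to a constant total of 10^6 (counts per million);
#' median-of-ratios computes DESeq-style size factors within each
#' bait-condition replicate group; RUVs removes `k` factors of unwanted
#' within-replicate-group variation on the log scale.
#'
#' @param x A raw [y2h_counts] object.
#' @param method One of `"library_size"`, `"tpm"`, `"median_of_ratios"`,
#'   `"ruvs"`.
#' @param lengths Named numeric vector of prey fragment lengths in bases
#'   (TPM only).
#' @param k Number of unwanted-variation factors to remove (RUVs only).
#' @return A normalized [y2h_counts] object.
#' @export
normalize_counts <- function(x,
                             method = c(
                               "library_size", "tpm",
                               "median_of_ratios", "ruvs"
                             ),
                             lengths = NULL, k = 1) {
  method <- match.arg(method)
  switch(method,
    library_size = normalize_library_size(x),
    tpm = normalize_tpm(x, lengths),
    median_of_ratios = normalize_median_of_ratios(x),
    ruvs = normalize_ruvs(x, k = k)
  )
}

#' Library-size (counts-per-million) normalization
#'
#' Each sample is scaled by `1e6 / total`, so every column of the result
#' sums to 10^6.
#'
#' @param x A [y2h_counts] object.
#' @return A [y2h_counts] with `normalized_by = "library_size"`.
#' @export
normalize_library_size <- function(x) {
  m <- count_matrix(x)
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0(
      "sample with zero total counts: ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  m <- sweep(m, 2, 1e6 / tot, `*`)
  replace_counts(x, m, "library_size")
}

#' Transcripts-per-million normalization
#'
#' Counts are first divided by prey fragment length, then each sample is
#' rescaled so the length-corrected rates sum to 10^6. With equal lengths
#' this reduces to library-size normalization.
#'
#' @param x A [y2h_counts] object.
#' @param lengths Named numeric vector (names = prey ids) of positive
#'   fragment lengths in bases.
#' @return A [y2h_counts] with `normalized_by = "tpm"`.
#' @export
normalize_tpm <- function(x, lengths) {
  if (is.null(lengths)) abort("TPM normalization needs prey lengths")
  miss <- setdiff(x$prey, names(lengths))
  if (length(miss)) {
    abort(paste0(
      "missing length for prey: ",
      paste(head(miss, 5), collapse = ", ")
    ))
  }
  len <- as.numeric(lengths[x$prey])
  if (any(!is.finite(len)) || any(len <= 0)) {
    abort("prey lengths must be positive")
  }
  m <- count_matrix(x) / len
  tot <- colSums(m)
  if (any(tot == 0)) {
    abort(paste0(
      "sample with zero total counts: ",
      paste(colnames(m)[tot == 0], collapse = ", ")
    ))
  }
  m <- sweep(m, 2, 1e6 / tot, `*`)
  replace_counts(x, m, "tpm")
}

#' Median-of-ratios normalization within bait-condition groups
#'
#' For each bait-condition replicate group, the size factor of a sample is
#' the median, over preys with strictly positive counts in every sample of
#' the group, of the ratio of the sample's count to the prey's geometric
#' mean across the group. Counts are divided by their sample's size factor.
#'
#' @param x A [y2h_counts] object.
#' @return A [y2h_counts] with `normalized_by = "median_of_ratios"`.
#' @export
normalize_median_of_ratios <- function(x) {
  sf <- size_factors(x, method = "median_of_ratios", rescale = FALSE)
  m <- sweep(count_matrix(x), 2, sf, `/`)
  replace_counts(x, m, "median_of_ratios")
}

#' Per-sample size factors
#'
#' Size factors summarise sequencing depth and enter the negative binomial
#' fits as offsets (the counts themselves are never pre-divided). For
#' `"library_size"` the factor is the sample total; for
#' `"median_of_ratios"` it is the within-group median ratio described in
#' [normalize_median_of_ratios()].
#'
#' @param x A [y2h_counts] object.
#' @param method `"library_size"` or `"median_of_ratios"`.
#' @param rescale If `TRUE` (default) factors are divided by their
#'   geometric mean, the conventional identifiability constraint.
#' @return A named numeric vector, one factor per sample.
#' @export
size_factors <- function(x, method = c("library_size", "median_of_ratios"),
                         rescale = TRUE) {
  method <- match.arg(method)
  m <- count_matrix(x)
  meta <- sample_meta(x)
  if (method == "library_size") {
    sf <- colSums(m)
    if (any(sf == 0)) {
      abort(paste0(
        "sample with zero total counts: ",
        paste(colnames(m)[sf == 0], collapse = ", ")
      ))
    }
  } else {
    sf <- setNames(rep(NA_real_, ncol(m)), colnames(m))
    grp <- paste(meta$bait, meta$condition)
    for (g in unique(grp)) {
      cols <- which(grp == g)
      sub <- m[, cols, drop = FALSE]
      pos <- rowSums(sub > 0) == ncol(sub)
      if (!any(pos)) {
        abort(paste0(
          "no prey with all-positive counts in group '", g,
          "'; cannot compute median-of-ratios size factors"
        ))
      }
      lg <- log(sub[pos, , drop = FALSE])
      geo <- rowMeans(lg)
      sf[cols] <- apply(exp(lg - geo), 2, median)
    }
  }
  if (rescale) sf <- sf / exp(mean(log(sf)))
  sf
}

#' Remove unwanted variation using replicate samples (RUVs)
#'
#' Implements the replicate-sample variant of RUV on `log(x + 1)` counts:
#' samples are centred within their replicate groups, the first `k` left
#' singular vectors of the centred matrix estimate the unwanted factors,
#' and their contribution is regressed out of every prey before
#' back-transforming (negative values are floored at zero, and zero raw
#' counts remain zero). Following the
#' recommended grouping for interaction screens, the method is applied to
#' the selected and the non-selected samples separately: selected
#' replicates are grouped per bait, while all non-selected samples form a
#' single group (their composition is bait-independent). All preys act as
#' the control set, as the replicate-based variant requires.
#'
#' @param x A raw [y2h_counts] object.
#' @param k Number of unwanted factors (default 1).
#' @param replicate_groups Optional named list mapping group labels to
#'   character vectors of sample ids, overriding the default grouping.
#' @return A [y2h_counts] with `normalized_by = "ruvs"`.
#' @export
normalize_ruvs <- function(x, k = 1, replicate_groups = NULL) {
  meta <- sample_meta(x)
  m <- count_matrix(x)
  if (k == 0) {
    return(replace_counts(x, m, "ruvs"))
  }
  if (is.null(replicate_groups)) {
    sel <- meta$sample_id[meta$condition == "selected"]
    nonsel <- meta$sample_id[meta$condition == "non_selected"]
    replicate_groups <- list()
    if (length(sel)) {
      sb <- split(sel, meta$bait[match(sel, meta$sample_id)])
      names(sb) <- paste0("selected.", names(sb))
      replicate_groups <- c(replicate_groups, sb)
    }
    if (length(nonsel)) replicate_groups$non_selected <- nonsel
  }
  sizes <- lengths(replicate_groups)
  if (any(sizes < 2)) {
    abort(paste0(
      "replicate group of size 1: ",
      paste(names(replicate_groups)[sizes < 2], collapse = ", ")
    ))
  }
  out <- m
  # the two conditions are corrected independently
  cond_of <- setNames(meta$condition, meta$sample_id)
  grp_cond <- vapply(
    replicate_groups,
    function(s) unique(cond_of[s])[1], character(1)
  )
  for (cond in unique(grp_cond)) {
    groups <- replicate_groups[grp_cond == cond]
    ids <- unlist(groups, use.names = FALSE)
    if (k >= length(ids)) abort("k must be smaller than the number of samples")
    ly <- t(log(m[, ids, drop = FALSE] + 1)) # samples x preys
    d <- ly
    for (g in groups) {
      rows <- match(g, ids)
      d[rows, ] <- sweep(d[rows, , drop = FALSE], 2,
        colMeans(d[rows, , drop = FALSE]), `-`
      )
    }
    sv <- svd(d, nu = k, nv = 0)
    if (max(sv$d) < 1e-10) next # no within-group variation to remove
    w <- sv$u %*% diag(sv$d[seq_len(k)], nrow = k) # unwanted factors
    alpha <- solve(crossprod(w), crossprod(w, d))
    corrected <- ly - w %*% alpha
    fixed <- pmax(t(exp(corrected) - 1), 0)
    fixed[m[, ids, drop = FALSE] == 0] <- 0 # zero counts stay zero
    out[, ids] <- fixed
  }
  replace_counts(x, out, "ruvs")
}

#' Coefficient of variation across replicates, per prey
#'
#' The CV (standard deviation over mean across replicates) is computed for
#' every prey within each bait-condition group. Preys whose replicate mean
#' is zero are reported as missing.
#'
#' @param x A [y2h_counts] object (raw or normalized).
#' @return A tibble with columns `bait`, `condition`, `prey`, `cv`.
#' @export
prey_cv <- function(x) {
  meta <- sample_meta(x)
  m <- count_matrix(x)
  grp <- paste(meta$bait, meta$condition, sep = "\r")
  out <- map_dfr(unique(grp), function(g) {
    cols <- which(grp == g)
    if (length(cols) < 2) {
      abort("prey_cv needs at least 2 replicates per bait-condition group")
    }
    sub <- m[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, sd)
    parts <- strsplit(g, "\r", fixed = TRUE)[[1]]
    tibble(
      bait = parts[1], condition = parts[2], prey = rownames(m),
      cv = unname(ifelse(mu > 0, s / mu, NA_real_))
    )
  })
  out
}

#' Pairwise Pearson correlations between samples of one condition
#'
#' @param x A [y2h_counts] object.
#' @param condition `"selected"` or `"non_selected"`.
#' @return A symmetric correlation matrix (diagonal 1); pairs involving a
#'   constant sample are `NA`.
#' @export
pairwise_pearson <- function(x, condition = c("non_selected", "selected")) {
  condition <- match.arg(condition)
  meta <- sample_meta(x)
  ids <- meta$sample_id[meta$condition == condition]
  if (length(ids) < 2) {
    abort("need at least 2 samples in the condition")
  }
  m <- count_matrix(x)[, ids, drop = FALSE]
  const <- apply(m, 2, sd) == 0
  r <- suppressWarnings(cor(m))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- 1
  r
}

#' Compare normalization methods on one dataset
#'
#' Runs the requested normalizations, collects per-prey CVs and pairwise
#' within-condition Pearson correlations for each, and tests paired
#' differences between the CV distributions of every method pair with a
#' Wilcoxon signed-rank test (two-sided; exact where the sample permits,
#' otherwise the normal approximation with continuity correction).
#'
#' @param x A raw [y2h_counts] object.
#' @param methods Methods to compare, a subset of `"raw"`,
#'   `"library_size"`, `"tpm"`, `"median_of_ratios"`, `"ruvs"`.
#' @param lengths Prey lengths for TPM.
#' @param k RUVs factor count.
#' @return A `y2h_norm_report` list with tibbles `cv`, `pearson`,
#'   `wilcoxon`.
#' @export
normalization_report <- function(x,
                                 methods = c(
                                   "raw", "library_size",
                                   "median_of_ratios"
                                 ),
                                 lengths = NULL, k = 1) {
  normed <- lapply(setNames(methods, methods), function(mth) {
    if (mth == "raw") x else normalize_counts(x, mth, lengths = lengths, k = k)
  })
  cv <- imap_dfr(normed, function(cnt, mth) {
    mutate(prey_cv(cnt), method = mth, .before = 1)
  })
  pearson <- imap_dfr(normed, function(cnt, mth) {
    map_dfr(c("non_selected", "selected"), function(cond) {
      r <- pairwise_pearson(cnt, cond)
      lt <- which(lower.tri(r), arr.ind = TRUE)
      tibble(
        method = mth, condition = cond,
        sample_a = rownames(r)[lt[, 1]], sample_b = colnames(r)[lt[, 2]],
        pearson = r[lt]
      )
    })
  })
  cmb <- utils::combn(methods, 2, simplify = FALSE)
  wilcoxon <- map_dfr(cmb, function(pair) {
    a <- cv$cv[cv$method == pair[1]]
    b <- cv$cv[cv$method == pair[2]]
    keep <- is.finite(a) & is.finite(b)
    pv <- if (sum(keep) >= 2) {
      suppressWarnings(wilcox.test(a[keep], b[keep], paired = TRUE)$p.value)
    } else {
      NA_real_
    }
    tibble(method_a = pair[1], method_b = pair[2], p_value = pv)
  })
  structure(
    list(cv = cv, pearson = pearson, wilcoxon = wilcoxon),
    class = "y2h_norm_report"
  )
}

#' @export
print.y2h_norm_report <- function(x, ...) {
  cat("<y2h_norm_report>", length(unique(x$cv$method)), "methods\n")
  print(x$wilcoxon)
  invisible(x)
}

#' @rdname normalization_report
#' @param object A `y2h_norm_report`.
#' @param ... Ignored.
#' @export
autoplot.y2h_norm_report <- function(object, ...) {
  ggplot2::ggplot(
    tidyr::drop_na(object$cv, "cv"),
    ggplot2::aes(x = .data$method, y = .data$cv, fill = .data$method)
  ) +
    ggplot2::geom_boxplot(outlier.size = 0.3) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::labs(
      x = NULL, y = "per-prey CV across replicates",
      title = "Replicate variability by normalization"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Principal-component projection of a count table
#'
#' Convenience plumbing for diagnostic plots: centred, unscaled PCA of
#' `log2(x + 1)` of the (optionally normalized) counts, samples as points.
#'
#' @param x A [y2h_counts] object.
#' @param n_components Number of components to return.
#' @return A tibble with sample metadata and `PC1`, `PC2`, ...
#' @export
pca_projection <- function(x, n_components = 2) {
  m <- t(log2(count_matrix(x) + 1))
  keep <- apply(m, 2, sd) > 0
  pc <- prcomp(m[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  bind_cols(
    sample_meta(x),
    as_tibble(pc$x[, seq_len(n_components), drop = FALSE])
  )
}
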