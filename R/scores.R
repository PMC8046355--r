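#' Scoring parameters
#'
#' Controls the p-value threshold `alpha`, the number `windows` of equal
#' p-value windows used for the within-window fold-change ranks (window
#' width `w = alpha / windows`), and the fold-change zero thresholds, for
#' the enrichment and specificity chains separately. The published
#' software defaults are `alpha = 1` and `fold_change = 0` for both
#' scores.
#'
#' The specificity chain always zeroes a triple whose log fold-change
#' falls below `spec_fold_change` (default 0: preys not enriched with
#' bait i over bait j contribute nothing). For the enrichment chain the
#' rank construction itself carries no fold-change rule; set
#' `enrich_fold_change` to a finite value to additionally zero pairs
#' below it (`-Inf` disables the rule entirely).
#'
#' @param enrich_alpha,spec_alpha P-value thresholds in (0, 1].
#' @param enrich_windows,spec_windows Positive integer window counts.
#' @param enrich_fold_change Zero threshold for the enrichment score
#'   (default 0).
#' @param spec_fold_change Zero threshold for the specificity score
#'   (default 0).
#' @return A `y2h_score_params` list.
#' @export
score_params <- function(enrich_alpha = 1, enrich_windows = 10,
                         enrich_fold_change = 0,
                         spec_alpha = 1, spec_windows = 10,
                         spec_fold_change = 0) {
  stopifnot(
    enrich_alpha > 0, enrich_alpha <= 1, spec_alpha > 0, spec_alpha <= 1,
    enrich_windows >= 1, spec_windows >= 1,
    enrich_windows == round(enrich_windows),
    spec_windows == round(spec_windows)
  )
  structure(
    list(
      enrich_alpha = enrich_alpha,
      enrich_windows = as.integer(enrich_windows),
      enrich_fold_change = enrich_fold_change,
      spec_alpha = spec_alpha,
      spec_windows = as.integer(spec_windows),
      spec_fold_change = spec_fold_change
    ),
    class = "y2h_score_params"
  )
}

rank_min <- function(x) rank(x, ties.method = "min")

# window index for p in (0, alpha]; p = 0 falls in window 1
p_window <- function(p, alpha, b) {
  pmin(pmax(ceiling(p / (alpha / b)), 1L), b)
}

# Shared rank-within-rank chain: ascending competition ranks of p give the
# p-score (N - R)/N over the set with p <= alpha; within each p-window,
# descending competition ranks of the fold-change give the f-score
# (maxR - R)/maxR; the combined score adds the f-score scaled by the
# window's p-score spread over its size.
rank_chain <- function(p, f, alpha, b) {
  n <- length(p)
  member <- p <= alpha
  out <- list(
    member = member,
    p_score = rep(0, n), f_score = rep(0, n), combined = rep(0, n)
  )
  if (!any(member)) {
    return(out)
  }
  idx <- which(member)
  pv <- p[idx]
  fv <- f[idx]
  nn <- length(idx)
  p_score <- (nn - rank_min(pv)) / nn
  win <- p_window(pv, alpha, b)
  f_score <- numeric(nn)
  combined <- numeric(nn)
  for (l in unique(win)) {
    in_w <- which(win == l)
    rf <- rank_min(-fv[in_w])
    max_r <- max(rf)
    fs <- (max_r - rf) / max_r
    spread <- (max(p_score[in_w]) - min(p_score[in_w])) / length(in_w)
    f_score[in_w] <- fs
    combined[in_w] <- p_score[in_w] + spread * fs
  }
  out$p_score[idx] <- p_score
  out$f_score[idx] <- f_score
  out$combined[idx] <- combined
  out
}

#' Enrichment score
#'
#' Converts per-(bait, prey) enrichment contrasts into a [0, 1] score by
#' ranking log2 fold-changes within ranks of p-values: pairs with
#' `p > alpha` score zero; among the rest, smaller p-values earn larger
#' p-scores `(N - R(p))/N`; pairs are then partitioned into equal p-value
#' windows and within each window larger fold-changes earn larger
#' f-scores, added with a weight equal to the window's p-score spread over
#' its size; the combined score is rescaled by its global maximum.
#' Missing p-values count as 1 and missing fold-changes as 0.
#'
#' @param enrichment A tibble from [fit_enrichment()] (columns `bait`,
#'   `prey`, `log2fc`, `pvalue`).
#' @param params A [score_params()] list.
#' @return A tibble `bait`, `prey`, `enrichment` with values in [0, 1].
#' @export
enrichment_score <- function(enrichment, params = score_params()) {
  if (nrow(enrichment) == 0) {
    return(tibble(
      bait = character(), prey = character(),
      enrichment = numeric()
    ))
  }
  p <- replace_na(enrichment$pvalue, 1)
  f <- replace_na(enrichment$log2fc, 0)
  ch <- rank_chain(p, f, params$enrich_alpha, params$enrich_windows)
  e <- ch$combined
  if (is.finite(params$enrich_fold_change)) {
    e[f < params$enrich_fold_change] <- 0
  }
  if (max(e) > 0) e <- e / max(e)
  tibble(bait = enrichment$bait, prey = enrichment$prey, enrichment = e)
}

#' Specificity score
#'
#' Penalizes preys enriched with several baits. The rank chain of
#' [enrichment_score()] is applied to the unordered bait-pair contrasts
#' (one triple per pair and prey, using the positive-direction fold-change
#' magnitude for the within-window ranks). A directed triple (i over j) is
#' zeroed when its fold-change falls below `spec_fold_change` (default 0)
#' or its p-value exceeds `spec_alpha`; p-scores and windowed fold-change
#' increments are then averaged over the `n_b - 1` comparisons of each
#' (bait, prey) pair and the result rescaled by its global maximum.
#'
#' @param pairwise A tibble from [fit_specificity_pairs()] (columns
#'   `bait`, `bait_other`, `prey`, `log2fc`, `pvalue`).
#' @param params A [score_params()] list.
#' @return A tibble `bait`, `prey`, `specificity` with values in [0, 1].
#' @export
specificity_score <- function(pairwise, params = score_params()) {
  baits <- unique(c(pairwise$bait, pairwise$bait_other))
  if (length(baits) < 2) {
    abort("specificity score needs at least 2 baits")
  }
  n_b <- length(baits)
  p <- replace_na(pairwise$pvalue, 1)
  f <- replace_na(pairwise$log2fc, 0)
  # canonical unordered triples: first-listed direction of each pair
  key_a <- pmin(pairwise$bait, pairwise$bait_other)
  key_b <- pmax(pairwise$bait, pairwise$bait_other)
  key <- paste(key_a, key_b, pairwise$prey, sep = "\r")
  canon <- !duplicated(key)
  ch <- rank_chain(p[canon], abs(f[canon]), params$spec_alpha,
                   params$spec_windows)
  # windowed fold-change increment (spread factor times f-score) per triple
  f_incr <- ch$combined - ch$p_score
  p_sc <- ch$p_score
  pos <- match(key, key[canon])
  p_all <- p_sc[pos]
  f_all <- f_incr[pos]
  zero <- f < params$spec_fold_change | p > params$spec_alpha
  p_all[zero] <- 0
  f_all[zero] <- 0
  res <- tibble(
    bait = pairwise$bait, prey = pairwise$prey,
    p_part = p_all, f_part = f_all
  ) |>
    group_by(.data$bait, .data$prey) |>
    summarise(
      s = sum(.data$p_part) / (n_b - 1) + sum(.data$f_part) / (n_b - 1),
      .groups = "drop"
    )
  s <- res$s
  if (max(s) > 0) s <- s / max(s)
  tibble(bait = res$bait, prey = res$prey, specificity = s)
}

#' In-frame score
#'
#' Ranks the in-frame z statistics of all (bait, prey) pairs ascending and
#' divides by the maximum rank, so the strongest in-frame enrichment under
#' selection scores 1. Pairs with no fusion reads in either condition
#' (undefined statistic) score 0.
#'
#' @param inframe A tibble from [fit_inframe()] (columns `bait`, `prey`,
#'   `rho`).
#' @return A tibble `bait`, `prey`, `inframe` with values in [0, 1].
#' @export
inframe_score <- function(inframe) {
  rho <- inframe$rho
  score <- rep(0, length(rho))
  ok <- is.finite(rho)
  if (any(ok)) {
    r <- rank_min(rho[ok])
    score[ok] <- r / max(r)
  }
  tibble(bait = inframe$bait, prey = inframe$prey, inframe = score)
}

#' Borda ensemble of the three scores
#'
#' Classic Borda (mean-rank) aggregation computed within each bait: every
#' component score is converted to ascending ranks (average ranks for
#' ties), ranks are averaged across the available components, and the mean
#' rank is rescaled to [0, 1] by the bait's maximum.
#'
#' @param scores A tibble with `bait`, `prey` and the component columns.
#' @param components Which columns to aggregate (default the three
#'   scores).
#' @return A tibble `bait`, `prey`, `borda`.
#' @export
borda_ensemble <- function(scores,
                           components = c(
                             "enrichment", "specificity", "inframe"
                           )) {
  components <- intersect(components, names(scores))
  if (length(components) == 0) {
    abort("no score components available for the Borda ensemble")
  }
  scores |>
    group_by(.data$bait) |>
    mutate(
      borda = rowMeans(
        vapply(
          across(all_of(components)),
          function(col) rank(col, ties.method = "average"),
          numeric(dplyr::n())
        )
      ),
      borda = .data$borda / max(.data$borda)
    ) |>
    ungroup() |>
    select("bait", "prey", "borda")
}

#' Assemble the full score table
#'
#' Joins the enrichment, specificity and in-frame scores on (bait, prey)
#' and appends the Borda ensemble of whichever components are present.
#'
#' @param enrichment Output of [fit_enrichment()], or `NULL`.
#' @param pairwise Output of [fit_specificity_pairs()], or `NULL`.
#' @param inframe Output of [fit_inframe()], or `NULL`.
#' @param params A [score_params()] list.
#' @return A `y2h_scores` tibble: `bait`, `prey`, available score columns
#'   and `borda`.
#' @export
compute_scores <- function(enrichment = NULL, pairwise = NULL,
                           inframe = NULL, params = score_params()) {
  parts <- list()
  if (!is.null(enrichment)) {
    parts$enrichment <- enrichment_score(enrichment, params)
  }
  if (!is.null(pairwise)) {
    parts$specificity <- specificity_score(pairwise, params)
  }
  if (!is.null(inframe)) {
    parts$inframe <- inframe_score(inframe)
  }
  if (length(parts) == 0) abort("no model outputs supplied")
  out <- purrr::reduce(parts, full_join, by = c("bait", "prey"))
  out <- mutate(out, across(-c("bait", "prey"), ~ replace_na(.x, 0)))
  out <- left_join(out, borda_ensemble(out), by = c("bait", "prey"))
  structure(
    arrange(out, .data$bait, dplyr::desc(.data$borda), .data$prey),
    params = params,
    class = c("y2h_scores", class(tibble()))
  )
}

#' Run the full scoring pipeline on a screen
#'
#' Convenience wrapper: negative binomial enrichment and bait-pair
#' contrasts on the raw counts (library-size offsets by default), the
#' in-frame test on the fusion table, then [compute_scores()].
#'
#' @param counts A raw [y2h_counts] object.
#' @param fusion Optional fusion tibble; without it the in-frame score is
#'   omitted.
#' @param params A [score_params()] list.
#' @param size_factor_method Offset normalization for the NB fits.
#' @param assume_null_third Use the 1/3 default null for the in-frame
#'   test (screens without non-selected fusion data).
#' @return A `y2h_scores` tibble.
#' @export
score_screen <- function(counts, fusion = NULL, params = score_params(),
                         size_factor_method = "library_size",
                         assume_null_third = FALSE) {
  meta <- sample_meta(counts)
  enr <- NULL
  if (any(meta$condition == "non_selected")) {
    enr <- fit_enrichment(counts, size_factor_method = size_factor_method)
  }
  pw <- NULL
  if (length(unique(meta$bait[meta$condition == "selected"])) >= 2) {
    pw <- fit_specificity_pairs(
      counts,
      size_factor_method = size_factor_method
    )
  }
  inf <- NULL
  if (!is.null(fusion)) {
    inf <- fit_inframe(fusion, counts, assume_null_third = assume_null_third)
  }
  compute_scores(enr, pw, inf, params)
}

#' @export
print.y2h_scores <- function(x, ...) {
  cat(
    "<y2h_scores> ", length(unique(x$bait)), " baits x ",
    length(unique(x$prey)), " preys\n",
    sep = ""
  )
  NextMethod()
}

#' @rdname compute_scores
#' @param x A `y2h_scores` tibble.
#' @param ... Ignored.
#' @export
tidy.y2h_scores <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname compute_scores
#' @export
glance.y2h_scores <- function(x, ...) {
  comps <- intersect(c("enrichment", "specificity", "inframe"), names(x))
  tibble(
    n_baits = length(unique(x$bait)),
    n_preys = length(unique(x$prey)),
    components = paste(comps, collapse = ","),
    max_borda = max(x$borda)
  )
}

#' @rdname compute_scores
#' @param object A `y2h_scores` tibble.
#' @export
autoplot.y2h_scores <- function(object, ...) {
  comps <- intersect(
    c("enrichment", "specificity", "inframe", "borda"),
    names(object)
  )
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object)),
    all_of(comps),
    names_to = "score", values_to = "value"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$value, fill = .data$score)
  ) +
    ggplot2::geom_histogram(bins = 40, show.legend = FALSE) +
    ggplot2::facet_wrap(~score) +
    ggplot2::scale_y_sqrt() +
    ggplot2::labs(
      x = "score", y = "bait-prey pairs (sqrt scale)",
      title = "Score distributions"
    ) +
    ggplot2::theme_minimal()
}
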