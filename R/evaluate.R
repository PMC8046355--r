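#' ROC area under the curve
#'
#' Trapezoidal AUC over all score thresholds, computed through the
#' Mann-Whitney mid-rank identity: the AUC equals the probability that a
#' random positive outranks a random negative, counting ties as 1/2.
#'
#' @param scores Numeric scores (larger = more interactor-like).
#' @param labels Logical (or 0/1) truth labels.
#' @return The AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC AUC needs at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall area under the curve
#'
#' Step-wise (non-interpolated) estimator: thresholds sweep the distinct
#' score values in descending order, tied scores enter as a block, and
#' the area is the sum of precision times the recall increment. Unbiased
#' under the heavy class imbalance typical of interaction screens, where
#' random scores give an AUC near the prevalence.
#'
#' @inheritParams roc_auc
#' @return The AUC in (0, 1].
#' @export
pr_auc <- function(scores, labels) {
  cv <- pr_curve(scores, labels)
  sum(cv$precision * diff(c(0, cv$recall)))
}

#' Precision-recall curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `recall`, `precision`, one row per
#'   distinct score value in descending order.
#' @export
pr_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) abort("PR curve needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[block_end]
  n_at <- block_end
  tibble(
    threshold = s[block_end],
    recall = tp / n_pos,
    precision = tp / n_at
  )
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return A tibble with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC curve needs both classes")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  block_end <- cumsum(rle(s)$lengths)
  tibble(
    threshold = s[block_end],
    fpr = cumsum(!l)[block_end] / n_neg,
    tpr = cumsum(l)[block_end] / n_pos
  )
}

#' Evaluate a score table against simulation truth
#'
#' Pools all (bait, prey) pairs into one curve per score. Positives are
#' the true-interactor pairs; every other pair - including auto-active /
#' non-specific preys - is a negative, since the task is to separate true
#' from promiscuous survivors of selection.
#'
#' @param scores A `y2h_scores` tibble (or any tibble with `bait`,
#'   `prey` and score columns).
#' @param truth A truth tibble from [sample_library()] (columns `bait`,
#'   `prey`, `label`).
#' @return A `y2h_eval` tibble: one row per score with `roc_auc`,
#'   `pr_auc`, `n_positives`, `n_total`.
#' @export
evaluate_scores <- function(scores, truth) {
  joined <- inner_join(
    as_tibble(as.data.frame(scores)),
    select(truth, "bait", "prey", "label"),
    by = c("bait", "prey")
  )
  lab <- joined$label == "true_interactor"
  comps <- intersect(
    c("enrichment", "specificity", "inframe", "borda"),
    names(joined)
  )
  out <- map_dfr(comps, function(sc) {
    tibble(
      score = sc,
      roc_auc = roc_auc(joined[[sc]], lab),
      pr_auc = pr_auc(joined[[sc]], lab),
      n_positives = sum(lab),
      n_total = length(lab)
    )
  })
  structure(out, class = c("y2h_eval", class(tibble())))
}

#' Simulate, score and evaluate one scenario over several seeds
#'
#' End-to-end driver of the simulation experiments: for each seed it
#' simulates the screen, fits the negative binomial contrasts with
#' library-size offsets, the in-frame tests, the three scores plus the
#' Borda ensemble, and evaluates pooled ROC and PR AUCs against the truth
#' labels.
#'
#' @param config A [scenario_config()].
#' @param params A [score_params()] list.
#' @param seeds Integer vector of simulation seeds.
#' @return A `y2h_eval` tibble with an extra `seed` column.
#' @export
run_scenario <- function(config = scenario_config(),
                         params = score_params(), seeds = 1:3) {
  out <- map_dfr(seeds, function(sd) {
    sim <- simulate_experiment(config, seed = sd)
    enr <- fit_enrichment(sim$counts)
    pw <- if (config$n_baits >= 2) fit_specificity_pairs(sim$counts)
    inf <- fit_inframe(sim$fusion, sim$counts)
    sc <- compute_scores(enr, pw, inf, params)
    mutate(evaluate_scores(sc, sim$truth), seed = sd, .before = 1)
  })
  structure(out, class = c("y2h_eval", class(tibble())))
}

#' @rdname evaluate_scores
#' @param x A `y2h_eval` tibble.
#' @param ... Ignored.
#' @export
glance.y2h_eval <- function(x, ...) {
  x |>
    group_by(.data$score) |>
    summarise(
      roc_auc = mean(.data$roc_auc), pr_auc = mean(.data$pr_auc),
      n_seeds = dplyr::n(), .groups = "drop"
    )
}

#' @rdname evaluate_scores
#' @param object A `y2h_eval` tibble.
#' @export
autoplot.y2h_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(as.data.frame(object)),
    c("roc_auc", "pr_auc"),
    names_to = "metric", values_to = "auc"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$score, y = .data$auc, fill = .data$score)
  ) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "AUC") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}
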