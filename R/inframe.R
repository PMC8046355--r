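#' Two-proportion z statistic for in-frame fusion-read enrichment
#'
#' Tests whether the proportion of in-frame fusion reads is larger under
#' selection than under non-selection. With `y_c` in-frame reads out of
#' `f_c` fusion reads in condition `c`, the statistic is
#' `rho = (pi_S - pi_N) / sqrt(pi * (1 - pi) * (1/f_S + 1/f_N))` with the
#' pooled proportion `pi = (y_S + y_N) / (f_S + f_N)`, against the
#' one-sided alternative `pi_N < pi_S`. Under random cloning of a 3-frame
#' library the null in-frame proportion is about 1/3.
#'
#' `rho` is missing when either condition has no fusion reads. When the
#' pooled proportion is exactly 0 or 1 while the two observed proportions
#' differ (impossible with consistent inputs but reachable through the
#' default-null variant), the statistic is represented by a large sentinel
#' `+/-1e6` and flagged; downstream scoring is rank-based so only the
#' ordering matters.
#'
#' @param y_s,f_s In-frame and total fusion reads under selection
#'   (vectorized).
#' @param y_n,f_n In-frame and total fusion reads under non-selection.
#' @return A tibble with `pi_S`, `pi_N`, `pi_pooled`, `rho`, `f_S`, `f_N`
#'   and a logical `sentinel` flag.
#' @export
inframe_z <- function(y_s, f_s, y_n, f_n) {
  n <- max(length(y_s), length(f_s), length(y_n), length(f_n))
  y_s <- rep_len(y_s, n)
  f_s <- rep_len(f_s, n)
  y_n <- rep_len(y_n, n)
  f_n <- rep_len(f_n, n)
  if (any(y_s > f_s, na.rm = TRUE) || any(y_n > f_n, na.rm = TRUE)) {
    abort("in-frame reads cannot exceed total fusion reads")
  }
  if (any(c(y_s, f_s, y_n, f_n) < 0, na.rm = TRUE)) {
    abort("fusion read counts must be >= 0")
  }
  pi_s <- ifelse(f_s > 0, y_s / f_s, NA_real_)
  pi_n <- ifelse(f_n > 0, y_n / f_n, NA_real_)
  pooled <- ifelse(f_s + f_n > 0, (y_s + y_n) / (f_s + f_n), NA_real_)
  denom <- sqrt(pooled * (1 - pooled) * (1 / f_s + 1 / f_n))
  rho <- (pi_s - pi_n) / denom
  # identical proportions are an exact null even when the pooled variance
  # degenerates (e.g. all reads in-frame in both conditions)
  rho[which(is.finite(pi_s) & is.finite(pi_n) & pi_s == pi_n)] <- 0
  sentinel <- is.finite(pi_s) & is.finite(pi_n) &
    (pooled %in% c(0, 1)) & (pi_s != pi_n)
  rho[sentinel] <- sign(pi_s[sentinel] - pi_n[sentinel]) * 1e6
  rho[f_s == 0 | f_n == 0] <- NA_real_
  tibble(
    pi_S = pi_s, pi_N = pi_n, pi_pooled = pooled, rho = rho,
    f_S = f_s, f_N = f_n, sentinel = sentinel
  )
}

#' In-frame z statistic against an assumed null proportion
#'
#' When non-selected fusion data are unavailable, the non-selected
#' proportion is substituted by the random-cloning expectation
#' `pi_n = 1/3` at an effective depth `f_n_effective`, and the pooled-z
#' formula of [inframe_z()] is applied. The default effective depth equals
#' the selected depth (an equally deep pseudo-sample); it is deliberately
#' exposed as a tunable because the statistic's scale, though not the
#' induced ranking's broad structure, depends on it.
#'
#' @param y_s,f_s In-frame and total fusion reads under selection.
#' @param pi_n Assumed non-selected in-frame proportion (default 1/3).
#' @param f_n_effective Effective non-selected depth (default `f_s`).
#' @return Same shape as [inframe_z()].
#' @export
inframe_z_default_null <- function(y_s, f_s, pi_n = 1 / 3,
                                   f_n_effective = f_s) {
  inframe_z(y_s, f_s, y_n = pi_n * f_n_effective, f_n = f_n_effective)
}

#' Per-(bait, prey) in-frame statistics from a fusion table
#'
#' Fusion reads are aggregated across replicates within each condition of
#' each bait (the binomial model indexes reads by condition, not
#' replicate), then the in-frame z statistic is computed per (bait, prey).
#' Preys missing from the fusion table count as `y = f = 0`.
#'
#' @param fusion A fusion tibble (`prey`, `sample_id`, `inframe_reads`,
#'   `fusion_reads`), as read by [read_fusion()].
#' @param meta Sample metadata tibble (or a [y2h_counts] whose metadata
#'   and prey universe should be used).
#' @param preys Optional character vector fixing the prey universe.
#' @param assume_null_third If `TRUE`, ignore non-selected fusion reads
#'   and use the 1/3 default null of [inframe_z_default_null()].
#' @return A tibble with one row per (bait, prey): aggregated `y_S`,
#'   `f_S`, `y_N`, `f_N` and the columns of [inframe_z()].
#' @export
fit_inframe <- function(fusion, meta, preys = NULL,
                        assume_null_third = FALSE) {
  if (inherits(meta, "y2h_counts")) {
    if (is.null(preys)) preys <- meta$prey
    meta <- sample_meta(meta)
  }
  fusion <- validate_fusion(fusion)
  bad <- setdiff(unique(fusion$sample_id), meta$sample_id)
  if (length(bad)) {
    abort(paste0(
      "fusion samples not in metadata: ", paste(bad, collapse = ", ")
    ))
  }
  if (is.null(preys)) preys <- sort(unique(fusion$prey))
  agg <- fusion |>
    inner_join(meta, by = "sample_id") |>
    group_by(.data$bait, .data$condition, .data$prey) |>
    summarise(
      y = sum(.data$inframe_reads), f = sum(.data$fusion_reads),
      .groups = "drop"
    )
  grid <- tidyr::expand_grid(bait = unique(meta$bait), prey = preys)
  wide <- grid |>
    left_join(
      tidyr::pivot_wider(agg,
        names_from = "condition", values_from = c("y", "f"),
        values_fill = 0
      ),
      by = c("bait", "prey")
    ) |>
    mutate(across(
      any_of(c("y_selected", "f_selected", "y_non_selected", "f_non_selected")),
      ~ replace_na(.x, 0)
    ))
  for (col in c("y_selected", "f_selected", "y_non_selected", "f_non_selected")) {
    if (!col %in% names(wide)) wide[[col]] <- 0
  }
  stats <- if (assume_null_third) {
    inframe_z_default_null(wide$y_selected, wide$f_selected)
  } else {
    inframe_z(
      wide$y_selected, wide$f_selected,
      wide$y_non_selected, wide$f_non_selected
    )
  }
  bind_cols(
    tibble(
      bait = wide$bait, prey = wide$prey,
      y_S = wide$y_selected, y_N = wide$y_non_selected
    ),
    stats
  )
}
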