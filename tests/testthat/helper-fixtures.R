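# Programmatic fixtures shared across test files.

# a minimal 3-prey, 2-bait screen with selected and non-selected replicates
tiny_counts <- function(n_preys = 3, baits = c("baitA", "baitB"),
                        n_replicates = 2, seed = 11, lambda = 50) {
  set.seed(seed)
  meta <- expand.grid(
    replicate = seq_len(n_replicates),
    condition = c("selected", "non_selected"),
    bait = baits, stringsAsFactors = FALSE
  )
  meta$sample_id <- sprintf(
    "%s_%s_r%d", meta$bait,
    ifelse(meta$condition == "selected", "S", "N"), meta$replicate
  )
  meta <- meta[, c("sample_id", "bait", "condition", "replicate")]
  counts <- data.frame(prey = sprintf("prey%02d", seq_len(n_preys)))
  for (id in meta$sample_id) {
    counts[[id]] <- rpois(n_preys, lambda)
  }
  y2h_counts(counts, meta)
}

# NB counts with a planted fold change for a subset of preys; returns the
# container plus the index of the enriched preys
nb_test_counts <- function(n_preys = 500, n_enriched = 50, fold = 8,
                           dispersion = 0.1, n_replicates = 3,
                           base_mean = 100, seed = 7, bait = "baitA") {
  set.seed(seed)
  mu0 <- rlnorm(n_preys, log(base_mean), 1)
  enriched <- seq_len(n_enriched)
  meta <- data.frame(
    sample_id = c(
      sprintf("%s_S_r%d", bait, seq_len(n_replicates)),
      sprintf("%s_N_r%d", bait, seq_len(n_replicates))
    ),
    bait = bait,
    condition = rep(c("selected", "non_selected"), each = n_replicates),
    replicate = rep(seq_len(n_replicates), 2)
  )
  counts <- data.frame(prey = sprintf("prey%04d", seq_len(n_preys)))
  for (i in seq_len(nrow(meta))) {
    mu <- mu0
    if (meta$condition[i] == "selected") {
      mu[enriched] <- mu[enriched] * fold
    }
    counts[[meta$sample_id[i]]] <-
      rnbinom(n_preys, mu = mu, size = 1 / dispersion)
  }
  list(counts = y2h_counts(counts, meta), enriched = enriched)
}

expect_tibble_equal <- function(a, b, tolerance = 1e-10) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
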