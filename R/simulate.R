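#' Simulation scenario configuration
#'
#' Defines the study conditions of a simulated Y2H-NGIS screen. Defaults
#' reproduce the idealized screen: 10 baits, 3 replicates per condition, a
#' 20,000-prey cDNA library with initial proportions spanning orders of
#' magnitude, 1-20 true interactors per bait, a stickiness (auto-active /
#' non-specific prey fraction) of 0.1%, true-interactor fitness above the
#' 99.9th percentile of the background fitness pool, 3.84e9 starting cells
#' grown to about 7.5e10, and 7.5e6 reads per sample.
#'
#' Growth fitness `e` is the per-generation division probability of a
#' diploid, so a prey's population multiplies by `(1 + e)` per generation.
#' Empirical parameter distributions are represented by parametric
#' stand-ins: library proportions are log-normal (`sdlog = q_sigma`),
#' inert preys draw selected fitness from `Beta(1, 50)`, sticky preys from
#' `Beta(8, 4)` under every bait, and true interactors sit above the
#' `strength_percentile` quantile of the pooled inert + sticky draws.
#' Overdispersions are log-normal with medians `0.5` (non-selected) and
#' `0.05` (selected) in `"random"` mode, or uniform over the high-tail
#' ranges `(2.27, 13.42)` and `(0.33, 2)` in `"high"` mode. Because real
#' screens sample abundance and non-selected overdispersion jointly -
#' abundant preys are measured with relatively less extra-Poisson noise,
#' which is what makes non-selected samples correlate above 0.95 - the
#' `"random"` mode couples `phi_N` to library abundance through a
#' Gaussian copula with correlation `-phi_abundance_cor`, preserving the
#' log-normal marginal. Fusion reads
#' are a small `Beta(2, 60)`-distributed fraction of total reads (mean
#' about 3%), in-frame with probability 1/3 except for true (0.95) and
#' sticky (uniform between the two) preys under selection.
#'
#' @param n_preys Library size (number of distinct preys).
#' @param n_baits Number of bait screens (2-10 in the study designs).
#' @param n_replicates Replicates per bait and condition.
#' @param interactors_per_bait Inclusive integer range from which each
#'   bait's number of true interactors is drawn uniformly.
#' @param stickiness Fraction of auto-active/non-specific preys.
#' @param strength_percentile Minimum quantile of the fitness pool for
#'   true-interactor fitness.
#' @param overdispersion `"random"` or `"high"`.
#' @param low_concentration If `TRUE`, true interactors' library
#'   proportions are forced to `1e-8` before renormalization.
#' @param m0 Initial total cell count of each culture.
#' @param target_population Total cells at which growth stops.
#' @param depth Sequencing reads per sample.
#' @param e_n Non-selected division probability (all preys).
#' @param q_sigma Log-sd of the library proportion distribution.
#' @param phi_abundance_cor Copula correlation between log abundance and
#'   log non-selected overdispersion (`"random"` mode).
#' @param inert_beta,sticky_beta Beta shape pairs for the fitness
#'   stand-ins.
#' @param fusion_beta Beta shape pair for the per-prey fusion-read
#'   fraction.
#' @param pi_true In-frame proportion of true interactors under
#'   selection.
#' @param max_generations Hard cap on selected-growth generations.
#' @return A `y2h_scenario` list.
#' @export
scenario_config <- function(n_preys = 20000, n_baits = 10,
                            n_replicates = 3,
                            interactors_per_bait = c(1, 20),
                            stickiness = 0.001,
                            strength_percentile = 0.999,
                            overdispersion = c("random", "high"),
                            low_concentration = FALSE,
                            m0 = 3.84e9, target_population = 7.5e10,
                            depth = 7.5e6, e_n = 0.9, q_sigma = 2,
                            phi_abundance_cor = 0.9,
                            inert_beta = c(1, 50), sticky_beta = c(8, 4),
                            fusion_beta = c(2, 60), pi_true = 0.95,
                            max_generations = 60) {
  overdispersion <- match.arg(overdispersion)
  stopifnot(
    n_preys >= 10, n_baits >= 1, n_replicates >= 1,
    length(interactors_per_bait) == 2,
    interactors_per_bait[1] >= 1,
    interactors_per_bait[2] >= interactors_per_bait[1],
    stickiness >= 0, stickiness <= 1,
    strength_percentile > 0, strength_percentile < 1,
    m0 > 0, target_population > m0, depth > 0,
    e_n > 0, e_n <= 1
  )
  if (stickiness + interactors_per_bait[2] / n_preys >= 1) {
    abort("stickiness plus interactor fraction must be below 1")
  }
  structure(
    list(
      n_preys = as.integer(n_preys), n_baits = as.integer(n_baits),
      n_replicates = as.integer(n_replicates),
      interactors_per_bait = as.integer(interactors_per_bait),
      stickiness = stickiness,
      strength_percentile = strength_percentile,
      overdispersion = overdispersion,
      low_concentration = isTRUE(low_concentration),
      m0 = m0, target_population = target_population, depth = depth,
      e_n = e_n, q_sigma = q_sigma,
      phi_abundance_cor = phi_abundance_cor,
      inert_beta = inert_beta, sticky_beta = sticky_beta,
      fusion_beta = fusion_beta, pi_true = pi_true,
      max_generations = as.integer(max_generations)
    ),
    class = "y2h_scenario"
  )
}

# binomial draws that stay exact for populations of ~1e10 cells; R's
# rbinom returns doubles above .Machine$integer.max, so only an NA result
# (never observed in practice) falls back to a normal approximation
rbinom_large <- function(n, size, prob) {
  x <- as.numeric(suppressWarnings(rbinom(n, size, prob)))
  bad <- is.na(x) & size > 0
  if (any(bad)) {
    m <- size[bad] * prob[bad]
    v <- m * (1 - prob[bad])
    x[bad] <- pmin(pmax(round(rnorm(sum(bad), m, sqrt(v))), 0), size[bad])
  }
  x
}

prey_ids <- function(n) sprintf("prey%05d", seq_len(n))
bait_ids <- function(n) sprintf("bait%02d", seq_len(n))

#' Sample a prey library and its truth labels
#'
#' Draws the initial library proportions, assigns each prey a label
#' (true interactor of specific baits, auto-active/non-specific, or
#' inert), and draws the per-(bait, prey) selected-condition fitness,
#' overdispersions and in-frame proportions described in
#' [scenario_config()].
#'
#' @param config A [scenario_config()].
#' @return A tibble with one row per (bait, prey): `bait`, `prey`,
#'   `label` (`true_interactor`, `auto_active_nonspecific` or `inert`),
#'   `q` (library proportion, summing to 1 within each bait), `e_S`
#'   (selected fitness), `phi_N`, `phi_S`, `pi_S`.
#' @export
sample_library <- function(config) {
  np <- config$n_preys
  nb <- config$n_baits
  preys <- prey_ids(np)
  baits <- bait_ids(nb)
  q_raw <- rlnorm(np, meanlog = 0, sdlog = config$q_sigma)
  q <- q_raw / sum(q_raw)
  sticky <- runif(np) < config$stickiness
  # per-(prey, bait) background fitness; sticky preys are fast under every
  # bait, inert preys barely divide under selection
  e_s <- matrix(
    rbeta(np * nb, config$inert_beta[1], config$inert_beta[2]),
    nrow = np
  )
  if (any(sticky)) {
    e_s[sticky, ] <- rbeta(
      sum(sticky) * nb,
      config$sticky_beta[1], config$sticky_beta[2]
    )
  }
  pool <- as.numeric(e_s)
  thr <- quantile(pool, config$strength_percentile, names = FALSE)
  true_mat <- matrix(FALSE, np, nb)
  candidates <- which(!sticky)
  for (b in seq_len(nb)) {
    n_true <- sample(
      seq(config$interactors_per_bait[1], config$interactors_per_bait[2]),
      1
    )
    chosen <- sample(candidates, n_true)
    true_mat[chosen, b] <- TRUE
    e_s[chosen, b] <- thr + runif(n_true) * (1 - thr)
  }
  if (config$low_concentration) {
    any_true <- rowSums(true_mat) > 0
    q[any_true] <- 1e-8
    q <- q / sum(q)
  }
  phi_n <- switch(config$overdispersion,
    random = {
      # abundant preys carry less extra-Poisson noise (joint q, phi_N
      # structure of real screens); marginal stays log-normal
      rho <- config$phi_abundance_cor
      zq <- (log(q_raw) - 0) / config$q_sigma
      zn <- -rho * zq + sqrt(1 - rho^2) * rnorm(np)
      exp(log(0.5) + zn)
    },
    high = runif(np, 2.27, 13.42)
  )
  phi_s <- switch(config$overdispersion,
    random = matrix(rlnorm(np * nb, meanlog = log(0.05), sdlog = 1),
      nrow = np
    ),
    high = matrix(runif(np * nb, 0.33, 2), nrow = np)
  )
  pi_s <- matrix(1 / 3, np, nb)
  pi_s[true_mat] <- config$pi_true
  if (any(sticky)) {
    pi_s[sticky, ] <- runif(sum(sticky) * nb, 1 / 3, config$pi_true)
  }
  label <- matrix("inert", np, nb)
  label[sticky, ] <- "auto_active_nonspecific"
  label[true_mat] <- "true_interactor"
  tibble(
    bait = rep(baits, each = np),
    prey = rep(preys, nb),
    label = as.vector(label),
    q = rep(q, nb),
    e_S = as.vector(e_s),
    phi_N = rep(phi_n, nb),
    phi_S = as.vector(phi_s),
    pi_S = as.vector(pi_s)
  )
}

#' Simulate one culture's Galton-Watson growth
#'
#' Cells carrying prey k start at `Bin(m0, q_k)` and gain
#' `Bin(X, e_k)` offspring per synchronous generation. Non-selected
#' cultures (uniform fitness `e_n`) run for the deterministic number of
#' generations that reaches the target population; selected cultures
#' (prey-specific fitness) grow until the total population first reaches
#' the target, which makes their duration stochastic.
#'
#' @param q Initial library proportions (sum to 1).
#' @param e Per-prey division probabilities in [0, 1]; a scalar is
#'   recycled.
#' @param config A [scenario_config()].
#' @param condition `"selected"` or `"non_selected"` (chooses the
#'   stopping rule).
#' @return A list with `cells` (final per-prey populations),
#'   `generations`, `size_factor` (`depth / total cells`) and an
#'   `extinct` flag (all populations zero).
#' @export
simulate_growth <- function(q, e, config,
                            condition = c("selected", "non_selected")) {
  condition <- match.arg(condition)
  np <- length(q)
  e <- rep_len(e, np)
  x <- rbinom_large(np, rep(config$m0, np), q)
  t_gen <- 0L
  if (condition == "non_selected") {
    t_total <- ceiling(
      log(config$target_population / config$m0) / log(1 + config$e_n)
    )
    for (t in seq_len(t_total)) {
      x <- x + rbinom_large(np, x, e)
    }
    t_gen <- as.integer(t_total)
  } else {
    while (sum(x) < config$target_population &&
      t_gen < config$max_generations && sum(x) > 0) {
      x <- x + rbinom_large(np, x, e)
      t_gen <- t_gen + 1L
    }
  }
  total <- sum(x)
  list(
    cells = x,
    generations = t_gen,
    size_factor = if (total > 0) config$depth / total else NA_real_,
    extinct = total == 0
  )
}

#' Observe read counts from a grown culture
#'
#' Reads for prey k are drawn from a negative binomial with mean
#' `L * X_k` (size factor times cells) and variance `mu + phi * mu^2`;
#' `phi = 0` degenerates to Poisson.
#'
#' @param growth Output of [simulate_growth()].
#' @param phi Per-prey overdispersion values.
#' @return An integer-valued numeric vector of read counts.
#' @export
simulate_reads <- function(growth, phi) {
  mu <- growth$size_factor * growth$cells
  phi <- rep_len(phi, length(mu))
  z <- numeric(length(mu))
  pois <- phi < 1e-12 | mu == 0
  if (any(pois)) z[pois] <- rpois(sum(pois), mu[pois])
  if (any(!pois)) {
    z[!pois] <- rnbinom(sum(!pois), mu = mu[!pois], size = 1 / phi[!pois])
  }
  z
}

#' Draw fusion reads for one sample
#'
#' Fusion reads are a small binomial fraction of each prey's total reads
#' (per-prey fraction drawn from the scenario's `fusion_beta`
#' distribution), and in-frame reads are binomial within them at the
#' prey's in-frame proportion for the sample's condition.
#'
#' @param z Total read counts of the sample.
#' @param fusion_fraction Per-prey fusion-read fractions.
#' @param pi_inframe Per-prey in-frame proportions for this condition.
#' @return A tibble with `fusion_reads` and `inframe_reads`.
#' @export
simulate_fusion <- function(z, fusion_fraction, pi_inframe) {
  f <- rbinom_large(length(z), z, rep_len(fusion_fraction, length(z)))
  y <- rbinom_large(length(z), f, rep_len(pi_inframe, length(z)))
  tibble(fusion_reads = f, inframe_reads = y)
}

#' Simulate a complete labelled Y2H-NGIS screen
#'
#' Runs library sampling, growth, sequencing and fusion-read generation
#' for every bait, condition and replicate, and returns the paired count
#' table, fusion table and truth labels. Fully reproducible from `seed`.
#'
#' @param config A [scenario_config()].
#' @param seed Integer seed for all randomness.
#' @return A `y2h_sim` list: `counts` (a [y2h_counts]), `fusion` (long
#'   tibble of samples with at least one fusion read), `truth` (the
#'   [sample_library()] tibble), `config`, `seed`, and `extinct` (ids of
#'   extinct cultures, normally empty).
#' @export
simulate_experiment <- function(config = scenario_config(), seed = 1) {
  set.seed(seed)
  truth <- sample_library(config)
  np <- config$n_preys
  preys <- prey_ids(np)
  baits <- bait_ids(config$n_baits)
  q <- truth$q[seq_len(np)]
  phi_n <- truth$phi_N[seq_len(np)]
  fusion_fraction <- rbeta(np, config$fusion_beta[1], config$fusion_beta[2])
  counts <- list()
  fusion <- list()
  meta <- list()
  extinct <- character()
  for (b in baits) {
    rows <- truth$bait == b
    e_sel <- truth$e_S[rows]
    phi_sel <- truth$phi_S[rows]
    pi_sel <- truth$pi_S[rows]
    for (cond in c("non_selected", "selected")) {
      for (r in seq_len(config$n_replicates)) {
        id <- paste0(b, "_", if (cond == "selected") "S" else "N", "_r", r)
        gr <- if (cond == "selected") {
          simulate_growth(q, e_sel, config, "selected")
        } else {
          simulate_growth(q, config$e_n, config, "non_selected")
        }
        if (gr$extinct) {
          extinct <- c(extinct, id)
          z <- numeric(np)
        } else {
          z <- simulate_reads(gr, if (cond == "selected") phi_sel else phi_n)
        }
        pi_use <- if (cond == "selected") pi_sel else rep(1 / 3, np)
        fu <- simulate_fusion(z, fusion_fraction, pi_use)
        counts[[id]] <- z
        keep <- fu$fusion_reads > 0
        if (any(keep)) {
          fusion[[id]] <- tibble(
            prey = preys[keep], sample_id = id,
            inframe_reads = fu$inframe_reads[keep],
            fusion_reads = fu$fusion_reads[keep]
          )
        }
        meta[[id]] <- tibble(
          sample_id = id, bait = b, condition = cond, replicate = r
        )
      }
    }
  }
  counts_tbl <- bind_cols(tibble(prey = preys), as_tibble(counts))
  structure(
    list(
      counts = y2h_counts(counts_tbl, bind_rows(meta)),
      fusion = bind_rows(fusion),
      truth = truth,
      config = config,
      seed = seed,
      extinct = extinct
    ),
    class = "y2h_sim"
  )
}

#' @export
print.y2h_sim <- function(x, ...) {
  cfg <- x$config
  cat(
    "<y2h_sim> ", cfg$n_preys, " preys, ", cfg$n_baits, " baits, ",
    cfg$n_replicates, " replicates/condition (seed ", x$seed, ")\n",
    "  true interactor pairs: ",
    sum(x$truth$label == "true_interactor"), "\n",
    sep = ""
  )
  invisible(x)
}
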