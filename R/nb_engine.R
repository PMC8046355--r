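# Vectorized gene-wise negative binomial Wald engine.
#
# Model per prey g and sample s: z_gs ~ NB(mu_gs, phi_g) with
# mu_gs = sf_s * exp(beta_{g,group(s)}) and Var = mu + phi mu^2. The design
# is a single two-level factor, so the two group coefficients decouple and
# each is fit by a one-dimensional Newton iteration, vectorized across all
# preys at once. Dispersion is estimated gene-wise by method of moments on
# size-factor-normalized counts and shrunk on the log scale toward a
# parametric a0 + a1/mu trend (prior weight = residual d.f. of the trend
# prior), with a hard floor so that pseudo-replicated or underdispersed
# preys do not produce negative estimates.

DISPERSION_FLOOR <- 1e-8
DISPERSION_CEIL <- 50
PRIOR_DF <- 4

# gene-wise method-of-moments dispersion given fitted group means
mom_dispersion <- function(z, sf, group) {
  n <- ncol(z)
  p <- length(unique(group))
  y <- sweep(z, 2, sf, `/`)
  mu <- matrix(0, nrow(z), n)
  for (g in unique(group)) {
    cols <- group == g
    mu[, cols] <- rowMeans(y[, cols, drop = FALSE])
  }
  resid2 <- (y - mu)^2
  # on the normalized scale Var(y) = mu/sf + phi mu^2
  num <- rowSums(resid2) * n / max(n - p, 1) -
    rowSums(sweep(mu, 2, sf, `/`))
  den <- rowSums(mu^2)
  phi <- ifelse(den > 0, num / den, NA_real_)
  list(phi = pmin(pmax(phi, DISPERSION_FLOOR), DISPERSION_CEIL),
       base_mean = rowMeans(y))
}

# fit phi ~ a0 + a1/mu over informative preys; fall back to the median
dispersion_trend <- function(phi, base_mean) {
  use <- is.finite(phi) & phi > DISPERSION_FLOOR * 10 & base_mean > 1
  if (sum(use) >= 20) {
    fit <- lm(phi[use] ~ I(1 / base_mean[use]))
    a0 <- max(coef(fit)[1], DISPERSION_FLOOR)
    a1 <- max(coef(fit)[2], 0)
  } else {
    a0 <- max(median(phi, na.rm = TRUE), DISPERSION_FLOOR)
    a1 <- 0
  }
  pmin(pmax(a0 + a1 / pmax(base_mean, 1e-8), DISPERSION_FLOOR),
       DISPERSION_CEIL)
}

moderate_dispersion <- function(phi, trend, df) {
  w <- df / (df + PRIOR_DF)
  exp(w * log(phi) + (1 - w) * log(trend))
}

# Newton fit of one group coefficient per prey (vectorized over preys).
# Returns beta (natural log scale) and the expected information.
fit_group_beta <- function(z, sf, phi, iter = 25) {
  tot <- rowSums(z)
  beta <- log(pmax(tot, 0.5) / sum(sf))
  active <- tot > 0
  for (it in seq_len(iter)) {
    if (!any(active)) break
    mu <- exp(beta) %o% sf
    u <- rowSums((z - mu) / (1 + phi * mu))
    j <- rowSums(mu * (1 + phi * z) / (1 + phi * mu)^2)
    step <- ifelse(j > 0, u / j, 0)
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + ifelse(active, step, 0)
  }
  mu <- exp(beta) %o% sf
  info <- rowSums(mu / (1 + phi * mu))
  list(beta = beta, info = pmax(info, 1e-12))
}

# Wald contrast of group A over group B for every prey.
# z: preys x samples integer matrix; sf: per-sample size factors;
# idx_a/idx_b: column indices of the two groups.
nb_wald <- function(z, sf, idx_a, idx_b) {
  cols <- c(idx_a, idx_b)
  zz <- z[, cols, drop = FALSE]
  sfs <- sf[cols]
  group <- rep(c("A", "B"), c(length(idx_a), length(idx_b)))
  est <- mom_dispersion(zz, sfs, group)
  df <- length(cols) - 2
  trend <- dispersion_trend(est$phi, est$base_mean)
  phi <- pmin(pmax(moderate_dispersion(est$phi, trend, df),
                   DISPERSION_FLOOR), DISPERSION_CEIL)
  fa <- fit_group_beta(zz[, group == "A", drop = FALSE], sfs[group == "A"],
                       phi)
  fb <- fit_group_beta(zz[, group == "B", drop = FALSE], sfs[group == "B"],
                       phi)
  delta <- fa$beta - fb$beta
  se <- sqrt(1 / fa$info + 1 / fb$info)
  stat <- delta / se
  # t reference with moderated degrees of freedom (residual + prior), so
  # that the uncertainty of the shrunken dispersion estimates propagates
  # into the tail at small replicate numbers
  pval <- 2 * stats::pt(-abs(stat), df = df + PRIOR_DF)
  all_zero <- rowSums(zz) == 0
  tibble(
    prey = rownames(z),
    log2fc = unname(ifelse(all_zero, 0, delta / log(2))),
    pvalue = unname(ifelse(all_zero, NA_real_, pval)),
    base_mean = unname(est$base_mean),
    dispersion = unname(phi)
  )
}
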