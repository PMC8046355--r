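test_that("library-size normalization maps proportions to counts per million", {
  x <- tiny_counts(n_preys = 4, seed = 3)
  norm <- normalize_library_size(x)
  expect_equal(unname(colSums(count_matrix(norm))),
    rep(1e6, ncol(count_matrix(x))),
    tolerance = 1e-9
  )
  # equal proportions in different-depth samples map to equal values
  counts <- data.frame(prey = c("p1", "p2"), s1 = c(10L, 90L), s2 = c(20L, 180L))
  meta <- data.frame(
    sample_id = c("s1", "s2"), bait = "b", condition = "selected",
    replicate = 1:2
  )
  n <- normalize_library_size(y2h_counts(counts, meta))
  expect_equal(n$s1, n$s2)
  expect_equal(n$s1, c(1e5, 9e5))

  zero <- counts
  zero$s2 <- c(0L, 0L)
  expect_error(
    normalize_library_size(y2h_counts(zero, meta)),
    "zero total.*s2"
  )
})

test_that("TPM equals library size under equal lengths and follows the rate formula", {
  x <- tiny_counts(n_preys = 5, seed = 4)
  len_equal <- stats::setNames(rep(500, 5), x$prey)
  expect_equal(
    count_matrix(normalize_tpm(x, len_equal)),
    count_matrix(normalize_library_size(x))
  )
  counts <- data.frame(prey = c("p1", "p2"), s1 = c(10L, 20L))
  meta <- data.frame(
    sample_id = "s1", bait = "b", condition = "selected", replicate = 1
  )
  tpm <- normalize_tpm(
    y2h_counts(counts, meta),
    c(p1 = 100, p2 = 200)
  )
  expect_equal(tpm$s1, c(5e5, 5e5)) # rates 0.1 and 0.1
  expect_equal(sum(tpm$s1), 1e6)
  expect_error(
    normalize_tpm(y2h_counts(counts, meta), c(p1 = 100)),
    "missing length.*p2"
  )
})

test_that("median-of-ratios recovers planted scale factors", {
  set.seed(5)
  base <- rpois(20, 100) + 1
  counts <- data.frame(
    prey = sprintf("p%02d", 1:20),
    r1 = base, r2 = 2L * base, r3 = base
  )
  meta <- data.frame(
    sample_id = c("r1", "r2", "r3"), bait = "b",
    condition = "selected", replicate = 1:3
  )
  x <- y2h_counts(counts, meta)
  sf <- size_factors(x, "median_of_ratios", rescale = FALSE)
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(sf[3] / sf[1]), 1)
  norm <- normalize_median_of_ratios(x)
  m <- count_matrix(norm)
  expect_equal(m[, "r1"], m[, "r2"])

  # independent geometric-mean/median computation on a 4x3 hand matrix
  hand <- matrix(
    c(
      10, 20, 30,
      5, 5, 5,
      100, 50, 200,
      1, 2, 4
    ),
    nrow = 4, byrow = TRUE
  )
  hcounts <- data.frame(prey = paste0("p", 1:4), a = hand[, 1], b = hand[, 2], c = hand[, 3])
  hx <- y2h_counts(hcounts, data.frame(
    sample_id = c("a", "b", "c"), bait = "b", condition = "selected",
    replicate = 1:3
  ))
  geo <- apply(hand, 1, function(r) exp(mean(log(r))))
  expected <- apply(hand / geo, 2, median)
  got <- size_factors(hx, "median_of_ratios", rescale = FALSE)
  expect_equal(unname(got), unname(expected))

  # all-zero-overlap group errors
  z <- data.frame(prey = c("p1", "p2"), a = c(0L, 3L), b = c(4L, 0L))
  zx <- y2h_counts(z, data.frame(
    sample_id = c("a", "b"), bait = "b", condition = "selected",
    replicate = 1:2
  ))
  expect_error(size_factors(zx, "median_of_ratios"), "all-positive")
})

test_that("normalizations preserve zeros", {
  x <- tiny_counts(n_preys = 6, seed = 9, lambda = 2)
  zero_mask <- count_matrix(x) == 0
  expect_true(any(zero_mask))
  lens <- stats::setNames(rep(300, 6), x$prey)
  for (norm in list(
    normalize_library_size(x),
    normalize_tpm(x, lens),
    normalize_median_of_ratios(x),
    normalize_ruvs(x)
  )) {
    expect_true(all(count_matrix(norm)[zero_mask] == 0))
  }
})

test_that("RUVs removes a planted replicate-wise shift and respects k", {
  set.seed(21)
  n_preys <- 60
  mu <- rlnorm(n_preys, log(200), 1)
  make <- function() rpois(n_preys, mu)
  counts <- data.frame(
    prey = sprintf("p%02d", 1:n_preys),
    b1_S_r1 = make(), b1_S_r2 = make(), b1_S_r3 = make(),
    b1_N_r1 = make(), b1_N_r2 = make(), b1_N_r3 = make()
  )
  # plant a multiplicative batch shift on one selected replicate
  counts$b1_S_r2 <- as.integer(round(counts$b1_S_r2 * 3))
  meta <- data.frame(
    sample_id = names(counts)[-1], bait = "b1",
    condition = rep(c("selected", "non_selected"), each = 3),
    replicate = rep(1:3, 2)
  )
  x <- y2h_counts(counts, meta)
  corrected <- normalize_ruvs(x, k = 1)
  lm_before <- log(count_matrix(x)[, 1:3] + 1)
  lm_after <- log(count_matrix(corrected)[, 1:3] + 1)
  spread <- function(m) mean(apply(m, 1, sd))
  expect_lt(spread(lm_after), 0.35 * spread(lm_before))

  # independent check: within-group centering + rank-1 SVD removal on logs
  ly <- t(log(count_matrix(x)[, 1:3] + 1))
  d <- sweep(ly, 2, colMeans(ly))
  sv <- svd(d)
  w <- sv$u[, 1, drop = FALSE] * sv$d[1]
  manual <- ly - w %*% solve(crossprod(w), crossprod(w, d))
  expect_equal(
    unname(t(lm_after)), unname(manual),
    tolerance = 1e-8
  )

  expect_equal(
    count_matrix(normalize_ruvs(x, k = 0)),
    count_matrix(x)
  )
  # identical replicates carry no unwanted variation to estimate
  same <- counts
  same$b1_S_r2 <- same$b1_S_r1
  same$b1_S_r3 <- same$b1_S_r1
  same$b1_N_r2 <- same$b1_N_r1
  same$b1_N_r3 <- same$b1_N_r1
  xs <- y2h_counts(same, meta)
  expect_equal(
    count_matrix(normalize_ruvs(xs, k = 1)),
    count_matrix(xs),
    tolerance = 1e-6
  )
  expect_error(
    normalize_ruvs(x, k = 1, replicate_groups = list(g = "b1_S_r1")),
    "size 1"
  )
  expect_error(normalize_ruvs(x, k = 10), "smaller than the number")
})

test_that("per-prey CV matches its definition and flags zero means", {
  counts <- data.frame(
    prey = c("pa", "pb", "pc"),
    r1 = c(10L, 0L, 5L), r2 = c(10L, 0L, 10L), r3 = c(10L, 0L, 15L)
  )
  meta <- data.frame(
    sample_id = c("r1", "r2", "r3"), bait = "b",
    condition = "selected", replicate = 1:3
  )
  cv <- prey_cv(y2h_counts(counts, meta))
  expect_equal(cv$cv[cv$prey == "pa"], 0)
  expect_true(is.na(cv$cv[cv$prey == "pb"]))
  expect_equal(cv$cv[cv$prey == "pc"], sd(c(5, 10, 15)) / 10)
})

test_that("pairwise Pearson matrix is symmetric with unit diagonal", {
  x <- tiny_counts(n_preys = 10, seed = 2, n_replicates = 3)
  r <- pairwise_pearson(x, "selected")
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, nrow(r)))
  m <- count_matrix(x)
  ids <- sample_meta(x)$sample_id[sample_meta(x)$condition == "selected"]
  expect_equal(
    r[ids[1], ids[2]],
    cor(m[, ids[1]], m[, ids[2]])
  )
  # a duplicated sample correlates perfectly; an anti-pattern gives -1
  counts <- data.frame(
    prey = c("p1", "p2"), a = c(1L, 9L), b = c(1L, 9L), c = c(9L, 1L)
  )
  meta <- data.frame(
    sample_id = c("a", "b", "c"), bait = "b",
    condition = "non_selected", replicate = 1:3
  )
  r2 <- pairwise_pearson(y2h_counts(counts, meta), "non_selected")
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)
})

test_that("normalization report compares methods with signed-rank tests", {
  x <- tiny_counts(n_preys = 30, seed = 13, n_replicates = 3, lambda = 200)
  rep <- normalization_report(x, methods = c("raw", "library_size"))
  expect_s3_class(rep, "y2h_norm_report")
  expect_true(all(rep$pearson$pearson >= -1 & rep$pearson$pearson <= 1,
    na.rm = TRUE
  ))
  expect_true(all(rep$cv$cv >= 0, na.rm = TRUE))
  expect_true(all(rep$wilcoxon$p_value >= 0 & rep$wilcoxon$p_value <= 1,
    na.rm = TRUE
  ))
  # paired signed-rank comparison is symmetric in the method order
  a <- rep$cv$cv[rep$cv$method == "raw"]
  b <- rep$cv$cv[rep$cv$method == "library_size"]
  keep <- is.finite(a) & is.finite(b)
  p_ab <- suppressWarnings(
    wilcox.test(a[keep], b[keep], paired = TRUE, alternative = "less")
  )$p.value
  p_ba <- suppressWarnings(
    wilcox.test(b[keep], a[keep], paired = TRUE, alternative = "greater")
  )$p.value
  expect_equal(p_ab, p_ba)
})
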