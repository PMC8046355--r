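test_that("the enrichment chain reproduces the worked 4-prey example", {
  enr <- tibble::tibble(
    bait = "b1", prey = paste0("p", 1:4),
    pvalue = c(0.001, 0.2, 0.6, 0.9),
    log2fc = c(3, 2, -1, 4)
  )
  params <- score_params(
    enrich_alpha = 1, enrich_windows = 2,
    enrich_fold_change = -Inf
  )
  got <- enrichment_score(enr, params)$enrichment
  # E(p) = (.75, .5, .25, 0); windows {p1,p2} and {p3,p4};
  # within-window E(f) = (.5, 0, 0, .5); spread/size factor = .125 in both;
  # combined = (.8125, .5, .25, .0625), rescaled by .8125
  expect_equal(got, c(1, 8 / 13, 4 / 13, 1 / 13))
  expect_equal(got, oracle_enrichment(enr$pvalue, enr$log2fc, 1, 2))
})

test_that("pairs beyond alpha score zero and empty inputs stay empty", {
  enr <- tibble::tibble(
    bait = "b1", prey = paste0("p", 1:3),
    pvalue = c(0.2, 0.5, 0.9), log2fc = c(5, 1, 2)
  )
  sc <- enrichment_score(enr, score_params(enrich_alpha = 0.1))
  expect_equal(sc$enrichment, c(0, 0, 0))
  expect_equal(nrow(enrichment_score(enr[0, ])), 0)
})

test_that("duplicating all pairs across a second bait preserves the ordering", {
  set.seed(41)
  enr <- tibble::tibble(
    bait = "b1", prey = sprintf("p%02d", 1:20),
    pvalue = runif(20), log2fc = rnorm(20)
  )
  both <- dplyr::bind_rows(enr, dplyr::mutate(enr, bait = "b2"))
  s1 <- enrichment_score(enr)
  s2 <- enrichment_score(both)
  s2b1 <- s2[s2$bait == "b1", ]
  expect_equal(order(s1$enrichment), order(s2b1$enrichment))
  expect_equal(s1$enrichment, s2b1$enrichment, tolerance = 0.06)
})

test_that("missing p and f values are treated conservatively", {
  enr <- tibble::tibble(
    bait = "b1", prey = c("p1", "p2", "p3"),
    pvalue = c(0.01, NA, 0.5), log2fc = c(2, NA, 1)
  )
  sc <- enrichment_score(enr)
  expect_equal(sc$enrichment[1], 1)
  expect_gte(sc$enrichment[2], 0) # NA p counts as 1, still in G at alpha = 1
  expect_true(all(sc$enrichment >= 0 & sc$enrichment <= 1))
})

test_that("specificity rewards bait-specific enrichment and applies the f < 0 rule", {
  pw <- tibble::tibble(
    bait = c("bA", "bA", "bB", "bC", "bB", "bC"),
    bait_other = c("bB", "bC", "bA", "bA", "bC", "bB"),
    prey = "p1",
    log2fc = c(4, 4.2, -4, -4.2, 0.1, -0.1),
    pvalue = c(1e-6, 1e-7, 1e-6, 1e-7, 0.9, 0.9)
  )
  s <- specificity_score(pw)
  expect_equal(s$specificity[s$bait == "bA"], 1)
  # bC saw the prey only through negative or weak contrasts
  expect_lt(s$specificity[s$bait == "bC"], s$specificity[s$bait == "bA"])

  # all-negative fold-changes zero the score outright
  neg <- tibble::tibble(
    bait = c("bA", "bA"), bait_other = c("bB", "bC"), prey = "p1",
    log2fc = c(-2, -3), pvalue = c(1e-5, 1e-5)
  )
  pos <- tibble::tibble(
    bait = c("bB", "bC"), bait_other = c("bA", "bA"), prey = "p1",
    log2fc = c(2, 3), pvalue = c(1e-5, 1e-5)
  )
  s2 <- specificity_score(dplyr::bind_rows(neg, pos))
  expect_equal(s2$specificity[s2$bait == "bA"], 0)
  expect_error(specificity_score(neg[0, ]), "at least 2")
})

test_that("the specificity chain matches the loops-only oracle", {
  set.seed(57)
  for (rep in 1:5) {
    n_b <- sample(2:4, 1)
    n_p <- sample(5:20, 1)
    baits <- paste0("b", seq_len(n_b))
    grid <- expand.grid(
      bait = baits, bait_other = baits, prey = sprintf("p%02d", seq_len(n_p)),
      stringsAsFactors = FALSE
    )
    grid <- grid[grid$bait != grid$bait_other, ]
    key <- paste(pmin(grid$bait, grid$bait_other),
      pmax(grid$bait, grid$bait_other), grid$prey)
    first <- !duplicated(key)
    p <- runif(sum(first))
    f <- rnorm(sum(first), sd = 2)
    grid$pvalue <- p[match(key, key[first])]
    grid$log2fc <- f[match(key, key[first])]
    flip <- grid$bait > grid$bait_other
    grid$log2fc[flip] <- -grid$log2fc[flip]
    got <- specificity_score(tibble::as_tibble(grid))
    want <- oracle_specificity(
      data.frame(
        bait = grid$bait, bait_other = grid$bait_other,
        prey = grid$prey, p = grid$pvalue, f = grid$log2fc
      ),
      alpha = 1, b = 10, fc = 0
    )
    got <- got[order(got$bait, got$prey), ]
    expect_equal(got$specificity, want$s, tolerance = 1e-12)
  }
})

test_that("the in-frame score is the rescaled ascending rank of rho", {
  inf <- tibble::tibble(
    bait = "b", prey = c("p1", "p2", "p3"),
    rho = c(-2, 0, 3)
  )
  expect_equal(inframe_score(inf)$inframe, c(1 / 3, 2 / 3, 1))
  one <- tibble::tibble(bait = "b", prey = "p1", rho = 5)
  expect_equal(inframe_score(one)$inframe, 1)
  zero <- tibble::tibble(
    bait = "b", prey = c("p1", "p2"),
    rho = c(NA_real_, 2)
  )
  expect_equal(inframe_score(zero)$inframe, c(0, 1))
})

test_that("Borda aggregation is a rescaled mean rank within baits", {
  sc <- tibble::tibble(
    bait = "b", prey = c("p1", "p2"),
    enrichment = c(1, 0), specificity = c(0, 1), inframe = c(0.5, 0.5)
  )
  expect_equal(borda_ensemble(sc)$borda, c(1, 1))
  # identical orderings are preserved
  sc2 <- tibble::tibble(
    bait = "b", prey = paste0("p", 1:4),
    enrichment = c(0.9, 0.5, 0.2, 0.1),
    specificity = c(1, 0.6, 0.3, 0),
    inframe = c(0.8, 0.7, 0.1, 0)
  )
  b <- borda_ensemble(sc2)$borda
  expect_equal(order(b, decreasing = TRUE), 1:4)
  # a constant component leaves the ordering to the informative ones
  sc3 <- dplyr::mutate(sc2, inframe = 0.4)
  b3 <- borda_ensemble(sc3)$borda
  mean_rank <- (rank(sc2$enrichment) + rank(sc2$specificity)) / 2
  expect_equal(order(b3), order(mean_rank))
})

test_that("scores are invariant to monotone transforms that respect windows", {
  set.seed(71)
  enr <- tibble::tibble(
    bait = "b", prey = sprintf("p%02d", 1:30),
    pvalue = runif(30), log2fc = rnorm(30)
  )
  params <- score_params(enrich_windows = 1, enrich_fold_change = -Inf)
  base <- enrichment_score(enr, params)$enrichment
  squeezed <- dplyr::mutate(enr, pvalue = pvalue^2, log2fc = log2fc * 3 + 1)
  expect_equal(
    enrichment_score(squeezed, params)$enrichment,
    base
  )
  inf <- tibble::tibble(bait = "b", prey = enr$prey, rho = rnorm(30))
  expect_equal(
    inframe_score(inf)$inframe,
    inframe_score(dplyr::mutate(inf, rho = atan(rho) * 5))$inframe
  )
})

test_that("random instances match the loops-only enrichment oracle exactly", {
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(3:50, 1)
    alpha <- sample(c(1, 0.5, 0.2), 1)
    b <- sample(c(1, 2, 5, 10), 1)
    p <- round(runif(n), sample(1:3, 1)) # ties likely
    f <- round(rnorm(n, sd = 2), 1)
    enr <- tibble::tibble(
      bait = "b", prey = sprintf("p%03d", seq_len(n)),
      pvalue = p, log2fc = f
    )
    got <- enrichment_score(
      enr,
      score_params(
        enrich_alpha = alpha, enrich_windows = b,
        enrich_fold_change = -Inf
      )
    )$enrichment
    expect_equal(got, oracle_enrichment(p, f, alpha, b), tolerance = 1e-12)
  }
})

test_that("compute_scores assembles components, flags ranges and orders output", {
  set.seed(3)
  enr <- tibble::tibble(
    bait = rep(c("b1", "b2"), each = 5),
    prey = rep(paste0("p", 1:5), 2),
    pvalue = runif(10), log2fc = rnorm(10)
  )
  pw <- tibble::tibble(
    bait = rep(c("b1", "b2"), each = 5),
    bait_other = rep(c("b2", "b1"), each = 5),
    prey = rep(paste0("p", 1:5), 2),
    log2fc = c(rnorm(5), -rnorm(5)), pvalue = rep(runif(5), 2)
  )
  inf <- tibble::tibble(
    bait = rep(c("b1", "b2"), each = 5),
    prey = rep(paste0("p", 1:5), 2),
    rho = c(rnorm(4), NA, rnorm(5))
  )
  sc <- compute_scores(enr, pw, inf)
  expect_s3_class(sc, "y2h_scores")
  expect_equal(nrow(sc), 10)
  for (col in c("enrichment", "specificity", "inframe", "borda")) {
    expect_true(all(sc[[col]] >= 0 & sc[[col]] <= 1))
  }
  expect_equal(max(sc$enrichment), 1)
  expect_equal(glance(sc)$n_baits, 2)
  expect_equal(nrow(tidy(sc)), 10)
  expect_s3_class(autoplot(sc), "ggplot")
})
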