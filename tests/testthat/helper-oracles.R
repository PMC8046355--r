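# Independent, loops-only oracles used to validate the vectorized
# implementations. These deliberately transcribe the score equations and
# AUC definitions one term at a time and share no code with R/.

oracle_rank_asc <- function(x) {
  # competition (minimum) rank, ascending
  vapply(x, function(v) 1L + sum(x < v), integer(1))
}

oracle_window <- function(p, alpha, b) {
  w <- alpha / b
  l <- ceiling(p / w)
  if (l < 1) l <- 1
  if (l > b) l <- b
  l
}

# enrichment chain: p-value ranks, within-window fold-change ranks,
# combined and rescaled; returns one score per input row
oracle_enrichment <- function(p, f, alpha, b) {
  n <- length(p)
  member <- which(p <= alpha)
  e <- rep(0, n)
  if (length(member) == 0) {
    return(e)
  }
  np <- length(member)
  rp <- oracle_rank_asc(p[member])
  ep <- (np - rp) / np
  win <- vapply(
    p[member], oracle_window, numeric(1),
    alpha = alpha, b = b
  )
  comb <- numeric(np)
  for (i in seq_len(np)) {
    in_w <- which(win == win[i])
    rf <- 1L + sum(f[member][in_w] > f[member][i])
    max_rf <- max(vapply(
      in_w,
      function(j) 1L + sum(f[member][in_w] > f[member][j]), integer(1)
    ))
    ef <- (max_rf - rf) / max_rf
    spread <- (max(ep[in_w]) - min(ep[in_w])) / length(in_w)
    comb[i] <- ep[i] + spread * ef
  }
  e[member] <- comb
  if (max(e) > 0) e <- e / max(e)
  e
}

# specificity chain over ordered triples (bait, bait_other, prey);
# the canonical triple of each unordered pair carries |f| into the
# fold-change ranks, and a directed triple is zeroed when f < fc or
# p > alpha before averaging over the n_b - 1 comparisons of each bait
oracle_specificity <- function(df, alpha, b, fc = 0) {
  baits <- unique(c(df$bait, df$bait_other))
  n_b <- length(baits)
  df$p[is.na(df$p)] <- 1
  df$f[is.na(df$f)] <- 0
  key <- paste(
    pmin(df$bait, df$bait_other), pmax(df$bait, df$bait_other),
    df$prey
  )
  canon_rows <- which(!duplicated(key))
  cp <- df$p[canon_rows]
  cf <- abs(df$f[canon_rows])
  member <- which(cp <= alpha)
  p_sc <- rep(0, length(canon_rows))
  f_in <- rep(0, length(canon_rows))
  if (length(member) > 0) {
    np <- length(member)
    rp <- oracle_rank_asc(cp[member])
    ep <- (np - rp) / np
    win <- vapply(
      cp[member], oracle_window, numeric(1),
      alpha = alpha, b = b
    )
    for (i in seq_len(np)) {
      in_w <- which(win == win[i])
      rf <- 1L + sum(cf[member][in_w] > cf[member][i])
      max_rf <- max(vapply(
        in_w,
        function(j) 1L + sum(cf[member][in_w] > cf[member][j]),
        integer(1)
      ))
      ef <- (max_rf - rf) / max_rf
      spread <- (max(ep[in_w]) - min(ep[in_w])) / length(in_w)
      p_sc[member[i]] <- ep[i]
      f_in[member[i]] <- spread * ef
    }
  }
  pos <- match(key, key[canon_rows])
  out <- data.frame(
    bait = df$bait, prey = df$prey,
    p_part = p_sc[pos], f_part = f_in[pos]
  )
  drop <- df$f < fc | df$p > alpha
  out$p_part[drop] <- 0
  out$f_part[drop] <- 0
  agg <- aggregate(cbind(p_part, f_part) ~ bait + prey, out, sum)
  agg$s <- (agg$p_part + agg$f_part) / (n_b - 1)
  if (max(agg$s) > 0) agg$s <- agg$s / max(agg$s)
  agg[order(agg$bait, agg$prey), c("bait", "prey", "s")]
}

oracle_inframe_score <- function(rho) {
  ok <- which(is.finite(rho))
  s <- rep(0, length(rho))
  if (length(ok)) {
    r <- vapply(ok, function(i) 1L + sum(rho[ok] < rho[i]), integer(1))
    s[ok] <- r / max(r)
  }
  s
}

# ROC AUC by explicit pairwise comparison (ties count 1/2)
oracle_roc_auc <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# step-wise PR AUC from an explicit precision/recall table
oracle_pr_auc <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels)
  prev_recall <- 0
  area <- 0
  for (t in th) {
    called <- scores >= t
    precision <- sum(labels & called) / sum(called)
    recall <- sum(labels & called) / n_pos
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}
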