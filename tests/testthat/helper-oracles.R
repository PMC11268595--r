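# Independent naive oracles: each is a direct, loop-based transcription of
# the printed formulas, deliberately sharing no code with the package
# implementation it checks.

# per-group confusion counts and rates by explicit row loops
naive_group_metrics <- function(df) {
  out <- list()
  for (g in sort(unique(df$group))) {
    tp <- fp <- tn <- fn <- 0
    for (i in seq_len(nrow(df))) {
      if (df$group[i] != g) next
      if (df$y_true[i] == 1 && df$y_pred[i] == 1) tp <- tp + 1
      if (df$y_true[i] == 0 && df$y_pred[i] == 1) fp <- fp + 1
      if (df$y_true[i] == 0 && df$y_pred[i] == 0) tn <- tn + 1
      if (df$y_true[i] == 1 && df$y_pred[i] == 0) fn <- fn + 1
    }
    n <- tp + fp + tn + fn
    f1_pos <- if (2 * tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
    f1_neg <- if (2 * tn + fn + fp == 0) 1 else 2 * tn / (2 * tn + fn + fp)
    out[[g]] <- list(
      tp = tp, fp = fp, tn = tn, fn = fn,
      s = (tp + fp) / n,
      tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
      macro_f1 = (f1_pos + f1_neg) / 2
    )
  }
  out
}

naive_dpr_overall <- function(s) {
  lo <- Inf; hi <- -Inf
  for (v in s) { if (v < lo) lo <- v; if (v > hi) hi <- v }
  lo / hi
}

naive_dpr_privileged <- function(s, star) {
  lo <- Inf
  for (g in names(s)) if (g != star && s[[g]] < lo) lo <- s[[g]]
  lo / s[[star]]
}

naive_eor_overall <- function(tpr, fpr, delta = 0.001) {
  min((min(unlist(tpr)) + delta) / (max(unlist(tpr)) + delta),
      (min(unlist(fpr)) + delta) / (max(unlist(fpr)) + delta))
}

naive_eor_privileged <- function(tpr, fpr, star, delta = 0.001) {
  t_term <- Inf; f_term <- Inf
  for (g in names(tpr)) {
    if (g == star) next
    t_term <- min(t_term, (tpr[[g]] + delta) / (tpr[[star]] + delta))
    f_term <- min(f_term, (fpr[[star]] + delta) / (fpr[[g]] + delta))
  }
  min(t_term, f_term)
}

# random small prediction table; every group has at least one subject of
# each class so all rates are defined
random_pred_table <- function() {
  k <- sample(2:4, 1)
  groups <- letters[seq_len(k)]
  rows <- lapply(groups, function(g) {
    n <- sample(5:50, 1)
    y <- c(0, 1, stats::rbinom(n - 2, 1, stats::runif(1, 0.2, 0.8)))
    data.frame(group = g, y_true = y,
               y_pred = stats::rbinom(n, 1, stats::runif(1, 0.2, 0.8)),
               score = stats::runif(n))
  })
  do.call(rbind, rows)
}

# best equalized-odds accuracy by exhaustive chord enumeration: for each
# group, every mixture of two deterministic thresholds traces the chord
# between their ROC points, so the achievable TPR ceiling at a given FPR is
# the maximum chord height there; the common target takes the minimum
# ceiling across groups.
naive_best_eo_accuracy <- function(scores, labels, groups, fpr_grid) {
  glev <- unique(groups)
  ceilings <- matrix(NA_real_, length(fpr_grid), length(glev))
  for (j in seq_along(glev)) {
    s <- scores[groups == glev[j]]
    y <- labels[groups == glev[j]]
    thr <- c(-Inf, sort(unique(s)))
    fpr <- tpr <- numeric(length(thr))
    for (i in seq_along(thr)) {
      fpr[i] <- sum(s > thr[i] & y == 0) / sum(y == 0)
      tpr[i] <- sum(s > thr[i] & y == 1) / sum(y == 1)
    }
    best <- rep(-Inf, length(fpr_grid))
    for (a in seq_along(thr)) {
      for (b in seq_along(thr)) {
        lo <- min(fpr[a], fpr[b]); hi <- max(fpr[a], fpr[b])
        idx <- which(fpr_grid >= lo - 1e-12 & fpr_grid <= hi + 1e-12)
        if (!length(idx)) next
        h <- if (hi - lo < 1e-12) max(tpr[a], tpr[b]) else
          tpr[a] + (tpr[b] - tpr[a]) * (fpr_grid[idx] - fpr[a]) / (fpr[b] - fpr[a])
        best[idx] <- pmax(best[idx], h)
      }
    }
    ceilings[, j] <- best
  }
  tpr_feas <- apply(ceilings, 1, min)
  pi_hat <- mean(labels)
  acc <- pi_hat * tpr_feas + (1 - pi_hat) * (1 - fpr_grid)
  list(accuracy = max(acc), fpr = fpr_grid[which.max(acc)],
       tpr = tpr_feas[which.max(acc)])
}

# Pearson X^2 by the textbook formula (no library call)
naive_chisq_stat <- function(g, y) {
  ct <- table(g, y)
  e <- outer(rowSums(ct), colSums(ct)) / sum(ct)
  sum((ct - e)^2 / e)
}

# permutation tails for independence of g and y. The permutation null is
# discrete, so a continuous reference p-value should land between the
# strict tail P(X^2 > obs) and the non-strict tail P(X^2 >= obs); both are
# returned (the jump between them is the equality mass at the observed
# statistic).
perm_chisq_tails <- function(g, y, B = 10000) {
  obs <- naive_chisq_stat(g, y)
  gt <- eq <- 0
  for (i in seq_len(B)) {
    v <- naive_chisq_stat(g, sample(y))
    if (v > obs + 1e-9) gt <- gt + 1
    else if (abs(v - obs) <= 1e-9) eq <- eq + 1
  }
  c(strict = gt / B, nonstrict = (gt + eq) / B)
}
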