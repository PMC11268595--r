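test_that("ROC curves enumerate thresholds and hull the separable and tiny cases", {
  # perfectly separating scores: hull contains (0, 1)
  roc <- build_roc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_true(any(roc$hull$fpr == 0 & roc$hull$tpr == 1))
  # endpoints always present
  expect_true(any(roc$points$fpr == 0 & roc$points$tpr == 0))
  expect_true(any(roc$points$fpr == 1 & roc$points$tpr == 1))

  # two distinct score values: at most 4 operating points incl. sentinels
  roc2 <- build_roc(c(0.3, 0.3, 0.7, 0.7), c(0, 1, 0, 1))
  expect_lte(nrow(roc2$points), 4)

  # single-class input: degenerate marker, no exception
  rocd <- build_roc(c(0.1, 0.9), c(1, 1))
  expect_true(rocd$degenerate)
})

test_that("the hull of an uninformative scorer approaches the diagonal", {
  set.seed(31)
  n <- 4000
  roc <- build_roc(runif(n), rbinom(n, 1, 0.5))
  h <- roc$hull
  auc <- sum(diff(h$fpr) * (head(h$tpr, -1) + tail(h$tpr, -1)) / 2)
  expect_lt(abs(auc - 0.5), 0.05)
})

test_that("identical score distributions give the unconstrained optimum with equal thresholds", {
  set.seed(5)
  n <- 400
  y <- rbinom(n, 1, 0.5)
  s <- plogis(1.5 * (2 * y - 1) + rnorm(n))
  g <- rep(c("a", "b"), n / 2)          # groups unrelated to scores
  pol <- fit_eo_policy(s, y, g, grid_resolution = 0.005)
  # unconstrained pooled optimum over single thresholds
  thr <- c(-Inf, sort(unique(s)))
  best_acc <- max(vapply(thr, function(t) mean((s > t) == (y == 1)), 0))
  er <- policy_expected_rates(pol, s, y, g)
  acc <- mean(y) * mean(er$expected_tpr) +
    (1 - mean(y)) * (1 - mean(er$expected_fpr))
  expect_gte(acc, best_acc - 0.02)      # constraint is (nearly) non-binding
  # never worse than the majority-class rule
  expect_gte(pol$accuracy, max(mean(y), 1 - mean(y)) - 0.005)
})

test_that("perfectly separable groups reach target (0, 1) with accuracy 1", {
  y <- rep(c(1, 0), each = 20)
  s <- ifelse(y == 1, runif(40, 0.8, 1), runif(40, 0, 0.2))
  g <- rep(c("a", "b"), 20)
  pol <- fit_eo_policy(s, y, g, grid_resolution = 0.01)
  expect_equal(unname(pol$target), c(0, 1))
  expect_equal(pol$accuracy, 1)
})

test_that("fitted policies achieve the common operating point exactly on the fitting data", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(c(60, 100, 150), 1)
    g <- sample(c("a", "b", "c")[seq_len(sample(2:3, 1))], n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y[g == unique(g)[1]])) < 2) next
    s <- plogis(ifelse(g == "a", 2, 0.7) * (2 * y - 1) + rnorm(n))
    pol <- tryCatch(fit_eo_policy(s, y, g, grid_resolution = 0.002),
                    error = function(e) NULL)
    if (is.null(pol)) next
    er <- policy_expected_rates(pol, s, y, g)
    ok <- !pol$groups$fallback[match(er$group, pol$groups$group)]
    expect_true(all(abs(er$expected_fpr[ok] - pol$target[["fpr"]]) < 1e-9))
    expect_true(all(abs(er$expected_tpr[ok] - pol$target[["tpr"]]) < 1e-9))
  }
})

test_that("degenerate groups fall back to the pooled threshold instead of failing", {
  y <- c(rbinom(50, 1, 0.5), rep(1, 6))
  s <- c(plogis(2 * (2 * y[1:50] - 1) + rnorm(50)), runif(6, 0.6, 1))
  g <- c(rep(c("a", "b"), 25), rep("c", 6))   # group c has positives only
  pol <- fit_eo_policy(s, y, g)
  expect_true(pol$groups$fallback[pol$groups$group == "c"])
  expect_false(any(pol$groups$fallback[pol$groups$group != "c"]))
  pred <- apply_policy(pol, s, g, seed = 3)
  expect_true(all(pred %in% 0:1))
})

test_that("a deterministic policy reduces to plain thresholding and reruns identically", {
  pol <- structure(list(
    target = c(fpr = 0.2, tpr = 0.8), prevalence = 0.5, accuracy = 0.8,
    grid_resolution = 0.01, seed = 1L,
    groups = tibble::tibble(group = "a", t_lo = 0.5, t_hi = 0.9, p = 1,
                            p_ignore = 0, achieved_fpr = 0.2,
                            achieved_tpr = 0.8, fallback = FALSE)),
    class = "eo_policy")
  s <- seq(0.05, 0.95, by = 0.1)
  g <- rep("a", length(s))
  expect_equal(apply_policy(pol, s, g, seed = 9), as.integer(s > 0.5))
  p1 <- apply_policy(pol, s, g, seed = 9)
  p2 <- apply_policy(pol, s, g, seed = 9)
  expect_identical(p1, p2)
})

test_that("randomized predictions are row-order invariant when keyed by subject id", {
  set.seed(23)
  n <- 200
  s <- runif(n)
  g <- rep(c("a", "b"), n / 2)
  y <- rbinom(n, 1, plogis(3 * (s - 0.5)))
  pol <- fit_eo_policy(s, y, g, grid_resolution = 0.01)
  ids <- sprintf("S%03d", seq_len(n))
  ord <- sample(n)
  p_direct <- apply_policy(pol, s, g, seed = 4, ids = ids)
  p_shuf <- apply_policy(pol, s[ord], g[ord], seed = 4, ids = ids[ord])
  expect_identical(p_direct[ord], p_shuf)
})

test_that("mixture predictions hit the expected selection rate", {
  # two thresholds with selection rates 0.2 and 0.6, mixed 0.3 / 0.7
  n <- 10000
  s <- (seq_len(n) - 0.5) / n              # uniform grid of scores
  pol <- structure(list(
    target = c(fpr = 0.4, tpr = 0.4), prevalence = 0.5, accuracy = 0.5,
    grid_resolution = 0.01, seed = 1L,
    groups = tibble::tibble(group = "a", t_lo = 0.8, t_hi = 0.4, p = 0.3,
                            p_ignore = 0, achieved_fpr = NA_real_,
                            achieved_tpr = NA_real_, fallback = FALSE)),
    class = "eo_policy")
  pred <- apply_policy(pol, s, rep("a", n), seed = 6)
  expected <- 0.3 * 0.2 + 0.7 * 0.6
  se <- sqrt(expected * (1 - expected) / n)
  expect_lt(abs(mean(pred) - expected), 3 * se)
})

test_that("unseen groups error without fallback and policies round-trip as JSON", {
  set.seed(2)
  y <- rbinom(80, 1, 0.5)
  s <- plogis(2 * (2 * y - 1) + rnorm(80))
  g <- rep(c("a", "b"), 40)
  pol <- fit_eo_policy(s, y, g, grid_resolution = 0.01)
  expect_error(apply_policy(pol, 0.5, "zz", fallback = FALSE), "zz")
  path <- withr::local_tempfile(fileext = ".json")
  write_policy(pol, path)
  pol2 <- read_policy(path)
  expect_equal(pol2$target, pol$target)
  expect_equal(as.data.frame(pol2$groups), as.data.frame(pol$groups))
  expect_identical(apply_policy(pol2, s, g, seed = 5),
                   apply_policy(pol, s, g, seed = 5))
})
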