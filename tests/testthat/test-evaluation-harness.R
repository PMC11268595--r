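small_cohort <- function(n = 40, seed = 2, sep = 1.5) {
  generate_cohort(cohort_config(
    attributes = list(group = c(a = n / 2, b = n / 2)),
    base_rate = c(a = 0.5, b = 0.5),
    modalities = list(
      list(name = "m1", dim = 3, separation = sep, noise_sd = 1),
      list(name = "m2", dim = 3, separation = sep, noise_sd = 1)),
    seed = seed))
}

test_that("every subject is tested exactly once per repeat and folds stratify the labels", {
  coh <- small_cohort(n = 40, seed = 3)
  pred <- run_repeated_cv(coh$features, coh$subjects$clinical_label,
                          coh$subjects, repeats = 2, folds = 5, seed = 1)
  for (m in c("m1", "m2")) {
    sub <- pred[pred$modality == m, ]
    expect_equal(nrow(sub), 80)
    counts <- table(sub$subject_id, sub[["repeat"]])
    expect_true(all(counts == 1))
  }
  # stratification: per-fold class counts within 1 of proportionality
  sub <- pred[pred$modality == "m1" & pred[["repeat"]] == 1, ]
  n_pos <- sum(coh$subjects$clinical_label)
  for (f in 1:5) {
    fold_pos <- sum(sub$y_true[sub$fold == f])
    expect_lte(abs(fold_pos - n_pos / 5), 1)
  }
})

test_that("the full pipeline is bit-for-bit reproducible from the master seed", {
  coh <- small_cohort(n = 40, seed = 4)
  spec <- attribute_spec("group", privileged = "a")
  run <- function() run_repeated_cv(
    coh$features, coh$subjects$clinical_label, coh$subjects,
    repeats = 2, folds = 4, seed = 11, mitigate = spec,
    grid_resolution = 0.01)
  expect_identical(run(), run())
})

test_that("a training fold missing a class is skipped with a message", {
  cfg <- cohort_config(
    attributes = list(group = c(a = 10, b = 10)),
    base_rate = c(a = 0.05, b = 0.05),
    modalities = list(list(name = "m", dim = 2, separation = 1, noise_sd = 1)),
    seed = 42)
  coh <- generate_cohort(cfg)
  # force exactly one positive subject
  coh$subjects$clinical_label <- c(1L, rep(0L, 19))
  expect_message(
    pred <- run_repeated_cv(coh$features, coh$subjects$clinical_label,
                            coh$subjects, repeats = 1, folds = 2, seed = 1),
    "single class")
  expect_lt(nrow(pred), 20)
})

test_that("majority fusion takes strict majorities and breaks ties by mean score", {
  base <- tibble::tibble(
    subject_id = "S1", "repeat" = 1L, fold = 1L, y_true = 1L,
    group = "a")
  three <- dplyr::bind_rows(base, base, base)
  three$modality <- c("x", "y", "z")
  three$mitigation <- "none"
  three$y_pred <- c(1L, 1L, 0L)
  three$score <- c(0.6, 0.7, 0.4)
  expect_equal(fuse_majority(three)$y_pred, 1L)

  two <- three[1:2, ]
  two$modality <- c("x", "y")
  two$y_pred <- c(1L, 0L)
  two$score <- c(0.9, 0.5)        # mean 0.7 > 0.5 breaks the tie toward 1
  expect_equal(fuse_majority(two)$y_pred, 1L)
  two$score <- c(0.5, 0.3)        # mean 0.4 breaks toward 0
  expect_equal(fuse_majority(two)$y_pred, 0L)

  # unanimity: fused equals the members
  three$y_pred <- c(1L, 1L, 1L)
  expect_equal(fuse_majority(three)$y_pred, 1L)
})

test_that("weighted fusion averages scores with a strict 0.5 decision rule", {
  base <- tibble::tibble(
    subject_id = "S1", "repeat" = 1L, fold = 1L, y_true = 1L, group = "a",
    mitigation = "none")
  three <- dplyr::bind_rows(base, base, base)
  three$modality <- c("x", "y", "z")
  three$y_pred <- c(1L, 0L, 1L)
  three$score <- c(0.6, 0.4, 0.9)
  fw <- fuse_weighted(three)
  expect_equal(fw$score, mean(c(0.6, 0.4, 0.9)))
  expect_equal(fw$y_pred, 1L)
  # exactly 0.5 is classified negative (strict inequality)
  three$score <- c(0.5, 0.5, 0.5)
  expect_equal(fuse_weighted(three)$y_pred, 0L)
  # scores outside [0,1] are rejected
  three$score <- c(1.2, 0.4, 0.4)
  expect_error(fuse_weighted(three), "outside")
})

test_that("weighted fusion of copies of one classifier reproduces that classifier", {
  coh <- small_cohort(n = 30, seed = 6)
  pred <- run_repeated_cv(coh$features["m1"], coh$subjects$clinical_label,
                          coh$subjects, repeats = 1, folds = 3, seed = 2)
  copy <- pred
  copy$modality <- "m1_copy"
  both <- dplyr::bind_rows(pred, copy)
  fused <- fuse_weighted(both)
  ord <- order(fused$subject_id)
  base_ord <- order(pred$subject_id)
  expect_equal(fused$score[ord], pred$score[base_ord])
  expect_equal(fused$y_pred[ord], pred$y_pred[base_ord])
})

test_that("misaligned member tables are rejected with the offending keys", {
  base <- tibble::tibble(
    subject_id = c("S1", "S2"), "repeat" = 1L, fold = 1L, y_true = 1L,
    group = "a", mitigation = "none", y_pred = 1L, score = 0.8)
  a <- base; a$modality <- "x"
  b <- base[1, ]; b$modality <- "y"
  expect_error(fuse_majority(dplyr::bind_rows(a, b)), "S2")
})

test_that("per-repeat fairness summaries recover exact fixture targets", {
  cfg <- rate_fixture_config(data.frame(
    group = c("a", "b"), n_pos = c(20, 10), n_neg = c(20, 10),
    tpr = c(0.9, 0.8), fpr = c(0.1, 0.2)), seed = 8)
  fx <- generate_prediction_fixture(cfg, repeats = 3)
  spec <- attribute_spec("group", privileged = "a", min_group_size = 1)
  rep <- summarize_fairness(fx, specs = list(group = spec), delta = 0.001)
  eor <- rep$metrics[rep$metrics$metric == "eor_overall", ]
  expect_equal(nrow(eor), 3)
  expect_equal(eor$value,
               rep(min(0.801 / 0.901, 0.101 / 0.201), 3), tolerance = 1e-12)
  # single-repeat summaries equal that repeat's value
  one <- summarize_fairness(fx[fx[["repeat"]] == 1, ], specs = list(spec))
  s <- one$summary[one$summary$metric == "eor_overall", ]
  expect_equal(s$median, min(0.801 / 0.901, 0.101 / 0.201), tolerance = 1e-12)
  expect_equal(s$iqr, 0)
})

test_that("identical group rates in every repeat give EOR exactly one", {
  cfg <- rate_fixture_config(data.frame(
    group = c("a", "b"), n_pos = c(10, 10), n_neg = c(10, 10),
    tpr = c(0.8, 0.8), fpr = c(0.2, 0.2)))
  fx <- generate_prediction_fixture(cfg, repeats = 4)
  spec <- attribute_spec("group", privileged = "a", min_group_size = 1)
  rep <- summarize_fairness(fx, specs = list(spec))
  ratios <- rep$metrics[grepl("dpr|eor", rep$metrics$metric), ]
  expect_true(all(ratios$value == 1))
})

test_that("rank-sum comparisons behave at the boundaries", {
  # identical samples: p = 1 by symmetry
  expect_equal(compare_distributions(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # frozen exact enumeration: U = 0 with n = m = 3 has two-sided p = 2/20
  expect_equal(compare_distributions(c(1, 2, 3), c(10, 11, 12))$p_value, 0.1)
  # two-sided symmetry under swapping
  a <- c(0.3, 0.5, 0.6, 0.9)
  b <- c(0.2, 0.4, 0.7)
  expect_equal(compare_distributions(a, b)$p_value,
               compare_distributions(b, a)$p_value)
  # all values tied: vacuous comparison, p = 1 with a warning
  expect_warning(r <- compare_distributions(c(1, 1), c(1, 1, 1)), "tied")
  expect_equal(r$p_value, 1)
})
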