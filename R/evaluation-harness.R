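#' Reference ridge-logistic classifier
#'
#' A minimal per-modality scorer for the cross-validation harness: an
#' L2-regularized linear logistic model with within-fold feature
#' standardization (centers and scales learned on the training fold only).
#' Any object with the same `fit`/`score` contract — `fit(x, y)` returning a
#' model and `score(model, x)` returning probabilities in `[0, 1]`, higher
#' meaning more likely positive — plugs into [run_repeated_cv()].
#'
#' @param lambda Ridge penalty passed to [glmnet::glmnet()] (default 0.05).
#' @return An object of class `classifier_spec`.
#' @export
classifier_logistic <- function(lambda = 0.05) {
  structure(list(
    name = "ridge_logistic",
    fit = function(x, y) {
      x <- as.matrix(x)
      center <- colMeans(x)
      scale <- apply(x, 2, stats::sd)
      scale[scale == 0] <- 1
      xs <- sweep(sweep(x, 2, center), 2, scale, "/")
      if (ncol(xs) < 2) xs <- cbind(xs, .pad = 0)   # glmnet needs >= 2 columns
      fit <- glmnet::glmnet(xs, factor(y, levels = 0:1), family = "binomial",
                            alpha = 0, lambda = lambda, standardize = FALSE)
      list(fit = fit, center = center, scale = scale, lambda = lambda)
    },
    score = function(model, x) {
      x <- as.matrix(x)
      xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
      if (ncol(xs) < length(rownames(model$fit$beta))) xs <- cbind(xs, .pad = 0)
      as.numeric(stats::predict(model$fit, newx = xs, s = model$lambda,
                                type = "response"))
    }
  ), class = "classifier_spec")
}

# label-stratified fold assignment: within each class, shuffled members are
# dealt into k folds so per-fold class counts differ by at most one; the
# fold receiving the remainder is itself randomized
make_stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cls in unique(labels)) {
    idx <- which(labels == cls)
    fold[sample(idx)] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  fold
}

#' Repeated stratified cross-validation with optional EO mitigation
#'
#' The evaluation protocol: `repeats` independent label-stratified
#' `folds`-fold partitions of the cohort; per training fold and per modality
#' the classifier is fitted and the held-out fold scored; when a mitigation
#' attribute is given, an equalized-odds threshold policy
#' ([fit_eo_policy()]) is additionally fitted on the training fold's own
#' scores and applied to the test fold, and the table carries both the
#' unmitigated and the mitigated predictions. The whole run is reproducible
#' from the single `seed`.
#'
#' @param features Named list of numeric matrices (subjects x features), one
#'   per modality, rows aligned with `subjects`.
#' @param labels Binary 0/1 outcome per subject.
#' @param subjects Subject table carrying `subject_id` and the demographic
#'   columns; copied onto the output rows.
#' @param classifier A [classifier_logistic()]-style spec.
#' @param repeats,folds Number of repeats R (default 100) and folds K
#'   (default 5).
#' @param seed Master seed for partitioning, fitting and mitigation
#'   randomization.
#' @param mitigate Optional [attribute_spec()] naming the sensitive
#'   attribute for threshold fitting, or `NULL` for no mitigation.
#' @param mitigate_fit `"train"` (default) fits the policy on the training
#'   fold's scores — no test-label leakage, at the price of in-sample ROC
#'   optimism; `"pooled"` fits on training + test scores of the repeat.
#' @param grid_resolution FPR grid step of the policy optimizer.
#' @return A prediction tibble: `subject_id`, `repeat`, `fold`, `y_true`,
#'   `score`, `y_pred`, `modality`, `mitigation` (`"none"` or the attribute
#'   name), plus the demographic columns of `subjects`. Each subject
#'   appears exactly once per (repeat, modality, mitigation tag).
#' @export
run_repeated_cv <- function(features, labels, subjects,
                            classifier = classifier_logistic(),
                            repeats = 100L, folds = 5L, seed = 1L,
                            mitigate = NULL,
                            mitigate_fit = c("train", "pooled"),
                            grid_resolution = 0.001) {
  stopifnot(is.list(features), length(features) >= 1, !is.null(names(features)),
            repeats >= 1, folds >= 2, all(labels %in% 0:1), !anyNA(labels))
  mitigate_fit <- match.arg(mitigate_fit)
  n <- length(labels)
  stopifnot(nrow(subjects) == n,
            all(vapply(features, nrow, 0L) == n))
  ids <- as.character(subjects$subject_id)
  mit_groups <- if (!is.null(mitigate)) attribute_groups(mitigate, subjects)

  set.seed(as.integer(seed))
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    fold_of <- make_stratified_folds(labels, folds)
    rows <- list()
    for (f in seq_len(folds)) {
      test <- which(fold_of == f)
      train <- which(fold_of != f)
      if (length(unique(labels[train])) < 2 ||
          min(table(labels[train])) < 2) {
        message("repeat ", r, " fold ", f,
                ": training fold has (almost) a single class; fold skipped")
        next
      }
      for (m in names(features)) {
        x <- features[[m]]
        model <- classifier$fit(x[train, , drop = FALSE], labels[train])
        s_test <- classifier$score(model, x[test, , drop = FALSE])
        base <- tibble::tibble(
          subject_id = ids[test], "repeat" = r, fold = f,
          y_true = as.integer(labels[test]),
          score = s_test, y_pred = as.integer(s_test > 0.5),
          modality = m, mitigation = "none")
        rows[[length(rows) + 1]] <- base
        if (!is.null(mitigate)) {
          fit_idx <- if (mitigate_fit == "train") train else c(train, test)
          s_fit <- if (mitigate_fit == "train") {
            classifier$score(model, x[fit_idx, , drop = FALSE])
          } else {
            c(classifier$score(model, x[train, , drop = FALSE]), s_test)
          }
          ok <- !is.na(mit_groups[fit_idx])
          pol <- tryCatch(
            fit_eo_policy(s_fit[ok], labels[fit_idx][ok],
                          mit_groups[fit_idx][ok],
                          grid_resolution = grid_resolution,
                          seed = seed + r),
            error = function(e) NULL)
          y_mit <- if (is.null(pol)) {
            as.integer(s_test > 0.5)   # policy unfittable: fall through
          } else {
            apply_policy(pol, s_test, mit_groups[test], seed = seed + r,
                         ids = paste(ids[test], r, f, m, sep = "/"))
          }
          mit <- base
          mit$y_pred <- y_mit
          mit$mitigation <- mitigate$name
          rows[[length(rows) + 1]] <- mit
        }
      }
    }
    out[[r]] <- dplyr::bind_rows(rows)
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {           # every fold skipped (degenerate labels)
    res <- tibble::tibble(
      subject_id = character(), "repeat" = integer(), fold = integer(),
      y_true = integer(), score = numeric(), y_pred = integer(),
      modality = character(), mitigation = character())
  }
  demo <- subjects[, setdiff(names(subjects), c("score", "y_pred")), drop = FALSE]
  dplyr::left_join(res, demo, by = "subject_id")
}

fusion_key <- c("subject_id", "repeat", "fold", "y_true", "mitigation")

check_aligned <- function(pred) {
  m <- length(unique(pred$modality))
  if (m < 2) stop("fusion needs at least two modalities", call. = FALSE)
  counts <- dplyr::count(pred, dplyr::across(dplyr::all_of(fusion_key)))
  bad <- counts[counts$n != m, ]
  if (nrow(bad)) {
    stop("misaligned prediction tables; offending keys: ",
         paste(utils::head(paste(bad$subject_id, bad$`repeat`, bad$fold,
                                 sep = ":"), 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(m)
}

#' Late fusion of unimodal classifiers
#'
#' `fuse_majority()` takes the majority vote of the member predictions;
#' with an even number of members, ties are broken by the
#' probability-weighted rule (mean member score above 0.5). `fuse_weighted()`
#' averages the member probability scores and thresholds the mean at 0.5
#' (strictly greater). Both return rows tagged with the fusion name in the
#' `modality` column; the fused `score` is the mean member score.
#'
#' @param pred A long prediction table from [run_repeated_cv()] containing
#'   two or more modalities, aligned on (subject, repeat, fold, mitigation).
#' @param name Modality tag for the fused rows.
#' @return A prediction tibble with the same columns as the input.
#' @export
fuse_majority <- function(pred, name = "fusion_majority") {
  check_aligned(pred)
  fuse_impl(pred, name, function(y_pred, score) {
    votes <- sum(y_pred)
    m <- length(y_pred)
    if (2 * votes != m) as.integer(2 * votes > m)
    else as.integer(mean(score) > 0.5)       # even split: weighted tie-break
  })
}

#' @rdname fuse_majority
#' @export
fuse_weighted <- function(pred, name = "fusion_weighted") {
  if (any(pred$score < 0 | pred$score > 1)) {
    stop("member scores outside [0, 1]; cannot fuse probabilities",
         call. = FALSE)
  }
  if (length(unique(pred$modality)) > 1) check_aligned(pred)
  fuse_impl(pred, name, function(y_pred, score) as.integer(mean(score) > 0.5))
}

fuse_impl <- function(pred, name, rule) {
  extra <- setdiff(names(pred), c(fusion_key, "score", "y_pred", "modality"))
  fused <- pred |>
    dplyr::group_by(dplyr::across(dplyr::all_of(fusion_key))) |>
    dplyr::summarise(
      score_out = mean(.data$score),
      y_pred = rule(.data$y_pred, .data$score),
      dplyr::across(dplyr::all_of(extra), dplyr::first),
      .groups = "drop") |>
    dplyr::rename(score = "score_out") |>
    dplyr::mutate(modality = name)
  fused[, names(pred)]
}

#' Per-repeat fairness metrics from a prediction table
#'
#' For every (attribute, modality, mitigation tag) and every repeat, pools
#' the test folds of that repeat, computes per-group rates, the four
#' fairness ratios, and the pooled macro-averaged F1 and accuracy — one
#' value per repeat per metric, summarized by median, quartiles and
#' 1.5-IQR outlier counts. Groups below the attribute's minimum size (or
#' with a missing group value) are excluded from that attribute's metrics
#' only.
#'
#' @param pred Prediction table from [run_repeated_cv()] (optionally with
#'   fused rows appended).
#' @param specs List of [attribute_spec()] objects; defaults to the
#'   standard four, restricted to columns present in `pred`.
#' @param delta Smoothing constant of the equalized odds ratios.
#' @return An object of class `fairness_report`: `metrics` (long tibble
#'   `attribute`, `modality`, `mitigation`, `repeat`, `metric`, `value`,
#'   `note` — undefined values are explicit `NA` rows with a reason, never
#'   dropped) and `summary` (median/IQR/outlier/undefined counts per
#'   attribute x modality x mitigation x metric), plus `delta`.
#' @export
summarize_fairness <- function(pred, specs = default_attribute_specs(),
                               delta = 0.001) {
  stopifnot(is.data.frame(pred), nrow(pred) > 0)
  specs <- Filter(function(s) s$source %in% names(pred), specs)
  if (!length(specs)) stop("no attribute in the prediction table matches a spec")
  if (!"mitigation" %in% names(pred)) pred$mitigation <- "none"
  if (!"modality" %in% names(pred)) pred$modality <- "classifier"

  slices <- split(
    pred, list(pred$modality, pred$mitigation, pred[["repeat"]]), drop = TRUE)
  res <- lapply(slices, function(sl) {
    per_attr <- lapply(specs, function(spec) {
      g <- attribute_groups(spec, sl)
      keep <- !is.na(g)
      # one subject can appear once per repeat; group sizes are subject counts
      cnt <- table(g[keep][!duplicated(sl$subject_id[keep])])
      small <- names(cnt)[cnt < spec$min_group_size]
      keep <- keep & !(g %in% small)
      if (!any(keep)) {
        return(tibble::tibble(
          attribute = spec$name,
          metric = c("dpr_overall", "dpr_privileged", "eor_overall",
                     "eor_privileged", "macro_f1", "accuracy"),
          value = NA_real_, note = "all groups excluded"))
      }
      d <- sl[keep, ]
      d$.group <- g[keep]
      rates <- suppressWarnings(group_rates(d, ".group"))
      ratios <- suppressWarnings(fairness_ratios(rates, spec$privileged, delta))
      perf <- tibble::tibble(
        metric = c("macro_f1", "accuracy"),
        value = c(macro_f1(tp = sum(d$y_true == 1 & d$y_pred == 1),
                           fp = sum(d$y_true == 0 & d$y_pred == 1),
                           tn = sum(d$y_true == 0 & d$y_pred == 0),
                           fn = sum(d$y_true == 1 & d$y_pred == 0)),
                  mean(d$y_true == d$y_pred)),
        symmetric = NA_real_)
      all <- dplyr::bind_rows(ratios, perf)
      tibble::tibble(
        attribute = spec$name, metric = all$metric, value = all$value,
        note = ifelse(is.na(all$value), "undefined (zero denominator or <2 groups)",
                      NA_character_))
    })
    out <- dplyr::bind_rows(per_attr)
    out$modality <- sl$modality[1]
    out$mitigation <- sl$mitigation[1]
    out[["repeat"]] <- sl[["repeat"]][1]
    out
  })
  metrics <- dplyr::bind_rows(res)[, c("attribute", "modality", "mitigation",
                                       "repeat", "metric", "value", "note")]

  summary <- metrics |>
    dplyr::group_by(.data$attribute, .data$modality, .data$mitigation,
                    .data$metric) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_undefined = sum(is.na(.data$value)),
      median = stats::median(.data$value, na.rm = TRUE),
      q1 = stats::quantile(.data$value, 0.25, na.rm = TRUE, names = FALSE),
      q3 = stats::quantile(.data$value, 0.75, na.rm = TRUE, names = FALSE),
      .groups = "drop") |>
    dplyr::mutate(iqr = .data$q3 - .data$q1)
  n_out <- metrics |>
    dplyr::group_by(.data$attribute, .data$modality, .data$mitigation,
                    .data$metric) |>
    dplyr::summarise(n_outliers = {
      v <- .data$value[!is.na(.data$value)]
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      sum(v < q[1] - 1.5 * (q[2] - q[1]) | v > q[2] + 1.5 * (q[2] - q[1]))
    }, .groups = "drop")
  summary <- dplyr::left_join(summary, n_out,
                              by = c("attribute", "modality", "mitigation",
                                     "metric"))
  structure(list(metrics = metrics, summary = summary, delta = delta),
            class = "fairness_report")
}

#' @export
print.fairness_report <- function(x, ...) {
  cat("<fairness_report> delta =", x$delta, "\n")
  print(x$summary, n = 30)
  invisible(x)
}

#' Two-sided Mann-Whitney comparison of two metric distributions
#'
#' Wraps the rank-sum test used throughout the protocol to compare fairness
#' or performance distributions between conditions (e.g. pre- vs
#' post-mitigation, or across modalities): exact when both samples are
#' small without ties, normal approximation with tie correction otherwise.
#' When every value in both samples is identical the test is vacuous and
#' `p = 1` is returned with a warning.
#'
#' @param a,b Numeric samples (`NA`s dropped).
#' @param alpha Significance level for the decision flag (default 0.05).
#' @return List with `statistic` (the Mann-Whitney U of the first sample),
#'   `p_value`, `significant`, `method`.
#' @export
compare_distributions <- function(a, b, alpha = 0.05) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  if (length(unique(c(a, b))) == 1) {
    warning("all values tied across both samples; comparison is vacuous")
    return(list(statistic = length(a) * length(b) / 2, p_value = 1,
                significant = FALSE, method = "Mann-Whitney (all ties)"))
  }
  ht <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       significant = ht$p.value < alpha, method = ht$method)
}
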