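#' Configuration for a synthetic interview cohort
#'
#' Describes a cohort of subjects with demographic attributes, a binary
#' clinical label with group-specific base rates, self-rated scale scores
#' (PHQ-9, GAD-7) conditional on the label, and per-modality numeric
#' feature blocks whose class separability can differ by group. Generated
#' cohorts stand in for protected clinical interview data so that the audit,
#' metric and mitigation stages can be exercised end to end.
#'
#' @param attributes Named list; each element is a named integer vector of
#'   per-group subject counts for one demographic attribute. All attributes
#'   must sum to the same total cohort size. Counts are exact, not sampled.
#' @param base_rate Named numeric vector of positive-label probabilities for
#'   each group of `label_attribute`.
#' @param label_attribute Attribute whose groups carry the base rates
#'   (default: the first attribute). Other attributes are generated
#'   independently of the label.
#' @param scale_params Label-conditional (mean, sd) for each scale, as a list
#'   `list(phq9 = list(pos = c(mean, sd), neg = c(mean, sd)), gad7 = ...)`.
#'   Scores are drawn from the Gaussian, rounded, and clipped to the
#'   instrument range (PHQ-9 0-27, GAD-7 0-21).
#' @param modalities List of modality descriptions, each
#'   `list(name =, dim =, separation =, noise_sd =)`. `separation` is either
#'   a scalar or a named vector over the groups of `sep_attribute`; it is the
#'   Euclidean distance between the two class means of the spherical
#'   Gaussian feature generator, so the within-group Bayes accuracy is
#'   `pnorm(separation / (2 * noise_sd))` under balanced classes.
#' @param sep_attribute Attribute whose groups modulate separability
#'   (default `label_attribute`).
#' @param covariates List with elements `age` and `education`, each
#'   `c(mean, sd)`; drawn as rounded clipped Gaussians (age 18-65,
#'   education 8-24 years).
#' @param joint Optional dependence between two demographic attributes:
#'   `list(attrs = c("a", "b"), counts = <matrix>)` where `counts` has the
#'   groups of `a` as rows and of `b` as columns and sums to the cohort
#'   size. The two attributes are then assigned jointly from this table
#'   instead of independently.
#' @param seed Integer seed; every draw in [generate_cohort()] derives from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(attributes,
                          base_rate,
                          label_attribute = names(attributes)[1],
                          scale_params = default_scale_params(),
                          modalities = list(),
                          sep_attribute = label_attribute,
                          covariates = list(age = c(40, 12), education = c(17, 2.5)),
                          joint = NULL,
                          seed = 1L) {
  stopifnot(is.list(attributes), length(attributes) >= 1,
            !is.null(names(attributes)))
  sizes <- vapply(attributes, sum, numeric(1))
  if (length(unique(sizes)) != 1) {
    stop("all attributes must partition the same cohort: counts sum to ",
         paste(sizes, collapse = ", "), call. = FALSE)
  }
  for (a in names(attributes)) {
    cnt <- attributes[[a]]
    if (is.null(names(cnt)) || anyDuplicated(names(cnt)) || any(cnt < 0)) {
      stop("attribute '", a, "': groups must be uniquely named with counts >= 0",
           call. = FALSE)
    }
  }
  stopifnot(label_attribute %in% names(attributes),
            sep_attribute %in% names(attributes))
  groups_lab <- names(attributes[[label_attribute]])
  if (!all(groups_lab %in% names(base_rate))) {
    stop("base_rate must name every group of '", label_attribute, "'",
         call. = FALSE)
  }
  stopifnot(all(base_rate >= 0 & base_rate <= 1))
  for (m in modalities) {
    stopifnot(is.character(m$name), m$dim >= 1, all(m$separation >= 0),
              m$noise_sd > 0)
  }
  if (!is.null(joint)) {
    stopifnot(length(joint$attrs) == 2, all(joint$attrs %in% names(attributes)),
              sum(joint$counts) == sizes[[1]])
  }
  structure(
    list(
      n = unname(sizes[[1]]),
      attributes = attributes,
      base_rate = base_rate,
      label_attribute = label_attribute,
      scale_params = scale_params,
      modalities = modalities,
      sep_attribute = sep_attribute,
      covariates = covariates,
      joint = joint,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> n =", x$n, "\n")
  cat("  attributes:", paste(names(x$attributes), collapse = ", "), "\n")
  cat("  label attribute:", x$label_attribute,
      " base rates:", paste(sprintf("%s=%.2f", names(x$base_rate), x$base_rate),
                            collapse = ", "), "\n")
  cat("  modalities:", if (length(x$modalities))
    paste(vapply(x$modalities, `[[`, "", "name"), collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Label-conditional scale score defaults
#'
#' Means/sds chosen so that the positive class mostly exceeds the clinical
#' cutoff of 10 while the negative class mostly does not, with realistic
#' overlap at the boundary.
#' @return List of per-scale label-conditional `(mean, sd)` parameters.
#' @export
default_scale_params <- function() {
  list(
    phq9 = list(pos = c(15, 4.5), neg = c(5, 3.5), range = c(0, 27)),
    gad7 = list(pos = c(13, 4), neg = c(5, 3), range = c(0, 21))
  )
}

#' Demo cohort configuration
#'
#' A 73-subject cohort approximating the demographic frame of a small remote
#' mental-health interview study: gender (including a small non-binary
#' group), race (including groups below the n = 5 analysis threshold), age
#' and education covariates, a clinical label with an overall positive rate
#' near 51/73, and three feature modalities. Per-group counts are a
#' plausible rendering of that frame, not a claim of per-group fidelity to
#' any particular dataset.
#'
#' @param seed Integer seed.
#' @param separation Named per-gender class separation of the feature
#'   generator (scalar for equal separability).
#' @return A [cohort_config()].
#' @export
demo_cohort_config <- function(seed = 1L, separation = 1.5) {
  cohort_config(
    attributes = list(
      gender = c(female = 38, male = 33, nonbinary = 2),
      race = c(white = 35, black = 21, asian = 11, other = 4, hispanic = 2)
    ),
    base_rate = c(female = 0.70, male = 0.70, nonbinary = 0.70),
    label_attribute = "gender",
    modalities = list(
      list(name = "face", dim = 8, separation = separation, noise_sd = 1),
      list(name = "voice", dim = 6, separation = separation, noise_sd = 1),
      list(name = "language", dim = 10, separation = separation, noise_sd = 1)
    ),
    seed = seed
  )
}

#' Two-group cohort with a configurable separability gap
#'
#' The study condition used to demonstrate disparity detection and
#' mitigation: two equally sized groups with equal base rates but different
#' feature-space class separation, so a trained classifier exhibits unequal
#' TPR/FPR across groups.
#'
#' @param n Total cohort size (split equally between the groups).
#' @param separation Named length-2 vector of class separations.
#' @param base_rate Positive-label probability shared by the groups.
#' @param dim Feature dimension of the single modality.
#' @param seed Integer seed.
#' @return A [cohort_config()].
#' @export
disparity_cohort_config <- function(n = 400,
                                    separation = c(a = 2.5, b = 0.5),
                                    base_rate = 0.5,
                                    dim = 6,
                                    seed = 1L) {
  stopifnot(n %% 2 == 0, length(separation) == 2, !is.null(names(separation)))
  g <- names(separation)
  cohort_config(
    attributes = stats::setNames(
      list(stats::setNames(c(n / 2, n / 2), g)), "group"),
    base_rate = stats::setNames(c(base_rate, base_rate), g),
    label_attribute = "group",
    modalities = list(
      list(name = "signal", dim = dim, separation = separation, noise_sd = 1)
    ),
    seed = seed
  )
}

#' Generate a synthetic cohort
#'
#' Draws a subject table and per-modality feature blocks from a
#' [cohort_config()]. Group counts are exact; labels are Bernoulli draws at
#' the configured per-group base rates; features come from label- and
#' group-conditional spherical Gaussians whose class means are `separation`
#' apart. Fully reproducible for a fixed config (the seed lives in the
#' config).
#'
#' @param config A [cohort_config()].
#' @return A list of class `cohort` with elements `subjects` (tibble:
#'   `subject_id`, one column per attribute, `age_years`,
#'   `education_years`, `phq9`, `gad7`, `clinical_label`) and `features`
#'   (named list of numeric matrices with subject ids as rownames).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n
  ids <- sprintf("S%04d", seq_len(n))

  cols <- list()
  joint_attrs <- if (!is.null(config$joint)) config$joint$attrs else character()
  if (length(joint_attrs)) {
    jc <- config$joint$counts
    # expand (row group, col group) pairs per joint counts, then shuffle
    row_g <- rep(rep(rownames(jc), each = ncol(jc)), as.vector(t(jc)))
    col_g <- rep(rep(colnames(jc), times = nrow(jc)), as.vector(t(jc)))
    ord <- sample.int(n)
    cols[[joint_attrs[1]]] <- row_g[ord]
    cols[[joint_attrs[2]]] <- col_g[ord]
  }
  for (a in setdiff(names(config$attributes), joint_attrs)) {
    cnt <- config$attributes[[a]]
    cols[[a]] <- sample(rep(names(cnt), cnt))
  }

  lab_group <- cols[[config$label_attribute]]
  label <- stats::rbinom(n, 1, config$base_rate[lab_group])

  draw_scale <- function(params) {
    mu <- ifelse(label == 1, params$pos[1], params$neg[1])
    sd <- ifelse(label == 1, params$pos[2], params$neg[2])
    pmin(pmax(round(stats::rnorm(n, mu, sd)), params$range[1]), params$range[2])
  }
  sp <- config$scale_params
  phq9 <- draw_scale(sp$phq9)
  gad7 <- draw_scale(sp$gad7)

  cov <- config$covariates
  age <- pmin(pmax(round(stats::rnorm(n, cov$age[1], cov$age[2])), 18), 65)
  edu <- pmin(pmax(round(stats::rnorm(n, cov$education[1], cov$education[2])), 8), 24)

  sep_group <- cols[[config$sep_attribute]]
  features <- list()
  for (m in config$modalities) {
    sep <- if (length(m$separation) == 1 && is.null(names(m$separation))) {
      stats::setNames(rep(m$separation, length(unique(sep_group))),
                      unique(sep_group))
    } else m$separation
    u <- rep(1 / sqrt(m$dim), m$dim)        # unit direction of the mean shift
    shift <- outer(ifelse(label == 1, 0.5, -0.5) * sep[sep_group], u)
    x <- shift + matrix(stats::rnorm(n * m$dim, sd = m$noise_sd), n, m$dim)
    rownames(x) <- ids
    colnames(x) <- paste0(m$name, "_f", seq_len(m$dim))
    features[[m$name]] <- x
  }

  subjects <- tibble::tibble(subject_id = ids)
  for (a in names(cols)) subjects[[a]] <- cols[[a]]
  subjects$age_years <- age
  subjects$education_years <- edu
  subjects$phq9 <- as.integer(phq9)
  subjects$gad7 <- as.integer(gad7)
  subjects$clinical_label <- as.integer(label)

  structure(list(subjects = subjects, features = features, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> n =", nrow(x$subjects),
      " positives =", sum(x$subjects$clinical_label),
      " modalities =", length(x$features), "\n")
  invisible(x)
}

#' Configuration for an exact-rate prediction fixture
#'
#' Per-group targets for a prediction table whose confusion counts are
#' constructed exactly (not sampled), so that fairness metrics computed from
#' the fixture equal the configured rates to machine precision. This is the
#' primary oracle for the metric formulas.
#'
#' @param groups A data frame with one row per group: `group`, `n_pos`,
#'   `n_neg`, `tpr`, `fpr`.
#' @param seed Integer seed used for score draws (and for label draws in
#'   sampled mode).
#' @param sampled If `TRUE`, predicted labels are Bernoulli draws at the
#'   target rates instead of exact counts (for stochastic tests).
#' @return An object of class `rate_fixture_config`.
#' @export
rate_fixture_config <- function(groups, seed = 1L, sampled = FALSE) {
  stopifnot(is.data.frame(groups),
            all(c("group", "n_pos", "n_neg", "tpr", "fpr") %in% names(groups)),
            all(groups$n_pos >= 0), all(groups$n_neg >= 0),
            all(groups$tpr >= 0 & groups$tpr <= 1),
            all(groups$fpr >= 0 & groups$fpr <= 1),
            !anyDuplicated(groups$group))
  structure(list(groups = tibble::as_tibble(groups), seed = as.integer(seed),
                 sampled = isTRUE(sampled)),
            class = "rate_fixture_config")
}

#' Build a prediction table with exact per-group confusion counts
#'
#' In exact mode (the default) a target TPR of 0.9 with 10 positives yields
#' exactly 9 true positives; a target that is not representable with the
#' given counts (e.g. TPR 0.85 with 10 positives) is an error naming the
#' nearest representable rate. Scores are drawn consistent with the
#' assigned predicted labels at the 0.5 decision threshold (predicted
#' positives score above 0.5, predicted negatives at or below).
#'
#' @param config A [rate_fixture_config()].
#' @param repeats Number of repeat indices to emit; each repeat is an
#'   independent copy of the construction (fresh scores, same exact counts
#'   in exact mode).
#' @return A tibble with columns `subject_id`, `repeat`, `fold`, `y_true`,
#'   `score`, `y_pred`, `group`.
#' @export
generate_prediction_fixture <- function(config, repeats = 1L) {
  stopifnot(inherits(config, "rate_fixture_config"), repeats >= 1)
  set.seed(config$seed)
  g <- config$groups
  if (!config$sampled) {
    for (i in seq_len(nrow(g))) {
      check_representable(g$tpr[i], g$n_pos[i], "TPR", g$group[i])
      check_representable(g$fpr[i], g$n_neg[i], "FPR", g$group[i])
    }
  }
  out <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    rows <- lapply(seq_len(nrow(g)), function(i) {
      n_pos <- g$n_pos[i]; n_neg <- g$n_neg[i]
      if (config$sampled) {
        pred_pos <- stats::rbinom(n_pos, 1, g$tpr[i])
        pred_neg <- stats::rbinom(n_neg, 1, g$fpr[i])
      } else {
        tp <- as.integer(round(g$tpr[i] * n_pos))
        fp <- as.integer(round(g$fpr[i] * n_neg))
        pred_pos <- c(rep(1L, tp), rep(0L, n_pos - tp))
        pred_neg <- c(rep(1L, fp), rep(0L, n_neg - fp))
      }
      y <- c(rep(1L, n_pos), rep(0L, n_neg))
      pred <- c(pred_pos, pred_neg)
      score <- ifelse(pred == 1,
                      0.5 + 0.5 * stats::runif(n_pos + n_neg),
                      0.5 * stats::runif(n_pos + n_neg))
      tibble::tibble(
        subject_id = sprintf("%s_%04d", g$group[i], seq_len(n_pos + n_neg)),
        y_true = y, score = score, y_pred = as.integer(pred),
        group = g$group[i]
      )
    })
    tab <- dplyr::bind_rows(rows)
    tab[["repeat"]] <- r
    tab$fold <- 1L
    out[[r]] <- tab
  }
  res <- dplyr::bind_rows(out)
  res[, c("subject_id", "repeat", "fold", "y_true", "score", "y_pred", "group")]
}

check_representable <- function(rate, n, what, group) {
  if (n == 0) return(invisible())
  k <- rate * n
  if (abs(k - round(k)) > 1e-9) {
    stop(sprintf(
      "%s %.4g is not representable with %d subjects in group '%s'; nearest representable rate is %.6g",
      what, rate, n, group, round(k) / n), call. = FALSE)
  }
  invisible()
}

#' Read or write a cohort configuration as YAML
#'
#' @param path File path.
#' @return `read_cohort_config()` returns a [cohort_config()];
#'   `write_cohort_config()` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$attributes <- lapply(raw$attributes, unlist)
  raw$base_rate <- unlist(raw$base_rate)
  raw$covariates <- lapply(raw$covariates, unlist)
  if (!is.null(raw$scale_params)) {
    raw$scale_params <- lapply(raw$scale_params, function(s) lapply(s, unlist))
  } else {
    raw$scale_params <- default_scale_params()
  }
  if (!is.null(raw$modalities)) {
    raw$modalities <- lapply(raw$modalities, function(m) {
      m$separation <- unlist(m$separation)
      m
    })
  }
  do.call(cohort_config, raw[setdiff(names(raw), "n")])
}

#' @rdname read_cohort_config
#' @param config A [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  x <- unclass(config)
  x$n <- NULL
  x$attributes <- lapply(x$attributes, as.list)
  x$base_rate <- as.list(x$base_rate)
  x$covariates <- lapply(x$covariates, as.list)
  x$scale_params <- lapply(x$scale_params, function(s) lapply(s, as.list))
  x$modalities <- lapply(x$modalities, function(m) {
    m$separation <- as.list(m$separation)
    m
  })
  yaml::write_yaml(x, path)
  invisible(path)
}
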