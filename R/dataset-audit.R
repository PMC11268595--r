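#' Sensitive-attribute specification
#'
#' Defines one demographic axis for fairness analysis: where its group
#' labels come from, which group is socially/economically privileged, how a
#' continuous source column is binarized, and the minimum group size below
#' which a group is excluded from that attribute's analyses.
#'
#' @param name Attribute name (used in reports and as the default source
#'   column).
#' @param privileged The privileged group label `g*`.
#' @param source Column of the subject table holding the raw values
#'   (default `name`).
#' @param binarize Optional function mapping the source column to group
#'   labels (used for continuous sources such as age or years of
#'   education); `NULL` means the source column already holds group labels.
#' @param min_group_size Groups with fewer subjects are excluded from this
#'   attribute's analyses (default 5).
#' @return An object of class `attribute_spec`.
#' @export
attribute_spec <- function(name, privileged, source = name,
                           binarize = NULL, min_group_size = 5L) {
  stopifnot(is.character(name), is.character(privileged),
            min_group_size >= 1, is.null(binarize) || is.function(binarize))
  structure(list(name = name, privileged = privileged, source = source,
                 binarize = binarize, min_group_size = as.integer(min_group_size)),
            class = "attribute_spec")
}

#' Group labels of an attribute for a subject table
#'
#' Applies the spec's binarization rule (if any) to the source column.
#' @param spec An [attribute_spec()].
#' @param data Subject (or prediction) table.
#' @return Character vector of group labels, `NA` where the source is
#'   missing.
#' @export
attribute_groups <- function(spec, data) {
  if (!spec$source %in% names(data)) {
    stop("attribute '", spec$name, "': source column '", spec$source,
         "' missing from data", call. = FALSE)
  }
  x <- data[[spec$source]]
  if (is.null(spec$binarize)) as.character(x) else as.character(spec$binarize(x))
}

#' Standard demographic attribute specs
#'
#' The conventional privileged-group definitions for clinical fairness
#' audits: male (gender), white (race), older — at least 40 years — (age),
#' and college-or-below — at most 16 years of education — (education).
#' Age and education are binarized from the continuous columns `age_years`
#' and `education_years`.
#'
#' @param min_group_size Minimum analyzable group size (default 5).
#' @return Named list of [attribute_spec()] objects.
#' @export
default_attribute_specs <- function(min_group_size = 5L) {
  list(
    gender = attribute_spec("gender", privileged = "male",
                            min_group_size = min_group_size),
    race = attribute_spec("race", privileged = "white",
                          min_group_size = min_group_size),
    age = attribute_spec(
      "age", privileged = "older", source = "age_years",
      binarize = function(x) ifelse(x >= 40, "older", "younger"),
      min_group_size = min_group_size),
    education = attribute_spec(
      "education", privileged = "college_or_below", source = "education_years",
      binarize = function(x) ifelse(x <= 16, "college_or_below", "above_college"),
      min_group_size = min_group_size)
  )
}

#' Label definition
#'
#' Either a direct binary column (the clinician-assigned label) or a
#' scale-cutoff rule: positive iff the score is strictly greater than the
#' cutoff.
#'
#' @param name Label name used in reports.
#' @param source Column of the subject table.
#' @param cutoff Integer cutoff for scale-based labels, or `NULL` for a
#'   direct binary column.
#' @param range Instrument range `c(lo, hi)` for validation of scale
#'   scores; required when `cutoff` is given.
#' @return An object of class `label_definition`.
#' @export
label_definition <- function(name, source, cutoff = NULL, range = NULL) {
  if (!is.null(cutoff)) {
    stopifnot(!is.null(range), length(range) == 2,
              cutoff >= range[1], cutoff <= range[2])
  }
  structure(list(name = name, source = source, cutoff = cutoff, range = range),
            class = "label_definition")
}

#' Standard label definitions
#'
#' Clinician-rated mental-health condition (direct binary column
#' `clinical_label`), self-rated depression (PHQ-9 > 10) and self-rated
#' anxiety (GAD-7 > 10).
#' @return Named list of [label_definition()] objects.
#' @export
default_label_definitions <- function() {
  list(
    clinical_mhc = label_definition("clinical_mhc", "clinical_label"),
    selfrated_depression = label_definition(
      "selfrated_depression", "phq9", cutoff = 10, range = c(0, 27)),
    selfrated_anxiety = label_definition(
      "selfrated_anxiety", "gad7", cutoff = 10, range = c(0, 21))
  )
}

#' Binarize a clinical scale at a cutoff
#'
#' Positive iff the score is strictly greater than the cutoff (a score of
#' 10 at cutoff 10 is negative, 11 is positive). Missing scores propagate
#' as missing; non-integer or out-of-range scores are an error naming the
#' offending row.
#'
#' @param scores Integer scale scores.
#' @param cutoff Integer cutoff.
#' @param range Instrument range `c(lo, hi)`.
#' @return Integer 0/1 vector with `NA` where `scores` is `NA`.
#' @export
binarize_scale <- function(scores, cutoff, range) {
  stopifnot(length(range) == 2, cutoff >= range[1], cutoff <= range[2])
  ok <- !is.na(scores)
  bad <- which(ok & (scores != round(scores) |
                       scores < range[1] | scores > range[2]))
  if (length(bad)) {
    stop("score out of range or non-integer at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value ", scores[bad[1]], ", range ", range[1], "-", range[2], ")",
         call. = FALSE)
  }
  out <- rep(NA_integer_, length(scores))
  out[ok] <- as.integer(scores[ok] > cutoff)
  out
}

label_values <- function(def, data) {
  if (!def$source %in% names(data)) {
    stop("label '", def$name, "': source column '", def$source, "' missing",
         call. = FALSE)
  }
  x <- data[[def$source]]
  if (is.null(def$cutoff)) {
    stopifnot(all(x %in% c(0, 1, NA)))
    as.integer(x)
  } else {
    binarize_scale(x, def$cutoff, def$range)
  }
}

#' Exclude under-sized groups for one attribute's analyses
#'
#' Rows whose group (for this attribute) has fewer than `min_group_size`
#' members, or whose group value is missing, are dropped for this
#' attribute's analyses only; analyses of other attributes keep those
#' subjects. The exclusion log records what was dropped and why.
#'
#' @param data Subject table.
#' @param spec An [attribute_spec()].
#' @return List with `data` (filtered table, plus a `.group` column of
#'   group labels) and `log` (tibble: `group`, `n`, `reason`).
#' @export
apply_exclusions <- function(data, spec) {
  g <- attribute_groups(spec, data)
  log <- tibble::tibble(group = character(), n = integer(), reason = character())
  keep <- !is.na(g)
  if (any(!keep)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      group = NA_character_, n = sum(!keep), reason = "missing attribute value"))
  }
  cnt <- table(g[keep])
  small <- names(cnt)[cnt < spec$min_group_size]
  if (length(small)) {
    log <- dplyr::bind_rows(log, tibble::tibble(
      group = small, n = as.integer(cnt[small]),
      reason = sprintf("group size below %d", spec$min_group_size)))
    keep <- keep & !(g %in% small)
  }
  out <- data[keep, , drop = FALSE]
  out$.group <- g[keep]
  list(data = tibble::as_tibble(out), log = log)
}

#' Audit the demographic composition of a cohort
#'
#' For every (attribute, label definition) pair: per-group subject counts,
#' positive counts and selection rates; a Pearson chi-square test (no
#' continuity correction) of independence between group and label; and, per
#' label, two-sided Mann-Whitney rank-sum comparisons of age and years of
#' education between the label classes. Small groups are excluded per
#' attribute via [apply_exclusions()]. Significance is flagged at the 0.05
#' level; no multiple-testing correction is applied, but the number of
#' tests performed is reported so users can apply their own.
#'
#' @param data Subject table (schema of [generate_cohort()]).
#' @param specs List of [attribute_spec()] (default
#'   [default_attribute_specs()], restricted to columns present).
#' @param labels List of [label_definition()] (default
#'   [default_label_definitions()], restricted to columns present).
#' @param alpha Significance level for the decision flags (default 0.05).
#' @return An object of class `audit_report`: a list with `composition`
#'   (per attribute x group x label counts and selection rates),
#'   `independence_tests` (chi-square results; `skipped` + `warning_note`
#'   when a marginal is zero or an expected cell is below 5),
#'   `covariate_tests` (Mann-Whitney results), `exclusions`, `n_tests`,
#'   `alpha`.
#' @export
audit_composition <- function(data,
                              specs = default_attribute_specs(),
                              labels = default_label_definitions(),
                              alpha = 0.05) {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  specs <- Filter(function(s) s$source %in% names(data), specs)
  labels <- Filter(function(l) l$source %in% names(data), labels)
  if (!length(specs)) stop("no usable attribute specs for this table")
  if (!length(labels)) stop("no usable label definitions for this table")

  comp <- list()
  tests <- list()
  excl <- list()
  for (spec in specs) {
    ex <- apply_exclusions(data, spec)
    if (nrow(ex$log)) {
      excl[[spec$name]] <- dplyr::mutate(ex$log, attribute = spec$name,
                                         .before = 1)
    }
    for (def in labels) {
      y <- label_values(def, ex$data)
      keep <- !is.na(y)
      g <- ex$data$.group[keep]
      y <- y[keep]
      tab <- tapply(y, g, function(v) c(n = length(v), pos = sum(v)))
      comp[[paste(spec$name, def$name)]] <- tibble::tibble(
        attribute = spec$name,
        label = def$name,
        group = names(tab),
        n = as.integer(unname(vapply(tab, `[[`, 0, "n"))),
        n_positive = as.integer(unname(vapply(tab, `[[`, 0, "pos"))),
        selection_rate = unname(vapply(tab, function(v) v[["pos"]] / v[["n"]], 0))
      )
      ct <- table(g, y)
      skipped <- nrow(ct) < 2 || ncol(ct) < 2 ||
        any(rowSums(ct) == 0) || any(colSums(ct) == 0)
      if (skipped) {
        tests[[paste(spec$name, def$name)]] <- tibble::tibble(
          attribute = spec$name, label = def$name,
          statistic = NA_real_, df = NA_real_, p_value = NA_real_,
          significant = NA, skipped = TRUE,
          warning_note = "degenerate contingency table (zero marginal)")
      } else {
        expected <- outer(rowSums(ct), colSums(ct)) / sum(ct)
        note <- if (any(expected < 5))
          "expected cell count below 5; chi-square approximation fragile"
        else NA_character_
        ht <- suppressWarnings(stats::chisq.test(ct, correct = FALSE))
        tests[[paste(spec$name, def$name)]] <- tibble::tibble(
          attribute = spec$name, label = def$name,
          statistic = unname(ht$statistic), df = unname(ht$parameter),
          p_value = ht$p.value, significant = ht$p.value < alpha,
          skipped = FALSE, warning_note = note)
      }
    }
  }

  cov_tests <- list()
  for (def in labels) {
    y <- label_values(def, data)
    for (covname in intersect(c("age_years", "education_years"), names(data))) {
      x <- data[[covname]]
      keep <- !is.na(y) & !is.na(x)
      a <- x[keep & y == 1]
      b <- x[keep & y == 0]
      mw <- compare_distributions(a, b)
      cov_tests[[paste(def$name, covname)]] <- tibble::tibble(
        label = def$name, covariate = covname,
        statistic = mw$statistic, p_value = mw$p_value,
        significant = mw$p_value < alpha)
    }
  }

  structure(list(
    composition = dplyr::bind_rows(comp),
    independence_tests = dplyr::bind_rows(tests),
    covariate_tests = dplyr::bind_rows(cov_tests),
    exclusions = if (length(excl)) dplyr::bind_rows(excl) else
      tibble::tibble(attribute = character(), group = character(),
                     n = integer(), reason = character()),
    n_tests = length(tests) + length(cov_tests),
    alpha = alpha
  ), class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  cat("<audit_report>\n")
  cat("  attributes:", paste(unique(x$composition$attribute), collapse = ", "), "\n")
  cat("  labels:    ", paste(unique(x$composition$label), collapse = ", "), "\n")
  cat("  tests run: ", x$n_tests, " (alpha = ", x$alpha, ")\n", sep = "")
  sig <- sum(x$independence_tests$significant, na.rm = TRUE) +
    sum(x$covariate_tests$significant, na.rm = TRUE)
  cat("  significant:", sig, "\n")
  if (nrow(x$exclusions)) {
    cat("  exclusions:\n")
    print(x$exclusions)
  }
  invisible(x)
}
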