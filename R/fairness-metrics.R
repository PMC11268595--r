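#' Per-group confusion counts and derived rates
#'
#' Computes, for every level of a sensitive attribute, the confusion counts
#' (TP, FP, TN, FN) of a binary classifier together with the derived
#' selection rate, true positive rate, false positive rate and
#' macro-averaged F1 score. These are the rate inputs to the demographic
#' parity and equalized odds ratios ([dpr_overall()], [eor_overall()] and
#' their privilege-referenced variants).
#'
#' A rate with an empty denominator (a group with no positives has no TPR, a
#' group with no negatives has no FPR) is reported as `NA` with an
#' explanatory `note`, never coerced to zero: silently substituting zero
#' would distort the downstream ratios.
#'
#' @param data A data frame with one row per classified subject.
#' @param group Name of the column holding the group membership for the
#'   sensitive attribute under analysis.
#' @param y_true,y_pred Names of the columns holding the true and predicted
#'   binary labels (0/1).
#' @return A tibble with one row per group: `group`, `n`, `tp`, `fp`, `tn`,
#'   `fn`, `selection_rate`, `tpr`, `fpr`, `macro_f1`, `note`.
#' @examples
#' d <- data.frame(g = c("a", "a", "a", "a"), y = c(1, 1, 0, 0), p = c(1, 0, 0, 1))
#' group_rates(d, group = "g", y_true = "y", y_pred = "p")
#' @export
group_rates <- function(data, group, y_true = "y_true", y_pred = "y_pred") {
  stopifnot(is.data.frame(data), nrow(data) > 0)
  for (col in c(group, y_true, y_pred)) {
    if (!col %in% names(data)) {
      stop("column '", col, "' not found in prediction data", call. = FALSE)
    }
  }
  g <- data[[group]]
  if (anyNA(g)) {
    stop("group column '", group, "' contains missing values; ",
         "drop or exclude those rows before computing rates", call. = FALSE)
  }
  y <- as.integer(data[[y_true]])
  p <- as.integer(data[[y_pred]])
  stopifnot(all(y %in% 0:1), all(p %in% 0:1))

  out <- lapply(split(seq_along(g), g), function(idx) {
    yi <- y[idx]
    pi <- p[idx]
    tp <- sum(yi == 1 & pi == 1)
    fp <- sum(yi == 0 & pi == 1)
    tn <- sum(yi == 0 & pi == 0)
    fn <- sum(yi == 1 & pi == 0)
    n <- length(idx)
    tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    fpr <- if (fp + tn > 0) fp / (fp + tn) else NA_real_
    note <- c(
      if (tp + fn == 0) "tpr undefined: no positives in group",
      if (fp + tn == 0) "fpr undefined: no negatives in group"
    )
    tibble::tibble(
      n = n, tp = tp, fp = fp, tn = tn, fn = fn,
      selection_rate = (tp + fp) / n,
      tpr = tpr, fpr = fpr,
      macro_f1 = macro_f1(tp = tp, fp = fp, tn = tn, fn = fn),
      note = if (length(note)) paste(note, collapse = "; ") else NA_character_
    )
  })
  res <- dplyr::bind_rows(out, .id = "group")
  tibble::as_tibble(res)
}

#' Macro-averaged F1 from confusion counts
#'
#' Unweighted mean of the positive-class and negative-class F1 scores of a
#' binary classifier. A class absent from both the truth and the
#' predictions contributes an F1 of 1 (a degenerate but perfect outcome); a
#' class absent from the truth but present in the predictions contributes 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return Macro-averaged F1 in `[0, 1]`.
#' @export
macro_f1 <- function(tp, fp, tn, fn) {
  f1_class <- function(tp_c, fp_c, fn_c) {
    denom <- 2 * tp_c + fp_c + fn_c
    if (denom == 0) return(1)          # class absent everywhere
    2 * tp_c / denom                   # = 0 when tp_c = 0 but fp_c/fn_c > 0
  }
  # positive class: as given; negative class: swap roles
  (f1_class(tp, fp, fn) + f1_class(tn, fn, fp)) / 2
}

#' Overall demographic parity ratio
#'
#' Ratio of the smallest to the largest per-group selection rate,
#' `min_g S_g / max_g S_g`, capturing parity between any pair of groups.
#' A value of 1 means all groups are selected (classified positive) at the
#' same rate; values further from 1 mean larger disparity.
#'
#' @param selection_rates Numeric vector of per-group selection rates
#'   (optionally named by group).
#' @return The ratio in `[0, 1]`, or `NA` (with a warning) when fewer than
#'   two groups have defined rates or the maximum rate is zero.
#' @export
dpr_overall <- function(selection_rates) {
  s <- drop_undefined(selection_rates, "selection rate")
  if (length(s) < 2) {
    warning("fewer than two groups with defined selection rates; DPR undefined")
    return(NA_real_)
  }
  if (max(s) == 0) {
    warning("all selection rates are zero; overall DPR undefined")
    return(NA_real_)
  }
  min(s) / max(s)
}

#' Privilege-referenced demographic parity ratio
#'
#' `min_{g != g*} S_g / S_{g*}`: the smallest unprivileged selection rate
#' relative to the privileged group's rate. Unlike the overall ratio this
#' can exceed 1, when every unprivileged group is selected more often than
#' the privileged one. No smoothing constant is applied (smoothing is used
#' only for the equalized odds ratios).
#'
#' @param selection_rates Named numeric vector of per-group selection rates.
#' @param privileged Name of the privileged group `g*`.
#' @return Nonnegative ratio, or `NA` with a warning when the privileged
#'   rate is zero or undefined.
#' @export
dpr_privileged <- function(selection_rates, privileged) {
  stopifnot(!is.null(names(selection_rates)))
  if (!privileged %in% names(selection_rates)) {
    stop("privileged group '", privileged, "' has no selection rate", call. = FALSE)
  }
  s_star <- selection_rates[[privileged]]
  others <- drop_undefined(
    selection_rates[setdiff(names(selection_rates), privileged)],
    "selection rate"
  )
  if (is.na(s_star) || length(others) < 1) {
    warning("privileged or all unprivileged selection rates undefined")
    return(NA_real_)
  }
  if (s_star == 0) {
    warning("privileged selection rate is zero; privilege-referenced DPR undefined")
    return(NA_real_)
  }
  min(others) / s_star
}

#' Overall equalized odds ratio
#'
#' `min( (min_g TPR_g + d) / (max_g TPR_g + d),
#'       (min_g FPR_g + d) / (max_g FPR_g + d) )` with smoothing constant
#' `d = delta` guarding against division by zero. A value of 1 means every
#' group has the same TPR and FPR.
#'
#' Groups with an undefined TPR or FPR are dropped from the computation with
#' a warning; if fewer than two groups remain the ratio is `NA`.
#'
#' @param tpr,fpr Numeric vectors of per-group true/false positive rates,
#'   aligned (and, if named, identically named).
#' @param delta Smoothing constant added to numerator and denominator
#'   (default 0.001).
#' @return Ratio in `(0, 1]` for `delta > 0`, or `NA` when undefined.
#' @export
eor_overall <- function(tpr, fpr, delta = 0.001) {
  stopifnot(length(tpr) == length(fpr), delta > 0)
  ok <- !is.na(tpr) & !is.na(fpr)
  if (any(!ok)) {
    warning(sum(!ok), " group(s) with undefined TPR or FPR dropped from EOR")
  }
  tpr <- tpr[ok]
  fpr <- fpr[ok]
  if (length(tpr) < 2) {
    warning("fewer than two groups with defined rates; overall EOR undefined")
    return(NA_real_)
  }
  min(
    (min(tpr) + delta) / (max(tpr) + delta),
    (min(fpr) + delta) / (max(fpr) + delta)
  )
}

#' Privilege-referenced equalized odds ratio
#'
#' `min( min_{g != g*} (TPR_g + d) / (TPR_{g*} + d),
#'       min_{g != g*} (FPR_{g*} + d) / (FPR_g + d) )`.
#'
#' The orientation is deliberate and asymmetric: the privileged TPR sits in
#' the denominator of the TPR term while the privileged FPR sits in the
#' numerator of the FPR term, so the ratio reads as "how much worse off, in
#' sensitivity or in false alarms, is the worst unprivileged group relative
#' to the privileged one". Either term — and hence the ratio — may exceed 1
#' when an unprivileged group outperforms the privileged group; values are
#' not clipped (see [symmetric_disparity()] for a folded summary).
#'
#' @param tpr,fpr Named numeric vectors of per-group rates.
#' @param privileged Name of the privileged group `g*`.
#' @inheritParams eor_overall
#' @return Nonnegative ratio, or `NA` when undefined.
#' @export
eor_privileged <- function(tpr, fpr, privileged, delta = 0.001) {
  stopifnot(length(tpr) == length(fpr), delta > 0,
            !is.null(names(tpr)), !is.null(names(fpr)),
            identical(names(tpr), names(fpr)))
  if (!privileged %in% names(tpr)) {
    stop("privileged group '", privileged, "' not present", call. = FALSE)
  }
  t_star <- tpr[[privileged]]
  f_star <- fpr[[privileged]]
  others <- setdiff(names(tpr), privileged)
  ok <- others[!is.na(tpr[others]) & !is.na(fpr[others])]
  if (length(ok) < length(others)) {
    warning(length(others) - length(ok),
            " unprivileged group(s) with undefined rates dropped from EOR")
  }
  if (is.na(t_star) || is.na(f_star) || length(ok) < 1) {
    warning("privileged rates or all unprivileged rates undefined; EOR undefined")
    return(NA_real_)
  }
  min(
    (min(tpr[ok]) + delta) / (t_star + delta),
    (f_star + delta) / (max(fpr[ok]) + delta)
  )
}

#' Symmetric disparity summary
#'
#' Folds a ratio that may exceed 1 onto `[0, 1]` via `min(x, 1/x)`, so that
#' "further from 1" always reads as "more disparate" regardless of which
#' side of the reference group a ratio falls. This is an extension beyond
#' the printed privilege-referenced formulas, offered as an optional report
#' column and clearly labelled as such.
#'
#' @param x Nonnegative ratio(s).
#' @return `min(x, 1/x)` elementwise; `NA` stays `NA`.
#' @export
symmetric_disparity <- function(x) {
  ifelse(is.na(x), NA_real_, pmin(x, ifelse(x > 0, 1 / x, Inf)))
}

#' All four fairness ratios from a group-rates table
#'
#' Convenience wrapper computing the overall and privilege-referenced
#' demographic parity ratios and equalized odds ratios from the output of
#' [group_rates()].
#'
#' @param rates A tibble as returned by [group_rates()].
#' @param privileged Name of the privileged group.
#' @param delta Smoothing constant for the equalized odds ratios.
#' @return A tibble with columns `metric` (`dpr_overall`, `dpr_privileged`,
#'   `eor_overall`, `eor_privileged`), `value`, and `symmetric` (the folded
#'   `min(x, 1/x)` summary).
#' @export
fairness_ratios <- function(rates, privileged, delta = 0.001) {
  stopifnot(is.data.frame(rates), "group" %in% names(rates))
  sr <- stats::setNames(rates$selection_rate, rates$group)
  tpr <- stats::setNames(rates$tpr, rates$group)
  fpr <- stats::setNames(rates$fpr, rates$group)
  vals <- c(
    dpr_overall = dpr_overall(sr),
    dpr_privileged = dpr_privileged(sr, privileged),
    eor_overall = eor_overall(tpr, fpr, delta),
    eor_privileged = eor_privileged(tpr, fpr, privileged, delta)
  )
  tibble::tibble(
    metric = names(vals),
    value = unname(vals),
    symmetric = symmetric_disparity(unname(vals))
  )
}

# drop NA entries from a rate vector with a warning naming the quantity
drop_undefined <- function(x, what) {
  if (anyNA(x)) {
    warning(sum(is.na(x)), " group(s) with undefined ", what, " dropped")
  }
  x[!is.na(x)]
}
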