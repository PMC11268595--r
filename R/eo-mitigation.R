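#' ROC operating points and their upper convex hull
#'
#' Enumerates one operating point per distinct decision threshold of a
#' score-based classifier (rule: predict positive iff `score > t`),
#' including the below-minimum sentinel threshold that classifies everyone
#' positive, and computes the upper convex hull of the point set by the
#' monotone-chain method. Every point on the hull — not just the raw
#' operating points — is achievable by randomizing between two thresholds,
#' which is the geometric basis of the derived equalized-odds predictor.
#'
#' @param scores Numeric scores (higher = more likely positive).
#' @param labels Binary 0/1 labels.
#' @return An object of class `roc_curve`: list with `points` (tibble
#'   `threshold`, `fpr`, `tpr`, ordered by decreasing threshold, i.e. from
#'   (0,0) to (1,1)), `hull` (the hull vertices in increasing `fpr`),
#'   `n_pos`, `n_neg`, and `degenerate` (`TRUE`, with empty tables, when
#'   only one class is present).
#' @export
build_roc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1),
            !anyNA(scores))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) {
    empty <- tibble::tibble(threshold = numeric(), fpr = numeric(),
                            tpr = numeric())
    return(structure(list(points = empty, hull = empty, n_pos = n_pos,
                          n_neg = n_neg, degenerate = TRUE),
                     class = "roc_curve"))
  }
  thr <- c(-Inf, sort(unique(scores)))
  pts <- vapply(thr, function(t) {
    pred <- scores > t
    c(fpr = sum(pred & labels == 0) / n_neg,
      tpr = sum(pred & labels == 1) / n_pos)
  }, c(fpr = 0, tpr = 0))
  points <- tibble::tibble(threshold = thr, fpr = pts["fpr", ],
                           tpr = pts["tpr", ])
  points <- points[order(-points$threshold), ]  # (0,0) first, (1,1) last

  hull_idx <- upper_hull(points$fpr, points$tpr)
  structure(list(points = points, hull = points[hull_idx, ],
                 n_pos = n_pos, n_neg = n_neg, degenerate = FALSE),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  if (x$degenerate) {
    cat("<roc_curve> degenerate (single-class input)\n")
  } else {
    cat("<roc_curve>", nrow(x$points), "operating points,",
        nrow(x$hull), "hull vertices\n")
  }
  invisible(x)
}

# Andrew monotone-chain upper hull. Points need not be sorted. Returns the
# indices of the upper-hull vertices in increasing (x, y) order, keeping the
# left vertical edge (e.g. (0,0) below (0,1)) so that every vertex is a
# realizable operating point usable for two-threshold mixing.
upper_hull <- function(x, y) {
  ord <- order(x, y)
  chain <- integer(0)
  cross <- function(o, a, b) {
    (x[a] - x[o]) * (y[b] - y[o]) - (y[a] - y[o]) * (x[b] - x[o])
  }
  for (i in ord) {
    while (length(chain) >= 2 &&
           cross(chain[length(chain) - 1], chain[length(chain)], i) >= 0) {
      chain <- chain[-length(chain)]
    }
    chain <- c(chain, i)
  }
  # retain the lowest point at the leftmost x (vertical edge start)
  left <- ord[1]
  if (chain[1] != left) chain <- c(left, chain)
  chain
}

# height of the hull's upper boundary at the given fpr values
hull_height <- function(hull, fpr) {
  hx <- hull$fpr
  hy <- hull$tpr
  keep <- !duplicated(hx, fromLast = TRUE)  # max tpr per fpr (sorted asc)
  stats::approx(hx[keep], hy[keep], xout = fpr, rule = 2)$y
}

#' Fit an equalized-odds threshold policy
#'
#' Learns per-group randomized classification thresholds that maximize
#' overall accuracy subject to (approximately exact) equalized odds: all
#' groups operate at one common `(fpr*, tpr*)` point. The feasible set is
#' the intersection of the groups' ROC convex hulls; it is scanned along an
#' FPR grid, taking at each grid value the largest jointly achievable TPR
#' (the minimum of the per-group hull heights) and scoring it by
#' `acc = pi * tpr + (1 - pi) * (1 - fpr)` with `pi` the pooled prevalence.
#' Ties are broken toward smaller FPR.
#'
#' Each group's policy realizes the target as a randomized rule with three
#' components: two thresholds `t_lo`, `t_hi` mixed with weight `p` (which
#' reaches the group's hull boundary at `fpr*`), plus an ignore probability
#' `p_ignore` under which the score is discarded and the subject is
#' classified positive with probability `fpr*` (which pulls the operating
#' point down from the hull boundary to the common target when this group's
#' hull lies above it). For the group whose hull binds the target,
#' `p_ignore = 0` and the rule is a plain two-threshold mixture.
#'
#' A degenerate group (only one class in the fitting data) falls back to
#' the single pooled-data accuracy-optimal threshold and is logged, rather
#' than failing the fold — small groups are routine at cohort sizes near
#' 73 split over 5 folds.
#'
#' @param scores Numeric scores on the fitting data.
#' @param labels Binary 0/1 labels.
#' @param groups Group membership (character) per row.
#' @param grid_resolution FPR grid step in (0, 0.1]; default 0.001. The
#'   achieved operating points match the target to within this resolution
#'   (exactly, up to floating point, at grid values).
#' @param seed Default seed stored in the policy for [apply_policy()].
#' @return An object of class `eo_policy`: `target` (`c(fpr, tpr)`),
#'   `prevalence`, `accuracy` (expected accuracy at the target),
#'   `grid_resolution`, `seed`, and `groups` — a tibble with per-group
#'   `t_lo`, `t_hi`, `p`, `p_ignore`, `achieved_fpr`, `achieved_tpr`,
#'   `fallback`.
#' @export
fit_eo_policy <- function(scores, labels, groups, grid_resolution = 0.001,
                          seed = 1L) {
  stopifnot(length(scores) == length(labels),
            length(scores) == length(groups),
            grid_resolution > 0, grid_resolution <= 0.1)
  groups <- as.character(groups)
  labels <- as.integer(labels)
  glev <- unique(groups)
  rocs <- lapply(stats::setNames(glev, glev), function(g) {
    build_roc(scores[groups == g], labels[groups == g])
  })
  degen <- vapply(rocs, `[[`, TRUE, "degenerate")
  if (sum(!degen) < 2) {
    stop("need at least two groups with both classes present to fit an ",
         "equalized-odds policy", call. = FALSE)
  }
  pi_hat <- mean(labels)

  fpr_grid <- seq(0, 1, by = grid_resolution)
  heights <- vapply(rocs[!degen], function(r) hull_height(r$hull, fpr_grid),
                    numeric(length(fpr_grid)))
  tpr_grid <- do.call(pmin, as.data.frame(heights))
  # the diagonal is always inside every hull, so the intersection is nonempty
  stopifnot(all(tpr_grid >= fpr_grid - 1e-9))
  acc <- pi_hat * tpr_grid + (1 - pi_hat) * (1 - fpr_grid)
  best <- which.max(acc)          # first maximum = smallest fpr on ties
  target <- c(fpr = fpr_grid[best], tpr = tpr_grid[best])

  rows <- lapply(glev, function(g) {
    if (degen[[g]]) {
      t_fb <- pooled_optimal_threshold(scores, labels)
      return(tibble::tibble(
        group = g, t_lo = t_fb, t_hi = t_fb, p = 1, p_ignore = 0,
        achieved_fpr = NA_real_, achieved_tpr = NA_real_, fallback = TRUE))
    }
    pol <- realize_target(rocs[[g]], target)
    tibble::tibble(group = g, t_lo = pol$t_lo, t_hi = pol$t_hi, p = pol$p,
                   p_ignore = pol$p_ignore, achieved_fpr = pol$fpr,
                   achieved_tpr = pol$tpr, fallback = FALSE)
  })

  structure(list(
    target = target,
    prevalence = pi_hat,
    accuracy = pi_hat * target[["tpr"]] + (1 - pi_hat) * (1 - target[["fpr"]]),
    grid_resolution = grid_resolution,
    seed = as.integer(seed),
    groups = dplyr::bind_rows(rows)
  ), class = "eo_policy")
}

#' @export
print.eo_policy <- function(x, ...) {
  cat(sprintf("<eo_policy> target (fpr, tpr) = (%.4f, %.4f), accuracy = %.4f\n",
              x$target[["fpr"]], x$target[["tpr"]], x$accuracy))
  print(x$groups)
  invisible(x)
}

# mixture of the two hull vertices bracketing the target fpr, then an
# ignore component down from the hull boundary to the target tpr
realize_target <- function(roc, target) {
  fpr_t <- target[["fpr"]]
  tpr_t <- target[["tpr"]]
  hull <- roc$hull
  bx <- hull$fpr
  by <- hull$tpr
  bt <- hull$threshold
  if (fpr_t <= bx[1] + 1e-12 && length(bx) >= 2 && bx[2] <= bx[1] + 1e-12) {
    # vertical left edge: mix (0, by[1]) with (0, by[2]) directly
    lo <- 1; hi <- 2
    h <- by[2]
    p <- if (h > 0) 1 - min(tpr_t, h) / h else 1
    mix_tpr <- p * by[1] + (1 - p) * by[2]
    q <- 0
    if (mix_tpr > tpr_t + 1e-12) q <- (mix_tpr - tpr_t) / (mix_tpr - fpr_t)
  } else {
    keep <- which(!duplicated(bx, fromLast = TRUE))
    i <- max(keep[bx[keep] <= fpr_t + 1e-12])
    j <- min(keep[bx[keep] >= fpr_t - 1e-12])
    if (i == j) {
      lo <- i; hi <- i; p <- 1
      h <- by[i]
    } else {
      lo <- i; hi <- j
      p <- (bx[j] - fpr_t) / (bx[j] - bx[i])
      h <- p * by[i] + (1 - p) * by[j]
    }
    q <- if (h > tpr_t + 1e-12) (h - tpr_t) / (h - fpr_t) else 0
  }
  exp_fpr <- (1 - q) * (p * bx[lo] + (1 - p) * bx[hi]) + q * fpr_t
  exp_tpr <- (1 - q) * (p * by[lo] + (1 - p) * by[hi]) + q * fpr_t
  list(t_lo = bt[lo], t_hi = bt[hi], p = p, p_ignore = q,
       fpr = exp_fpr, tpr = exp_tpr)
}

# single threshold maximizing plain accuracy on the pooled data
pooled_optimal_threshold <- function(scores, labels) {
  thr <- c(-Inf, sort(unique(scores)))
  acc <- vapply(thr, function(t) mean((scores > t) == (labels == 1)), 0)
  thr[max(which(acc == max(acc)))]   # ties: larger threshold (fewer positives)
}

#' Apply an equalized-odds policy to new scores
#'
#' Classifies each row by the fitted randomized rule of its group: with
#' probability `p_ignore` the score is ignored and the row is positive with
#' probability `fpr*`; otherwise threshold `t_lo` is used with probability
#' `p`, else `t_hi` (predict positive iff `score > t`). Randomness for each
#' row is drawn from a dedicated stream derived from `(seed, id)`, so the
#' predictions are reproducible row-wise regardless of table order.
#'
#' @param policy An [fit_eo_policy()] result.
#' @param scores Numeric scores.
#' @param groups Group membership per row.
#' @param seed Integer seed (default: the seed stored in the policy).
#' @param ids Per-row identifiers keying the randomization stream
#'   (default: row position as character, which ties reproducibility to row
#'   order; pass subject ids for order-invariant predictions).
#' @param fallback If `TRUE` (default), rows from groups absent from the
#'   policy are classified by the policy's first fallback/overall rule at
#'   threshold 0.5; if `FALSE`, an unseen group is an error naming it.
#' @return Integer 0/1 predictions.
#' @export
apply_policy <- function(policy, scores, groups, seed = policy$seed,
                         ids = NULL, fallback = TRUE) {
  stopifnot(inherits(policy, "eo_policy"), length(scores) == length(groups))
  groups <- as.character(groups)
  if (is.null(ids)) ids <- as.character(seq_along(scores))
  stopifnot(length(ids) == length(scores))
  unseen <- setdiff(unique(groups), policy$groups$group)
  if (length(unseen) && !fallback) {
    stop("group(s) not covered by policy: ", paste(unseen, collapse = ", "),
         call. = FALSE)
  }
  ptab <- policy$groups
  fpr_t <- policy$target[["fpr"]]
  out <- integer(length(scores))
  for (k in seq_along(scores)) {
    g <- groups[k]
    row <- match(g, ptab$group)
    u <- row_uniforms(seed, ids[k])
    if (is.na(row)) {              # unseen group: plain 0.5 threshold
      out[k] <- as.integer(scores[k] > 0.5)
      next
    }
    if (u[1] < ptab$p_ignore[row]) {
      out[k] <- as.integer(u[2] < fpr_t)
    } else {
      t <- if (u[3] < ptab$p[row]) ptab$t_lo[row] else ptab$t_hi[row]
      out[k] <- as.integer(scores[k] > t)
    }
  }
  out
}

# three uniforms from a stream keyed by (seed, id); deterministic and
# independent of the global RNG state. The key is hashed with a polynomial
# rolling hash kept below 2^31 so arithmetic stays exact in doubles.
row_uniforms <- function(seed, id) {
  h <- 0
  for (code in utf8ToInt(paste0(seed, ":", id))) {
    h <- (h * 31 + code) %% 2147483647
  }
  row_seed <- h
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(row_seed))
  stats::runif(3)
}

#' Expected operating rates of a policy on labelled data
#'
#' Analytic expectation (over the policy's randomization) of the per-group
#' FPR and TPR on the given data — the quantity the equalized-odds
#' constraint controls, free of Monte-Carlo noise.
#'
#' @inheritParams apply_policy
#' @param labels Binary 0/1 labels.
#' @return Tibble with per-group `expected_fpr`, `expected_tpr`.
#' @export
policy_expected_rates <- function(policy, scores, labels, groups) {
  groups <- as.character(groups)
  fpr_t <- policy$target[["fpr"]]
  rows <- lapply(seq_len(nrow(policy$groups)), function(i) {
    r <- policy$groups[i, ]
    idx <- groups == r$group
    if (!any(idx)) return(NULL)
    s <- scores[idx]
    y <- labels[idx]
    p_pos <- (1 - r$p_ignore) *
      (r$p * (s > r$t_lo) + (1 - r$p) * (s > r$t_hi)) + r$p_ignore * fpr_t
    tibble::tibble(
      group = r$group,
      expected_fpr = if (any(y == 0)) mean(p_pos[y == 0]) else NA_real_,
      expected_tpr = if (any(y == 1)) mean(p_pos[y == 1]) else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}

#' Serialize / restore an equalized-odds policy as JSON
#'
#' @param policy An `eo_policy`.
#' @param path File path.
#' @return `write_policy()` returns `path` invisibly; `read_policy()` the
#'   restored `eo_policy`.
#' @export
write_policy <- function(policy, path) {
  stopifnot(inherits(policy, "eo_policy"))
  x <- unclass(policy)
  x$target <- as.list(x$target)
  # sentinel thresholds are +-Inf, which JSON cannot carry as numbers;
  # 17 significant digits keep finite thresholds exact through the round-trip
  x$groups$t_lo <- sprintf("%.17g", x$groups$t_lo)
  x$groups$t_hi <- sprintf("%.17g", x$groups$t_hi)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_policy
#' @export
read_policy <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$target <- c(fpr = x$target$fpr, tpr = x$target$tpr)
  x$groups <- tibble::as_tibble(x$groups)
  x$groups$t_lo <- as.numeric(x$groups$t_lo)
  x$groups$t_hi <- as.numeric(x$groups$t_hi)
  x$seed <- as.integer(x$seed)
  structure(x, class = "eo_policy")
}
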