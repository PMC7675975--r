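#' Match manual and automatic detections by centroid distance
#'
#' One-to-one greedy globally-minimal-distance matching: the closest
#' unmatched (manual, automatic) pair with centroid distance
#' `d = sqrt(dCx^2 + dCy^2) <= max_dist_px` is paired repeatedly until
#' no admissible pair remains. Unmatched manual objects are false
#' negatives, unmatched automatic objects false positives.
#'
#' @param manual,auto Two-column matrices or data frames of `(x, y)`
#'   centroids in the same pixel frame.
#' @param max_dist_px Maximal admissible centroid distance (pixels).
#' @return An object of class `detection_match`: list with `pairs`
#'   (tibble `manual_id`, `auto_id`, `distance_px`), `tp`, `fp`, `fn`.
#' @export
match_objects <- function(manual, auto, max_dist_px) {
  if (!is.numeric(max_dist_px) || max_dist_px < 0) {
    stop("`max_dist_px` must be non-negative", call. = FALSE)
  }
  m <- as.matrix(as.data.frame(manual))[, 1:2, drop = FALSE]
  a <- as.matrix(as.data.frame(auto))[, 1:2, drop = FALSE]
  nm <- nrow(m); na <- nrow(a)
  pairs <- tibble::tibble(manual_id = integer(), auto_id = integer(),
                          distance_px = double())
  if (nm > 0 && na > 0) {
    d <- sqrt(outer(m[, 1], a[, 1], `-`)^2 + outer(m[, 2], a[, 2], `-`)^2)
    ord <- order(d)
    ord <- ord[d[ord] <= max_dist_px]
    used_m <- logical(nm); used_a <- logical(na)
    mi <- (ord - 1) %% nm + 1
    ai <- (ord - 1) %/% nm + 1
    keep_m <- integer(); keep_a <- integer(); keep_d <- double()
    for (k in seq_along(ord)) {
      if (!used_m[mi[k]] && !used_a[ai[k]]) {
        used_m[mi[k]] <- TRUE; used_a[ai[k]] <- TRUE
        keep_m <- c(keep_m, mi[k]); keep_a <- c(keep_a, ai[k])
        keep_d <- c(keep_d, d[mi[k], ai[k]])
      }
    }
    pairs <- tibble::tibble(manual_id = keep_m, auto_id = keep_a, distance_px = keep_d)
  }
  structure(list(pairs = pairs, tp = nrow(pairs),
                 fp = na - nrow(pairs), fn = nm - nrow(pairs)),
            class = "detection_match")
}

#' @export
print.detection_match <- function(x, ...) {
  cat(sprintf("<detection_match> TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' @export
tidy.detection_match <- function(x, ...) x$pairs

#' Detection performance metrics
#'
#' Sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`, false negative
#' rate `FN/(FN+TP)` and F1 score `2TP/(2TP+FP+FN)` of a detection
#' match. Metrics with an empty denominator are `NA` (undefined).
#'
#' @param match A [match_objects()] result, or a list/vector with
#'   elements `tp`, `fp`, `fn`.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision`, `fnr`, `f1`.
#' @export
performance <- function(match) {
  tp <- match$tp; fp <- match$fp; fn <- match$fn
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    sensitivity = div(tp, tp + fn),
    precision = div(tp, tp + fp),
    fnr = div(fn, fn + tp),
    f1 = div(2 * tp, 2 * tp + fp + fn)
  )
}

#' Bland-Altman agreement of paired measurements
#'
#' Per-pair relative difference `100 (auto - manual) / manual` (in
#' percent) with its mean and t-based 95% confidence interval; pairs
#' with a zero manual value are excluded with a warning.
#'
#' @param manual_vals,auto_vals Paired numeric vectors of equal length
#'   (at least 3 usable pairs).
#' @return A one-row tibble: `mean_relative_difference_pct`,
#'   `ci95_low_pct`, `ci95_high_pct`, `n`.
#' @export
bland_altman <- function(manual_vals, auto_vals) {
  stopifnot(length(manual_vals) == length(auto_vals))
  zero <- manual_vals == 0
  if (any(zero)) {
    warning(sum(zero), " pair(s) with zero manual value excluded")
    manual_vals <- manual_vals[!zero]; auto_vals <- auto_vals[!zero]
  }
  n <- length(manual_vals)
  if (n < 3) stop("need at least 3 usable pairs", call. = FALSE)
  rel <- 100 * (auto_vals - manual_vals) / manual_vals
  m <- mean(rel)
  se <- stats::sd(rel) / sqrt(n)
  half <- stats::qt(0.975, df = n - 1) * se
  tibble::tibble(
    mean_relative_difference_pct = m,
    ci95_low_pct = m - half,
    ci95_high_pct = m + half,
    n = n
  )
}

#' Pearson correlation and two-way mixed absolute-agreement ICC
#'
#' Thin conveniences over the standard formulas for comparing manual
#' and automated counts; reported alongside the performance metrics.
#'
#' @param x,y Paired numeric vectors.
#' @return For `agreement_icc()`, the ICC(A,1) (two-way mixed,
#'   absolute agreement, single rater); for `count_correlation()`, the
#'   Pearson correlation.
#' @export
count_correlation <- function(x, y) stats::cor(x, y, method = "pearson")

#' @rdname count_correlation
#' @export
agreement_icc <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n >= 2)
  dat <- cbind(x, y)
  k <- 2
  grand <- mean(dat)
  ms_rows <- k * sum((rowMeans(dat) - grand)^2) / (n - 1)
  ms_cols <- n * sum((colMeans(dat) - grand)^2) / (k - 1)
  ss_err <- sum((dat - outer(rowMeans(dat), rep(1, k)) -
                   outer(rep(1, n), colMeans(dat)) + grand)^2)
  ms_err <- ss_err / ((n - 1) * (k - 1))
  (ms_rows - ms_err) / (ms_rows + (k - 1) * ms_err + k / n * (ms_cols - ms_err))
}
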