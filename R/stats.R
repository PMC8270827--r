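#' Cross-tabulate predictions against reference labels
#'
#' Builds the 2x2 confusion matrix with UA as the positive class. Stones
#' whose reference label is \code{"mixed"} are excluded before counting
#' (mixed stones have no reliable reference standard); the number excluded
#' is recorded.
#'
#' @param predictions per-stone predicted labels (\code{UA}/\code{non-UA}).
#' @param references per-stone reference labels (\code{UA}/\code{non-UA}/
#'   \code{mixed}), aligned with \code{predictions}.
#' @return An object of class \code{confusion_matrix}: list with counts
#'   \code{tp} (UA predicted UA), \code{fn}, \code{fp}, \code{tn} and
#'   \code{n_excluded}.
#' @examples
#' cm <- cross_tabulate(c("UA", "non-UA"), c("UA", "UA"))
#' cm$tp; cm$fn
#' @export
cross_tabulate <- function(predictions, references) {
  if (length(predictions) != length(references)) {
    stop("'predictions' and 'references' must have equal length")
  }
  pred <- normalize_label(predictions, allow_mixed = FALSE)
  ref <- normalize_label(references, allow_mixed = TRUE)
  keep <- ref != LBL_MIXED
  n_excluded <- sum(!keep)
  pred <- pred[keep]; ref <- ref[keep]
  confusion_matrix(
    tp = sum(pred == LBL_UA & ref == LBL_UA),
    fn = sum(pred == LBL_NONUA & ref == LBL_UA),
    fp = sum(pred == LBL_UA & ref == LBL_NONUA),
    tn = sum(pred == LBL_NONUA & ref == LBL_NONUA),
    n_excluded = n_excluded
  )
}

#' 2x2 confusion matrix (UA positive)
#'
#' @param tp,fn,fp,tn non-negative counts; \code{tp} = UA stones predicted
#'   UA, \code{tn} = non-UA predicted non-UA.
#' @param n_excluded number of mixed-reference stones excluded upstream.
#' @return An object of class \code{confusion_matrix}.
#' @export
confusion_matrix <- function(tp, fn, fp, tn, n_excluded = 0L) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be non-negative integers")
  }
  structure(list(tp = as.integer(tp), fn = as.integer(fn),
                 fp = as.integer(fp), tn = as.integer(tn),
                 n_excluded = as.integer(n_excluded)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("UA", "non-UA"),
                              reference = c("UA", "non-UA")))
  print(m)
  if (x$n_excluded > 0) cat(sprintf("(%d mixed stones excluded)\n", x$n_excluded))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Inverts the binomial tail via beta quantiles. At \code{x = 0} the lower
#' bound is exactly 0; at \code{x = n} the upper bound is exactly 1.
#'
#' @param x number of successes, \code{0 <= x <= n}.
#' @param n number of trials, \code{n >= 1}.
#' @param conf confidence level (default 0.95).
#' @return Numeric \code{c(lower, upper)} proportions.
#' @examples
#' round(exact_binomial_ci(37, 37) * 100)   # 91 100
#' round(exact_binomial_ci(103, 106) * 100) # 92  99
#' @export
exact_binomial_ci <- function(x, n, conf = 0.95) {
  if (!is_scalar_number(x) || !is_scalar_number(n) ||
      x != round(x) || n != round(n) || n < 1 || x < 0 || x > n) {
    stop("need integer counts with 0 <= x <= n and n >= 1")
  }
  if (!is_scalar_number(conf) || conf <= 0 || conf >= 1) {
    stop("'conf' must be in (0, 1)")
  }
  alpha <- 1 - conf
  lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
  upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
  c(lower = lower, upper = upper)
}

#' Sensitivity, specificity and accuracy with exact CIs
#'
#' Computes the three diagnostic proportions for the prediction of UA
#' stones, each with an exact binomial confidence interval. Raw proportions
#' are retained; integer-percent rounding (half up) happens only in the
#' print/format layer. A zero denominator yields \code{NA} with a flag
#' rather than being dropped silently.
#'
#' @param cm a \code{\link{confusion_matrix}}.
#' @param conf confidence level (default 0.95).
#' @return An object of class \code{diagnostic_report}: per metric a list
#'   with \code{estimate}, \code{x}, \code{n}, \code{ci} and
#'   \code{undefined}.
#' @examples
#' rep <- diagnostic_metrics(confusion_matrix(tp = 37, fn = 0, fp = 3, tn = 103))
#' print(rep)  # sensitivity 100%, specificity 97%, accuracy 98%
#' @export
diagnostic_metrics <- function(cm, conf = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  total <- cm$tp + cm$fn + cm$fp + cm$tn
  if (total == 0) stop("confusion matrix is empty")
  one <- function(x, n) {
    if (n == 0) {
      list(estimate = NA_real_, x = x, n = n,
           ci = c(lower = NA_real_, upper = NA_real_), undefined = TRUE)
    } else {
      list(estimate = x / n, x = x, n = n,
           ci = exact_binomial_ci(x, n, conf), undefined = FALSE)
    }
  }
  structure(list(
    sensitivity = one(cm$tp, cm$tp + cm$fn),
    specificity = one(cm$tn, cm$tn + cm$fp),
    accuracy = one(cm$tp + cm$tn, total),
    conf = conf,
    cm = cm
  ), class = "diagnostic_report")
}

#' Format a diagnostic metric as printed percent
#'
#' Integer percent, rounded half up, in the style
#' \code{"100\% (37/37) 91-100\%"}.
#'
#' @param metric one element of a \code{diagnostic_report} (e.g.
#'   \code{rep$sensitivity}).
#' @return A character string.
#' @export
format_metric <- function(metric) {
  if (isTRUE(metric$undefined)) return("undefined (0 denominator)")
  sprintf("%d%% (%d/%d) %d-%d%%",
          round_percent(metric$estimate), metric$x, metric$n,
          round_percent(metric$ci[["lower"]]), round_percent(metric$ci[["upper"]]))
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("Diagnostic accuracy for UA prediction (%.0f%% CI):\n", x$conf * 100))
  cat("  Sensitivity:", format_metric(x$sensitivity), "\n")
  cat("  Specificity:", format_metric(x$specificity), "\n")
  cat("  Accuracy:   ", format_metric(x$accuracy), "\n")
  invisible(x)
}

#' Exact McNemar test on discordant pairs
#'
#' Paired comparison of two classifiers evaluated on the same stones:
#' \code{b} and \code{c} are the two discordant counts (only classifier 1
#' correct / only classifier 2 correct). The default is the exact two-sided
#' binomial test of min(b, c) successes in b + c trials at probability 1/2;
#' a mid-p variant and the continuity-corrected chi-square are offered.
#'
#' @param b,c non-negative discordant-pair counts.
#' @param method \code{"exact"} (default), \code{"midp"} or
#'   \code{"chisq"}.
#' @return Two-sided p-value; 1 when \code{b == c == 0}.
#' @examples
#' mcnemar_exact(9, 3)  # 598/4096
#' @export
mcnemar_exact <- function(b, c, method = c("exact", "midp", "chisq")) {
  method <- match.arg(method)
  if (!is_scalar_number(b) || !is_scalar_number(c) || b < 0 || c < 0 ||
      b != round(b) || c != round(c)) {
    stop("'b' and 'c' must be non-negative integer counts")
  }
  n <- b + c
  if (n == 0) return(1)
  m <- min(b, c)
  switch(method,
    exact = min(1, 2 * stats::pbinom(m, n, 0.5)),
    midp = {
      p <- 2 * (stats::pbinom(m, n, 0.5) - 0.5 * stats::dbinom(m, n, 0.5))
      min(1, max(p, 0))
    },
    chisq = {
      if (b == c) return(1)
      stat <- (abs(b - c) - 1)^2 / n
      stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  )
}

#' Area under the ROC curve (midrank Mann-Whitney)
#'
#' Trapezoidal AUC over all score thresholds, computed as the Mann-Whitney
#' U statistic with midranks for ties: the probability that a randomly
#' chosen UA stone scores above a randomly chosen non-UA stone (+ half the
#' tie probability). For the kNN method the natural score is the UA vote
#' fraction; for the maxHU method use \code{direction = "lower"} (lower
#' attenuation is more UA-like).
#'
#' @param scores per-stone continuous scores.
#' @param references per-stone reference labels; mixed stones are excluded.
#' @param direction \code{"higher"} if larger scores mean more UA-like
#'   (default), \code{"lower"} for the opposite orientation.
#' @return AUC in [0, 1]; \code{NA} with a warning when only one class is
#'   present after exclusion.
#' @export
roc_auc <- function(scores, references, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  if (length(scores) != length(references)) {
    stop("'scores' and 'references' must have equal length")
  }
  if (!all(is.finite(scores))) stop("scores must be finite")
  ref <- normalize_label(references, allow_mixed = TRUE)
  keep <- ref != LBL_MIXED
  s <- scores[keep]; ref <- ref[keep]
  if (direction == "lower") s <- -s
  pos <- ref == LBL_UA
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(s, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
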