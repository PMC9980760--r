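# Diagnostic-accuracy statistics: confusion counts, sensitivity/specificity/
# PPV/NPV with exact (Clopper-Pearson) or Wilson confidence intervals, and
# the binary-indicator AUROC.

#' Confusion counts for a binary test against a reference standard
#'
#' @param predicted logical vector of test results.
#' @param truth logical vector of reference-standard results, same length.
#' @return a `two_by_two` object: list with integer fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
#' @examples
#' two_by_two(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
two_by_two <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop_invalid("predicted and truth must have equal length")
  }
  if (length(predicted) == 0) stop_invalid("empty input")
  predicted <- as.logical(predicted)
  truth <- as.logical(truth)
  if (anyNA(predicted) || anyNA(truth)) stop_invalid("NA in predicted/truth")
  two_by_two_counts(sum(predicted & truth), sum(predicted & !truth),
                    sum(!predicted & truth), sum(!predicted & !truth))
}

#' Construct a 2x2 table from its four counts
#'
#' @param tp,fp,fn,tn non-negative integer counts (true positive, false
#'   positive, false negative, true negative).
#' @return a `two_by_two` object.
#' @export
two_by_two_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be non-negative integers")
  }
  if (sum(counts) == 0) stop_invalid("empty table")
  structure(as.list(as.integer(counts)) |> stats::setNames(names(counts)),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Exact and approximate binomial confidence intervals
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method `"clopper-pearson"` (exact, default) or `"wilson"`.
#' @param conf confidence level.
#' @return numeric vector `c(lo, hi)` on the proportion scale.
#' @export
binom_ci <- function(x, n, method = c("clopper-pearson", "wilson"),
                     conf = 0.95) {
  method <- match.arg(method)
  if (n <= 0) return(c(NA_real_, NA_real_))
  a <- (1 - conf) / 2
  if (method == "clopper-pearson") {
    lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
  } else {
    z <- stats::qnorm(1 - a)
    p <- x / n
    den <- 1 + z^2 / n
    ctr <- (p + z^2 / (2 * n)) / den
    hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
    lo <- max(0, ctr - hw)
    hi <- min(1, ctr + hw)
  }
  c(lo, hi)
}

#' Sensitivity, specificity and predictive values with confidence intervals
#'
#' Computes the four standard accuracy statistics from a 2x2 table with 95%
#' confidence intervals (Clopper-Pearson exact by default). A statistic whose
#' denominator is zero is returned as `NA` with a warning rather than
#' silently as 0.
#'
#' @param t a [two_by_two()] object.
#' @param ci_method `"clopper-pearson"` or `"wilson"`.
#' @param conf confidence level (default 0.95).
#' @return tibble with columns `statistic`, `numerator`, `denominator`,
#'   `estimate`, `conf_low`, `conf_high` (proportions in `[0, 1]`).
#' @export
#' @examples
#' accuracy_stats(two_by_two_counts(65, 282, 13, 270))
accuracy_stats <- function(t, ci_method = c("clopper-pearson", "wilson"),
                           conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  ci_method <- match.arg(ci_method)
  spec <- list(
    sensitivity = c(t$tp, t$tp + t$fn),
    specificity = c(t$tn, t$tn + t$fp),
    ppv         = c(t$tp, t$tp + t$fp),
    npv         = c(t$tn, t$tn + t$fn)
  )
  rows <- lapply(names(spec), function(nm) {
    x <- spec[[nm]][1]; n <- spec[[nm]][2]
    if (n == 0) {
      warning("denominator of ", nm, " is zero; statistic undefined",
              call. = FALSE)
      est <- NA_real_; ci <- c(NA_real_, NA_real_)
    } else {
      est <- x / n
      ci <- binom_ci(x, n, method = ci_method, conf = conf)
    }
    tibble::tibble(statistic = nm, numerator = x, denominator = n,
                   estimate = est, conf_low = ci[1], conf_high = ci[2])
  })
  dplyr::bind_rows(rows)
}

#' AUROC of a binary indicator
#'
#' For a dichotomous test the ROC curve has a single interior vertex at
#' (1 - specificity, sensitivity), so the trapezoidal area reduces to
#' `(sensitivity + specificity) / 2`. The default confidence interval uses
#' the Hanley-McNeil standard error (the convention of the classic clinical
#' ROC literature and of SPSS-style outputs); the DeLong variance of the
#' indicator treated as a two-valued score is available as an alternative
#' and is typically narrower.
#'
#' @inheritParams accuracy_stats
#' @param se_method `"hanley-mcneil"` (default) or `"delong"`.
#' @return tibble with `auroc`, `conf_low`, `conf_high`.
#' @export
#' @examples
#' binary_auroc(two_by_two_counts(27, 15, 320, 596)) # about 0.53
binary_auroc <- function(t, conf = 0.95,
                         se_method = c("hanley-mcneil", "delong")) {
  stopifnot(inherits(t, "two_by_two"))
  se_method <- match.arg(se_method)
  n_pos <- t$tp + t$fn
  n_neg <- t$fp + t$tn
  if (n_pos == 0 || n_neg == 0) {
    stop_invalid("AUROC undefined: a class is empty")
  }
  sens <- t$tp / n_pos
  spec <- t$tn / n_neg
  auc <- (sens + spec) / 2
  if (se_method == "hanley-mcneil") {
    q1 <- auc / (2 - auc)
    q2 <- 2 * auc^2 / (1 + auc)
    v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
            (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  } else {
    scores <- c(rep(1, t$tp), rep(0, t$fn), rep(1, t$fp), rep(0, t$tn))
    labels <- c(rep(TRUE, n_pos), rep(FALSE, n_neg))
    v <- delong_auc_variance(scores, labels)
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tibble::tibble(auroc = auc,
                 conf_low = max(0, auc - z * sqrt(v)),
                 conf_high = min(1, auc + z * sqrt(v)))
}
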