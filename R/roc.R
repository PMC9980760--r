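# Rank-based AUROC, ROC curves and DeLong's paired test.

#' Empirical AUROC by the rank (Mann-Whitney) method
#'
#' Equals the probability that a randomly chosen case scores higher than a
#' randomly chosen control, plus half the probability of a tie. Identical to
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric vector of test scores (higher = more abnormal).
#' @param labels logical vector; `TRUE` for cases.
#' @return AUROC as a single number in `[0, 1]`.
#' @export
#' @examples
#' empirical_auroc(c(2, 3, 1, 2), c(TRUE, TRUE, FALSE, FALSE)) # 0.875
empirical_auroc <- function(scores, labels) {
  labels <- check_roc_input(scores, labels)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  r <- rank(scores)  # mid-ranks handle ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_roc_input <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop_invalid("length mismatch")
  if (anyNA(scores) || anyNA(labels)) stop_invalid("NA in scores/labels")
  if (!any(labels) || all(labels)) {
    stop_invalid("both classes must be present")
  }
  labels
}

# DeLong placement values: for each case, the fraction of controls it beats
# (ties half); for each control, the fraction of cases it is beaten by.
delong_placements <- function(scores, labels) {
  x <- scores[labels]    # cases
  y <- scores[!labels]   # controls
  m <- length(x)
  n <- length(y)
  # placement of each case among controls via ranks in the pooled sample
  all_r <- rank(c(x, y))
  rx <- rank(x)
  ry <- rank(y)
  v10 <- (all_r[seq_len(m)] - rx) / n
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

# DeLong variance of a single empirical AUROC
delong_auc_variance <- function(scores, labels) {
  labels <- check_roc_input(scores, labels)
  p <- delong_placements(scores, labels)
  stats::var(p$v10) / length(p$v10) + stats::var(p$v01) / length(p$v01)
}

#' Confidence interval for an empirical AUROC (DeLong variance)
#'
#' @inheritParams empirical_auroc
#' @param conf confidence level.
#' @return tibble with `auroc`, `conf_low`, `conf_high`.
#' @export
auroc_ci <- function(scores, labels, conf = 0.95) {
  auc <- empirical_auroc(scores, labels)
  v <- delong_auc_variance(scores, labels)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  tibble::tibble(auroc = auc,
                 conf_low = max(0, auc - z * sqrt(v)),
                 conf_high = min(1, auc + z * sqrt(v)))
}

#' DeLong's test for two paired (correlated) AUROCs
#'
#' Compares the AUROCs of two scores measured on the same subjects using the
#' placement-value covariance estimator; the difference is referred to a
#' standard normal. When the two scores induce identical placements the
#' variance of the difference is zero and the test returns `z = 0`, `p = 1`
#' with a warning.
#'
#' @param scores_a,scores_b numeric score vectors, paired by subject.
#' @param labels logical vector; `TRUE` for cases.
#' @param conf confidence level for the per-AUROC intervals.
#' @return a `delong_test` object: list with `auroc_a`, `auroc_b` (each a
#'   tibble from [auroc_ci()]), `diff`, `se_diff`, `z`, `p_value`.
#' @export
#' @examples
#' set.seed(1)
#' lab <- rep(c(TRUE, FALSE), each = 20)
#' a <- rnorm(40, mean = lab * 1.2)
#' b <- rnorm(40, mean = lab * 0.4)
#' delong_test(a, b, lab)
delong_test <- function(scores_a, scores_b, labels, conf = 0.95) {
  labels <- check_roc_input(scores_a, labels)
  check_roc_input(scores_b, labels)
  pa <- delong_placements(scores_a, labels)
  pb <- delong_placements(scores_b, labels)
  m <- length(pa$v10)
  n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  s <- s10 / m + s01 / n
  var_diff <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    warning("zero variance of AUROC difference; returning z = 0, p = 1",
            call. = FALSE)
    z <- 0
    p <- 1
    se <- 0
  } else {
    se <- sqrt(var_diff)
    z <- d / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(
    auroc_a = auroc_ci(scores_a, labels, conf),
    auroc_b = auroc_ci(scores_b, labels, conf),
    diff = d, se_diff = se, z = z, p_value = p
  ), class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat("DeLong's test for two correlated AUROCs\n")
  cat(sprintf("  AUROC A: %.3f (%.3f-%.3f)\n", x$auroc_a$auroc,
              x$auroc_a$conf_low, x$auroc_a$conf_high))
  cat(sprintf("  AUROC B: %.3f (%.3f-%.3f)\n", x$auroc_b$auroc,
              x$auroc_b$conf_low, x$auroc_b$conf_high))
  cat(sprintf("  difference = %.4f, z = %.3f, p = %.4g\n",
              x$diff, x$z, x$p_value))
  invisible(x)
}

#' Empirical ROC curve
#'
#' Threshold sweep over the unique score values (rule: positive if
#' `score >= threshold`), yielding the monotone staircase from (0, 0) to
#' (1, 1). Its trapezoidal area equals [empirical_auroc()].
#'
#' @inheritParams empirical_auroc
#' @return tibble with columns `threshold`, `fpr`, `tpr`; the first row is
#'   the (0, 0) corner with threshold `Inf`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_roc_input(scores, labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  tpr <- vapply(thr, function(t) sum(scores[labels] >= t) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!labels] >= t) / n0, numeric(1))
  tibble::tibble(threshold = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
}

# trapezoid area under a roc_curve tibble (used for cross-checks)
roc_auc_trapezoid <- function(curve) {
  sum(diff(curve$fpr) * (utils::head(curve$tpr, -1) + utils::tail(curve$tpr, -1)) / 2)
}
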