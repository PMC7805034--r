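# Diagnostic-accuracy metrics, tie-aware ROC concordance with DeLong
# variance, and the paired DeLong test for correlated AUCs.

check_truth <- function(truth) {
  truth <- as.logical(truth)
  if (anyNA(truth)) stop("truth labels must not be missing")
  if (!any(truth) || all(truth)) {
    stop("need at least one positive and one negative truth label")
  }
  truth
}

#' Confusion-table diagnostic metrics
#'
#' Sensitivity, specificity, positive and negative predictive value of a
#' binary predictor against a binary truth, reported both as exact fractions
#' and as percents rounded to the nearest integer. A metric whose denominator
#' is empty (e.g. PPV with no predicted positives) is returned as `NA` and
#' flagged in `undefined`.
#'
#' @param pred logical vector of predicted positives.
#' @param truth logical vector of true positives (at least one `TRUE` and one
#'   `FALSE`).
#' @return List with counts `tp`, `fp`, `tn`, `fn`, exact fractions
#'   `sensitivity`, `specificity`, `ppv`, `npv`, rounded
#'   `sensitivity_pct`, ..., and `undefined` (character vector of flagged
#'   metrics).
#' @examples
#' confusion_metrics(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_metrics <- function(pred, truth) {
  truth <- check_truth(truth)
  pred <- as.logical(pred)
  stopifnot(length(pred) == length(truth), !anyNA(pred))
  tp <- sum(pred & truth)
  fp <- sum(pred & !truth)
  tn <- sum(!pred & !truth)
  fn <- sum(!pred & truth)
  frac <- function(num, den) if (den == 0) NA_real_ else num / den
  out <- list(tp = tp, fp = fp, tn = tn, fn = fn,
              sensitivity = frac(tp, tp + fn),
              specificity = frac(tn, tn + fp),
              ppv = frac(tp, tp + fp),
              npv = frac(tn, tn + fn))
  pct <- lapply(out[c("sensitivity", "specificity", "ppv", "npv")],
                function(x) if (is.na(x)) NA_real_ else round(100 * x))
  names(pct) <- paste0(names(pct), "_pct")
  out <- c(out, pct)
  out$undefined <- names(which(vapply(
    out[c("sensitivity", "specificity", "ppv", "npv")], is.na, logical(1))))
  out
}

# Pairwise-comparison (placement) matrix psi[i, j] for positive score x_i vs
# negative score y_j: 1 if x > y, 0.5 if tied, 0 otherwise.
placement_matrix <- function(pos, neg) {
  (outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")) * 1
}

#' Tie-aware ROC concordance with DeLong variance
#'
#' Mann-Whitney estimator of the area under the ROC curve for an ordinal (or
#' continuous) score: the mean over all (positive, negative) pairs of the
#' indicator that the positive scores higher, with ties counting one half.
#' The variance is DeLong's structural-components estimator and the
#' confidence interval a normal approximation truncated to \[0, 1\].
#'
#' @param scores numeric or ordinal scores, higher meaning more likely
#'   positive.
#' @param truth logical outcome labels.
#' @param conf_level confidence level for the interval (default 0.95).
#' @return An `auc_result`: `auc`, `variance`, `ci_low`, `ci_high`, counts
#'   `n_pos`, `n_neg`, and the structural components `v10`, `v01`.
#' @examples
#' auc_ordinal(c(3, 3, 2, 1, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' @export
auc_ordinal <- function(scores, truth, conf_level = 0.95) {
  truth <- check_truth(truth)
  stopifnot(length(scores) == length(truth), !anyNA(scores))
  pos <- scores[truth]
  neg <- scores[!truth]
  m <- length(pos)
  n <- length(neg)
  psi <- placement_matrix(pos, neg)
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # one per positive
  v01 <- colMeans(psi)  # one per negative
  variance <- if (m > 1L && n > 1L) {
    stats::var(v10) / m + stats::var(v01) / n
  } else {
    NA_real_
  }
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  half <- if (is.na(variance)) NA_real_ else z * sqrt(variance)
  structure(list(auc = auc, variance = variance,
                 ci_low = max(0, auc - half), ci_high = min(1, auc + half),
                 conf_level = conf_level, n_pos = m, n_neg = n,
                 v10 = v10, v01 = v01),
            class = "auc_result")
}

#' @export
print.auc_result <- function(x, ...) {
  cat(sprintf("AUC = %.4f (%d%% CI %.2f-%.2f; DeLong), %d positives / %d negatives\n",
              x$auc, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Compares the ROC areas of two score vectors measured on the same subjects
#' using DeLong's structural-components covariance:
#' \deqn{\widehat{var}(\hat A_a - \hat A_b) =
#'   \frac{s^{10}_{aa} + s^{10}_{bb} - 2 s^{10}_{ab}}{m} +
#'   \frac{s^{01}_{aa} + s^{01}_{bb} - 2 s^{01}_{ab}}{n},}
#' with `z = dAUC / sqrt(var)` referred to a standard normal (two-sided).
#' When the estimated variance is zero (e.g. identical scores) the result is
#' reported as an exact tie, with no division performed: `p = 1` if the AUC
#' difference is zero, `NA` otherwise.
#'
#' @param scores_a,scores_b score vectors for the two models, same subjects,
#'   same order.
#' @param truth logical outcome labels.
#' @return A `delong_test`: `auc_a`, `auc_b`, `delta` (a minus b),
#'   `variance`, `z`, `p_value`, `tie` flag.
#' @export
delong_paired_test <- function(scores_a, scores_b, truth) {
  truth <- check_truth(truth)
  stopifnot(length(scores_a) == length(truth),
            length(scores_b) == length(truth))
  ra <- auc_ordinal(scores_a, truth)
  rb <- auc_ordinal(scores_b, truth)
  m <- ra$n_pos
  n <- ra$n_neg
  s10 <- stats::cov(cbind(ra$v10, rb$v10))
  s01 <- stats::cov(cbind(ra$v01, rb$v01))
  variance <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ra$auc - rb$auc
  if (!is.finite(variance) || variance <= 1e-30) {
    z <- NA_real_
    p <- if (abs(delta) < 1e-15) 1 else NA_real_
    tie <- TRUE
  } else {
    z <- delta / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
    tie <- FALSE
  }
  structure(list(auc_a = ra$auc, auc_b = rb$auc, delta = delta,
                 variance = variance, z = z, p_value = p, tie = tie),
            class = "delong_test")
}

#' @export
print.delong_test <- function(x, ...) {
  cat(sprintf("Paired DeLong test: AUC %.4f vs %.4f, dAUC = %+.4f\n",
              x$auc_a, x$auc_b, x$delta))
  if (x$tie) {
    cat("  degenerate variance: reported as exact tie, p =",
        format(x$p_value), "\n")
  } else {
    cat(sprintf("  z = %.3f, two-sided p = %.4g\n", x$z, x$p_value))
  }
  invisible(x)
}

#' Empirical ROC points
#'
#' Operating points of the empirical ROC curve of a score vector (one point
#' per distinct threshold, plus the extremes), suitable for plotting.
#'
#' @inheritParams auc_ordinal
#' @return Data frame with columns `threshold`, `fpr`, `tpr`, ordered from
#'   (0, 0) to (1, 1).
#' @export
roc_points <- function(scores, truth) {
  truth <- check_truth(truth)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  pts <- vapply(thresholds, function(thr) {
    pred <- scores >= thr
    c(fpr = sum(pred & !truth) / sum(!truth),
      tpr = sum(pred & truth) / sum(truth))
  }, numeric(2))
  data.frame(threshold = c(Inf, thresholds),
             fpr = c(0, pts["fpr", ]),
             tpr = c(0, pts["tpr", ]))
}
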