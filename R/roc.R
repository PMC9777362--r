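#' ROC curve of the PHC score against the gold standard
#'
#' Sweeps integer thresholds 0..17 with the test-positive convention
#' `score >= threshold`, so threshold 0 classifies everyone positive
#' (sensitivity 1, specificity 0) and threshold 17 no one (0, 1).
#' Sensitivity and specificity are weighted fractions when design weights
#' are supplied; with equal weights the curve equals the unweighted one
#' exactly. The AUC is computed by the trapezoidal rule over the
#' (1 - specificity, sensitivity) points, which for unweighted data equals
#' the Mann-Whitney concordance probability
#' \eqn{P(S_{pos} > S_{neg}) + P(S_{pos} = S_{neg})/2}.
#'
#' @param scores Numeric PHC scores (0..16; `NA` pairs are dropped).
#' @param labels Logical gold-standard labels (`TRUE` = positive).
#' @param weights Optional positive design weights; `NULL` for unweighted.
#' @return An object of class `roc_curve`: a list with the per-threshold
#'   table (`thresholds`, `sensitivity`, `specificity`, unweighted
#'   true-positive/true-negative counts `n_tp`, `n_tn`), `auc`, the
#'   positive/negative counts and the number of dropped incomplete pairs.
#' @export
roc_curve <- function(scores, labels, weights = NULL) {
  n <- length(scores)
  if (length(labels) != n) {
    stop("'scores' and 'labels' must have the same length", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  if (length(weights) != n) {
    stop("'weights' must match 'scores' in length", call. = FALSE)
  }
  labels <- as.logical(labels)
  keep <- !is.na(scores) & !is.na(labels) & !is.na(weights)
  n_dropped <- sum(!keep)
  s <- scores[keep]; y <- labels[keep]; w <- weights[keep]
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  if (!any(y)) {
    stop("degenerate input: no gold-positive observations", call. = FALSE)
  }
  if (all(y)) {
    stop("degenerate input: no gold-negative observations", call. = FALSE)
  }

  thresholds <- 0:17
  w_pos <- sum(w[y]); w_neg <- sum(w[!y])
  sens <- vapply(thresholds, function(t) sum(w[y & s >= t]) / w_pos,
                 numeric(1))
  spec <- vapply(thresholds, function(t) sum(w[!y & s < t]) / w_neg,
                 numeric(1))
  n_tp <- vapply(thresholds, function(t) sum(y & s >= t), numeric(1))
  n_tn <- vapply(thresholds, function(t) sum(!y & s < t), numeric(1))

  # trapezoid over the curve ordered from (0,0) to (1,1)
  fpr <- rev(1 - spec); tpr <- rev(sens)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)

  structure(
    list(
      thresholds = thresholds, sensitivity = sens, specificity = spec,
      n_tp = as.integer(n_tp), n_tn = as.integer(n_tn),
      auc = auc, n_pos = sum(y), n_neg = sum(!y),
      weighted = !all(w == w[1]), n_dropped = n_dropped
    ),
    class = "roc_curve"
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve: %d positives, %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Select the operating cutoff on a ROC curve
#'
#' The default rule maximises the Youden index J = sensitivity +
#' specificity - 1 over the swept thresholds; the alternative
#' `"corner"` rule minimises the squared distance to the perfect
#' (0, 1) corner. Ties are broken toward the lower threshold. Wilson
#' score 95% intervals for sensitivity and specificity are attached
#' (computed from the unweighted true-positive/true-negative counts).
#'
#' @param curve A [roc_curve()] object.
#' @param rule `"youden"` (default) or `"corner"`.
#' @param conf Confidence level for the Wilson intervals.
#' @return An object of class `cutoff_result` with the selected `cutoff`,
#'   sensitivity and specificity with confidence intervals, the curve's
#'   AUC, and the `selection_rule` label.
#' @export
select_cutoff <- function(curve, rule = c("youden", "corner"),
                          conf = 0.95) {
  if (!inherits(curve, "roc_curve")) {
    stop("expected a 'roc_curve' object", call. = FALSE)
  }
  rule <- match.arg(rule)
  # ties (including floating-point ties) break toward the lower threshold
  idx <- switch(rule,
    youden = {
      j <- curve$sensitivity + curve$specificity - 1
      which(j >= max(j) - 1e-10)[1]
    },
    corner = {
      d <- (1 - curve$sensitivity)^2 + (1 - curve$specificity)^2
      which(d <= min(d) + 1e-10)[1]
    }
  )
  structure(
    list(
      cutoff = curve$thresholds[idx],
      sensitivity = curve$sensitivity[idx],
      sensitivity_ci = proportion_ci(curve$n_tp[idx], curve$n_pos, conf),
      specificity = curve$specificity[idx],
      specificity_ci = proportion_ci(curve$n_tn[idx], curve$n_neg, conf),
      auc = curve$auc,
      selection_rule = rule,
      conf = conf
    ),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf(
    paste0("Selected cutoff %d (%s rule): sensitivity %.1f%% (%.1f; %.1f),",
           " specificity %.1f%% (%.1f; %.1f), AUC %.3f\n"),
    x$cutoff, x$selection_rule,
    100 * x$sensitivity, 100 * x$sensitivity_ci[1], 100 * x$sensitivity_ci[2],
    100 * x$specificity, 100 * x$specificity_ci[1], 100 * x$specificity_ci[2],
    x$auc
  ))
  invisible(x)
}

#' Wilson score confidence interval for a proportion
#'
#' Bounded, well-behaved at small n and at the 0/1 boundaries, unlike the
#' Wald interval.
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (>= 1).
#' @param conf Confidence level (default 0.95).
#' @return Numeric of length 2: lower and upper bound, within \[0, 1\].
#' @export
proportion_ci <- function(k, n, conf = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n) {
    stop("need 0 <= k <= n with n >= 1", call. = FALSE)
  }
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  pmin(1, pmax(0, c(centre - half, centre + half)))
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples respondents with replacement (or whole clusters, when a
#' cluster vector is given, so that the within-class dependence is
#' respected) and recomputes the trapezoidal AUC on each resample.
#' Resamples that lose one of the two classes are redrawn, up to a cap of
#' `10 * n_boot` total draws. Reproducible given `seed`; the global RNG
#' state is untouched.
#'
#' @inheritParams roc_curve
#' @param cluster Optional cluster identifiers for cluster bootstrap.
#' @param n_boot Number of bootstrap resamples (>= 100).
#' @param seed Integer RNG seed.
#' @param conf Confidence level.
#' @return Numeric of length 2: percentile interval for the AUC.
#' @export
auc_ci <- function(scores, labels, weights = NULL, cluster = NULL,
                   n_boot = 1000L, seed = 1L, conf = 0.95) {
  if (n_boot < 100) stop("'n_boot' must be at least 100", call. = FALSE)
  base <- roc_curve(scores, labels, weights)  # validates inputs
  n <- length(scores)
  if (is.null(weights)) weights <- rep(1, n)
  idx_by_cluster <- if (!is.null(cluster)) split(seq_len(n), cluster)

  withr::with_seed(as.integer(seed), {
    aucs <- numeric(n_boot)
    draws <- 0L
    cap <- 10L * n_boot
    b <- 1L
    while (b <= n_boot) {
      if (draws >= cap) {
        warning("bootstrap redraw cap reached; interval based on fewer resamples",
                call. = FALSE)
        aucs <- aucs[seq_len(b - 1L)]
        break
      }
      draws <- draws + 1L
      idx <- if (is.null(idx_by_cluster)) {
        sample.int(n, n, replace = TRUE)
      } else {
        unlist(idx_by_cluster[sample.int(length(idx_by_cluster),
                                         length(idx_by_cluster),
                                         replace = TRUE)],
               use.names = FALSE)
      }
      y <- labels[idx]
      ok <- !is.na(y)
      if (!any(y[ok]) || all(y[ok])) next  # degenerate resample: redraw
      aucs[b] <- roc_curve(scores[idx], y, weights[idx])$auc
      b <- b + 1L
    }
    alpha <- 1 - conf
    unname(quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  })
}
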