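#' Pearson correlation with t-based p-value
#'
#' Sample Pearson correlation; the two-sided p-value uses the exact null
#' transform `t = r * sqrt((n - 2) / (1 - r^2))` with `n - 2` degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite.
#' @return A `correlation_result`: list with `r`, `n`, `p`, `method`.
#' @examples
#' pearson_r(1:10, (1:10) + rnorm(10))
#' @export
pearson_r <- function(x, y) {
  check_xy(x, y)
  n <- length(x)
  dx <- x - mean(x); dy <- y - mean(y)
  ssx <- sum(dx^2); ssy <- sum(dy^2)
  if (ssx == 0 || ssy == 0) {
    stop("undefined correlation: zero variance in x or y")
  }
  r <- sum(dx * dy) / sqrt(ssx * ssy)
  r <- max(-1, min(1, r))
  p <- if (abs(r) == 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  }
  structure(list(r = r, n = n, p = p, method = "pearson"),
            class = "correlation_result")
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (ties receive their average rank), with
#' the same t-transform p-value computed on the rank correlation.
#'
#' @inheritParams pearson_r
#' @return A `correlation_result`.
#' @export
spearman_r <- function(x, y) {
  check_xy(x, y)
  out <- pearson_r(rank(x, ties.method = "average"),
                   rank(y, ties.method = "average"))
  out$method <- "spearman"
  out
}

check_xy <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  invisible(NULL)
}

#' Welch two-sample t-test
#'
#' Unequal-variance (Welch) t statistic with Welch-Satterthwaite degrees of
#' freedom and a two-sided p-value.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return List with `t`, `df`, `p`, and the sample means.
#' @examples
#' t_test_two_sample(rnorm(20), rnorm(20, 1))
#' @export
t_test_two_sample <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2,
            all(is.finite(a)), all(is.finite(b)))
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (mean(a) == mean(b)) {
      return(list(t = 0, df = na + nb - 2, p = 1,
                  mean_a = mean(a), mean_b = mean(b)))
    }
    stop("degenerate input: zero variance in both samples with unequal means")
  }
  tt <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = tt, df = df, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE),
       mean_a = mean(a), mean_b = mean(b))
}

# Map scores to a "risk" scale where larger means more disease-ward.
risk_scores <- function(scores, orientation) {
  if (orientation == "lower") -scores else scores
}

#' Empirical ROC curve and AUC
#'
#' ROC curve over all distinct score thresholds, with the orientation
#' stating which direction of the score indicates disease (for both PAV
#' and FMD, lower values do). The AUC is computed by the trapezoid rule
#' and equals the Mann-Whitney estimator with ties counted 1/2. A
#' Youden-optimal cutoff and its sensitivity/specificity are computed and
#' stored.
#'
#' @param scores numeric scores.
#' @param labels logical (or 0/1) disease labels; both classes must be
#'   present.
#' @param orientation `"lower"` (smaller score indicates disease) or
#'   `"higher"`.
#' @return A `roc_result`: list with `points` (data.frame `threshold`,
#'   `fpr`, `tpr`), `auc`, `orientation`, `cutoff`, `sensitivity`,
#'   `specificity`, `n_pos`, `n_neg`, and the input `scores`/`labels`.
#' @examples
#' coh <- simulate_cohort(cad_group_specs(), seed = 1)
#' roc_curve(coh$pav, coh$cad)$auc
#' @export
roc_curve <- function(scores, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)),
            !anyNA(labels))
  if (!any(labels) || all(labels)) {
    stop("both diseased and non-diseased subjects are required")
  }
  risk <- risk_scores(scores, orientation)
  thr <- sort(unique(risk), decreasing = TRUE)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- vapply(thr, function(th) sum(risk[labels] >= th), numeric(1)) / n_pos
  fpr <- vapply(thr, function(th) sum(risk[!labels] >= th), numeric(1)) / n_neg
  pts <- data.frame(
    threshold = c(NA, if (orientation == "lower") -thr else thr),
    fpr = c(0, fpr), tpr = c(0, tpr)
  )
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  out <- structure(list(points = pts, auc = auc, orientation = orientation,
                        n_pos = n_pos, n_neg = n_neg,
                        scores = scores, labels = labels),
                   class = "roc_result")
  out$cutoff <- youden_cutoff(out)
  ss <- sens_spec_at_cutoff(scores, labels, out$cutoff, orientation)
  out$sensitivity <- ss$sensitivity
  out$specificity <- ss$specificity
  out
}

#' Sensitivity and specificity at a fixed cutoff
#'
#' With `orientation = "lower"` (smaller score indicates disease):
#' sensitivity is the fraction of diseased subjects with score strictly
#' below the cutoff, specificity the fraction of non-diseased subjects
#' with score at or above it. With `"higher"` the inequalities are
#' mirrored (strictly above / at or below).
#'
#' @inheritParams roc_curve
#' @param cutoff decision threshold on the score scale.
#' @return List with `sensitivity` and `specificity`.
#' @export
sens_spec_at_cutoff <- function(scores, labels, cutoff,
                                orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels)) {
    stop("both diseased and non-diseased subjects are required")
  }
  positive <- if (orientation == "lower") scores < cutoff else scores > cutoff
  list(sensitivity = mean(positive[labels]),
       specificity = mean(!positive[!labels]))
}

#' Youden-optimal cutoff
#'
#' Scans the midpoints between adjacent distinct score values (plus one
#' candidate below the minimum and one above the maximum) and returns the
#' cutoff maximizing the Youden index J = sensitivity + specificity - 1.
#' Ties are broken toward the candidate nearest the score median.
#'
#' @param roc a `roc_result` from [roc_curve()].
#' @return The optimal cutoff (score scale).
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  s <- sort(unique(roc$scores))
  gap <- if (length(s) > 1) min(diff(s)) / 2 else 1
  cand <- c(s[1] - gap, if (length(s) > 1) (utils::head(s, -1) + utils::tail(s, -1)) / 2,
            s[length(s)] + gap)
  j <- vapply(cand, function(cu) {
    ss <- sens_spec_at_cutoff(roc$scores, roc$labels, cu, roc$orientation)
    ss$sensitivity + ss$specificity - 1
  }, numeric(1))
  best <- which(j >= max(j) - 1e-12)
  med <- stats::median(roc$scores)
  cand[best[which.min(abs(cand[best] - med))]]
}

#' DeLong paired comparison of two AUCs
#'
#' Tests the difference of two empirical AUCs computed on the SAME
#' subjects (e.g. PAV and FMD scores of one cohort) using the DeLong
#' placement-value covariance estimate: `Z = (AUC1 - AUC2) / SE(diff)`
#' with a two-sided normal p-value.
#'
#' @param roc1,roc2 `roc_result` objects built on identical subjects (same
#'   length, identical labels).
#' @return List with `z`, `p`, `auc1`, `auc2`, `se_diff`.
#' @examples
#' coh <- simulate_cohort(cad_group_specs(), seed = 1)
#' auc_compare_z(roc_curve(coh$pav, coh$cad),
#'               roc_curve(coh$fmd_percent, coh$cad))$z
#' @export
auc_compare_z <- function(roc1, roc2) {
  stopifnot(inherits(roc1, "roc_result"), inherits(roc2, "roc_result"))
  if (length(roc1$labels) != length(roc2$labels) ||
      !all(roc1$labels == roc2$labels)) {
    stop("unpaired inputs: the two ROC curves must share subjects and labels")
  }
  labels <- roc1$labels
  m <- sum(labels); n <- sum(!labels)
  placements <- function(roc) {
    risk <- risk_scores(roc$scores, roc$orientation)
    xs <- risk[labels]; ys <- risk[!labels]
    psi <- outer(xs, ys, function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  p1 <- placements(roc1); p2 <- placements(roc2)
  s10 <- stats::cov(cbind(p1$v10, p2$v10))
  s01 <- stats::cov(cbind(p1$v01, p2$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- p1$auc - p2$auc
  z <- if (var_diff <= 0) {
    if (d == 0) 0 else sign(d) * Inf
  } else d / sqrt(var_diff)
  list(z = z, p = 2 * stats::pnorm(abs(z), lower.tail = FALSE),
       auc1 = p1$auc, auc2 = p2$auc,
       se_diff = sqrt(max(var_diff, 0)))
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.3f (n = %d, two-sided p = %.3g)\n",
              x$method, x$r, x$n, x$p))
  invisible(x)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s score indicates disease): AUC = %.3f (%d diseased / %d controls)\n",
              x$orientation, x$auc, x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.3g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$cutoff, 100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}
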