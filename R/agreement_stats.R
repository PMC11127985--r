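#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' Supremum of the absolute difference of the two empirical CDFs, with the
#' asymptotic (Kolmogorov distribution) p-value. Used to ask whether an
#' automated method's attenuation values are distributed like the reference
#' standard's.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return A list with `statistic` and `p_value`.
#' @export
ks_compare <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  res <- suppressWarnings(stats::ks.test(a, b, alternative = "two.sided",
                                         exact = FALSE))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Bland-Altman analysis of paired readings
#'
#' Differences are `method - reference`; the 95% limits of agreement are the
#' mean difference plus/minus 1.96 sample standard deviations of the
#' differences.
#'
#' @param method_hu,reference_hu paired numeric readings (length >= 2).
#' @return A list with `mean_diff`, `loa_low`, `loa_high`.
#' @export
bland_altman <- function(method_hu, reference_hu) {
  check_pairs(method_hu, reference_hu)
  d <- method_hu - reference_hu
  m <- mean(d)
  s <- stats::sd(d)
  list(mean_diff = m, loa_low = m - 1.96 * s, loa_high = m + 1.96 * s)
}

check_pairs <- function(a, b) {
  if (length(a) != length(b)) stop("paired readings must have equal length")
  if (length(a) < 2L) stop("need at least 2 paired readings")
  if (any(!is.finite(a)) || any(!is.finite(b)))
    stop("readings must be finite")
  invisible(TRUE)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Intraclass correlation for agreement between k raters (or methods) each
#' measuring n subjects once, computed from the two-way ANOVA mean squares:
#' `icc = (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`, with the 95%
#' confidence interval from the F-distribution method of McGraw and Wong.
#'
#' @param ratings numeric matrix, n subjects x k raters, no missing cells,
#'   n >= 5 and k >= 2.
#' @param conf_level confidence level for the interval, default 0.95.
#' @return A list with `icc`, `ci_low`, `ci_high`, and the mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_absolute_single <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  if (any(!is.finite(ratings))) stop("ratings must be complete and finite")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (abs(denom) < 1e-300) stop("undefined ICC: zero variance in ratings")
  icc <- (msr - mse) / denom
  alpha <- 1 - conf_level
  if (mse <= 0 && msc <= msr * 1e-12) {
    # raters numerically identical: exact agreement, degenerate interval
    return(list(icc = 1, ci_low = 1, ci_high = 1,
                msr = msr, msc = msc, mse = mse))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       msr = msr, msc = msc, mse = mse)
}

#' Error and rank-correlation summaries of paired readings
#'
#' Mean absolute error, mean squared error, and Spearman's rank correlation
#' (average ranks on ties) between method and reference readings.
#'
#' @inheritParams bland_altman
#' @return A list with `mae`, `mse`, `spearman_rho`.
#' @export
error_and_correlation <- function(method_hu, reference_hu) {
  check_pairs(method_hu, reference_hu)
  d <- method_hu - reference_hu
  list(mae = mean(abs(d)), mse = mean(d^2),
       spearman_rho = stats::cor(method_hu, reference_hu,
                                 method = "spearman"))
}

#' Full agreement report between a method and the reference standard
#'
#' Bundles the distribution comparison (KS), Bland-Altman limits of
#' agreement, error summaries, Spearman correlation, and ICC(2,1) treating
#' the method and the reference as two raters of the same subjects.
#'
#' @inheritParams bland_altman
#' @return A list with components `ks`, `bland_altman`, `errors`, `icc`.
#' @export
agreement_report <- function(method_hu, reference_hu) {
  check_pairs(method_hu, reference_hu)
  list(ks = ks_compare(method_hu, reference_hu),
       bland_altman = bland_altman(method_hu, reference_hu),
       errors = error_and_correlation(method_hu, reference_hu),
       icc = icc_absolute_single(cbind(method = method_hu,
                                       reference = reference_hu)))
}

# Mann-Whitney AUC with average-rank tie correction; higher score = more
# positive. Deterministic, no resampling.
rank_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Steatosis classification performance with bootstrap CIs
#'
#' Evaluates the attenuation threshold rule (positive iff score strictly
#' below `threshold_hu`) against binary steatosis labels: sensitivity and
#' specificity from the confusion table, and AUC of the negated score (lower
#' attenuation means fattier liver, hence more positive) by the rank
#' (Mann-Whitney) method with tie correction. Percentile bootstrap over
#' cases gives the confidence intervals; bootstrap replicates in which only
#' one class is drawn are skipped and counted.
#'
#' @param scores_hu numeric attenuation values.
#' @param labels binary steatosis labels (1/TRUE = steatosis); both classes
#'   must be present.
#' @param threshold_hu decision threshold, default 40.
#' @param n_boot bootstrap replicates, default 1000.
#' @param seed RNG seed for resampling.
#' @param conf_level confidence level, default 0.95.
#' @return A `classification_report` list: `auc`, `sensitivity`,
#'   `specificity` with `*_ci` intervals, `threshold_hu`, the confusion
#'   counts `tp`, `fp`, `tn`, `fn`, and `n_boot_skipped`.
#' @export
classification_performance <- function(scores_hu, labels, threshold_hu = 40,
                                       n_boot = 1000L, seed = 1L,
                                       conf_level = 0.95) {
  if (any(!is.finite(scores_hu))) stop("scores must be finite")
  labels <- as.logical(labels > 0 | labels == TRUE)
  if (length(labels) != length(scores_hu))
    stop("scores and labels must have equal length")
  if (!any(labels) || all(labels))
    stop("both classes must be present in labels")

  point <- function(sc, lab) {
    pred <- sc < threshold_hu
    tp <- sum(pred & lab); fn <- sum(!pred & lab)
    tn <- sum(!pred & !lab); fp <- sum(pred & !lab)
    c(auc = rank_auc(-sc, lab),
      sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
      tp = tp, fp = fp, tn = tn, fn = fn)
  }
  est <- point(scores_hu, labels)

  n <- length(scores_hu)
  alpha <- 1 - conf_level
  boot <- matrix(NA_real_, nrow = n_boot, ncol = 3)
  skipped <- 0L
  with_local_seed(seed, {
    for (bb in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      lab <- labels[idx]
      if (!any(lab) || all(lab)) { skipped <- skipped + 1L; next }
      boot[bb, ] <- point(scores_hu[idx], lab)[1:3]
    }
  })
  ci <- apply(boot, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), na.rm = TRUE)
  structure(list(auc = unname(est["auc"]), auc_ci = unname(ci[, 1]),
                 sensitivity = unname(est["sensitivity"]),
                 sens_ci = unname(ci[, 2]),
                 specificity = unname(est["specificity"]),
                 spec_ci = unname(ci[, 3]),
                 threshold_hu = threshold_hu,
                 tp = unname(est["tp"]), fp = unname(est["fp"]),
                 tn = unname(est["tn"]), fn = unname(est["fn"]),
                 n_boot = n_boot, n_boot_skipped = skipped),
            class = "classification_report")
}

#' @export
print.classification_report <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%.3f (95%% CI %.3f-%.3f)", v, ci[1], ci[2])
  cat("<classification_report> threshold <", x$threshold_hu, "HU\n")
  cat("  AUC:        ", fmt(x$auc, x$auc_ci), "\n")
  cat("  sensitivity:", fmt(x$sensitivity, x$sens_ci), "\n")
  cat("  specificity:", fmt(x$specificity, x$spec_ci), "\n")
  cat("  confusion (tp fp tn fn):", x$tp, x$fp, x$tn, x$fn, "\n")
  if (x$n_boot_skipped > 0)
    cat("  single-class bootstrap replicates skipped:", x$n_boot_skipped, "\n")
  invisible(x)
}
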