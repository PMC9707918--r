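# Agreement and diagnostic-accuracy statistics comparing virtual FFR with
# invasively measured FFR. The measured value is always the reference
# standard; a lesion is physiologically significant when FFR <= 0.80.

#' Dichotomise FFR at the treatment threshold
#'
#' Positive (significant) if and only if the value is less than or equal
#' to the threshold; the threshold itself is positive.
#'
#' @param ffr numeric vector of FFR values.
#' @param threshold decision threshold (default 0.80).
#' @return logical vector, `TRUE` = physiologically significant.
#' @export
classify_ffr <- function(ffr, threshold = 0.80) {
  if (any(!is.finite(ffr))) stop("non-finite FFR value(s)")
  ffr <= threshold
}

#' 2x2 diagnostic performance of vFFR against measured FFR
#'
#' @param vffr computed (virtual) FFR values.
#' @param ffr_measured invasively measured FFR values (reference).
#' @param threshold decision threshold applied to both (default 0.80).
#' @return list with `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, and the 2x2 counts (`tp`, `fp`, `fn`, `tn`). Rates with a
#'   zero denominator are `NA`, not 0.
#' @export
diagnostic_table <- function(vffr, ffr_measured, threshold = 0.80) {
  if (length(vffr) != length(ffr_measured)) stop("length mismatch")
  if (length(vffr) == 0L) stop("empty input")
  truth <- classify_ffr(ffr_measured, threshold)
  test <- classify_ffr(vffr, threshold)
  tp <- sum(test & truth); fp <- sum(test & !truth)
  fn <- sum(!test & truth); tn <- sum(!test & !truth)
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  list(sensitivity = rate(tp, tp + fn),
       specificity = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp),
       npv = rate(tn, tn + fn),
       accuracy = (tp + tn) / length(vffr),
       tp = tp, fp = fp, fn = fn, tn = tn)
}

#' ROC area under the curve (Mann-Whitney form)
#'
#' AUC as the probability that a randomly chosen positive case scores
#' higher than a randomly chosen negative case, with half credit for
#' ties -- computed from rank sums, equivalent to averaging pairwise
#' concordance over all positive x negative pairs.
#'
#' For discriminating low FFR, pass `scores = -vffr` so that more severe
#' (lower) vFFR ranks higher.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels logical (or 0/1) true class labels.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks give ties half credit
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bland-Altman agreement analysis
#'
#' Differences are `vffr - ffr_measured`; the bias is their mean and the
#' limits of agreement lie `loa_factor` sample standard deviations either
#' side of the bias. The default factor 1.96 gives the usual 95% limits; a
#' factor of 2 ("2 SD") is a common rounding of the same convention.
#'
#' @param vffr computed FFR values.
#' @param ffr_measured measured FFR values.
#' @param loa_factor multiple of the SD defining the limits (default 1.96).
#' @return list with `bias`, `sd`, `loa` (lower, upper), `mean_abs_error`,
#'   `r` (Pearson correlation), `n`.
#' @export
bland_altman <- function(vffr, ffr_measured, loa_factor = 1.96) {
  if (length(vffr) != length(ffr_measured)) stop("length mismatch")
  if (length(vffr) < 2L) stop("need at least two paired values")
  delta <- vffr - ffr_measured
  bias <- mean(delta)
  s <- stats::sd(delta)
  list(bias = bias, sd = s,
       loa = c(lower = bias - loa_factor * s, upper = bias + loa_factor * s),
       mean_abs_error = mean(abs(delta)),
       r = stats::cor(vffr, ffr_measured),
       n = length(delta))
}

#' Diagnostic accuracy across the vFFR range
#'
#' Groups records into bins of the computed vFFR value and reports the
#' per-bin diagnostic accuracy against measured FFR: classification is
#' hardest, and accuracy lowest, in bins near the 0.80 threshold. Empty
#' bins are reported as `NA`, not zero.
#'
#' @param vffr,ffr_measured paired FFR values.
#' @param threshold decision threshold (default 0.80).
#' @param breaks increasing bin edges covering the data (default 0 to 1
#'   in steps of 0.1); bins are left-open, right-closed.
#' @return data.frame with `bin_center`, `accuracy`, `n`.
#' @export
accuracy_curve <- function(vffr, ffr_measured, threshold = 0.80,
                           breaks = seq(0, 1, by = 0.1)) {
  if (length(vffr) != length(ffr_measured)) stop("length mismatch")
  if (is.unsorted(breaks, strictly = TRUE))
    stop("breaks must be strictly increasing (bins must not overlap)")
  correct <- classify_ffr(vffr, threshold) == classify_ffr(ffr_measured, threshold)
  bin <- cut(vffr, breaks, include.lowest = TRUE)
  acc <- tapply(correct, bin, mean)
  n <- tapply(correct, bin, length)
  data.frame(bin_center = (breaks[-length(breaks)] + breaks[-1]) / 2,
             accuracy = as.numeric(acc),
             n = ifelse(is.na(n), 0L, as.integer(n)),
             row.names = NULL)
}

#' Full agreement/diagnostic report for one model variant
#'
#' Bundles [bland_altman()], [diagnostic_table()], [roc_auc()] (scores
#' `-vffr` against measured significance) and [accuracy_curve()] into one
#' report comparing a vector of computed vFFR values to measured FFR.
#'
#' @inheritParams bland_altman
#' @param threshold decision threshold (default 0.80).
#' @param loa_factor limits-of-agreement factor (default 1.96).
#' @param curve_breaks bin edges for the accuracy curve.
#' @return object of class `diagnostic_report`.
#' @export
diagnostic_report <- function(vffr, ffr_measured, threshold = 0.80,
                              loa_factor = 1.96,
                              curve_breaks = seq(0, 1, by = 0.1)) {
  ba <- bland_altman(vffr, ffr_measured, loa_factor)
  dt <- diagnostic_table(vffr, ffr_measured, threshold)
  truth <- classify_ffr(ffr_measured, threshold)
  auc <- if (any(truth) && any(!truth)) roc_auc(-vffr, truth) else NA_real_
  structure(list(n = length(vffr),
                 bias = ba$bias, sd_delta = ba$sd, loa = ba$loa,
                 mean_abs_error = ba$mean_abs_error, r = ba$r,
                 sensitivity = dt$sensitivity, specificity = dt$specificity,
                 ppv = dt$ppv, npv = dt$npv, accuracy = dt$accuracy,
                 auc = auc,
                 curve = accuracy_curve(vffr, ffr_measured, threshold,
                                        curve_breaks),
                 threshold = threshold),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  cat(sprintf("vFFR vs measured FFR (n = %d, threshold %.2f)\n", x$n, x$threshold))
  cat(sprintf("  bias %+.3f, LoA [%.3f, %.3f], MAE %.3f, r %.2f\n",
              x$bias, x$loa[1], x$loa[2], x$mean_abs_error, x$r))
  cat(sprintf("  accuracy %.0f%%, sens %.0f%%, spec %.0f%%, PPV %.0f%%, NPV %.0f%%, AUC %.2f\n",
              100 * x$accuracy, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$ppv, 100 * x$npv, x$auc))
  invisible(x)
}

# flat single-row view used by the report writers
.report_row <- function(report) {
  data.frame(n = report$n, bias = report$bias, sd_delta = report$sd_delta,
             loa_lower = report$loa[[1]], loa_upper = report$loa[[2]],
             mean_abs_error = report$mean_abs_error, r = report$r,
             sensitivity = report$sensitivity, specificity = report$specificity,
             ppv = report$ppv, npv = report$npv, accuracy = report$accuracy,
             auc = report$auc)
}
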