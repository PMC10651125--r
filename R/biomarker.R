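#' Peak intensity in a wavenumber window
#'
#' Maximum intensity within `center +/- half_window` cm^-1. On an exact tie
#' the value at the lower wavenumber is taken. Intended for
#' baseline-corrected spectra; an integral mode (`mode = "integral"`,
#' trapezoid over the window) is provided as an alternative summary.
#'
#' @param spectrum A `"raman_spectrum"`.
#' @param center Band centre (cm^-1).
#' @param half_window Half window width (cm^-1). Default 10.
#' @param mode `"max"` (default) or `"integral"`.
#' @return Scalar intensity.
#' @export
peak_intensity <- function(spectrum, center, half_window = 10,
                           mode = c("max", "integral")) {
  mode <- match.arg(mode)
  stopifnot(inherits(spectrum, "raman_spectrum"))
  keep <- abs(spectrum$wavenumber - center) <= half_window
  if (!any(keep))
    stop("window [", center - half_window, ", ", center + half_window,
         "] does not intersect the axis", call. = FALSE)
  if (mode == "integral") {
    if (sum(keep) < 2) stop("integral mode needs >= 2 window channels",
                            call. = FALSE)
    return(trapz_integral(spectrum$wavenumber[keep],
                          spectrum$intensity[keep]))
  }
  max(spectrum$intensity[keep])  # which.max would give the same (lowest) tie
}

#' TBI barcode features of a spectrum
#'
#' Extracts the six diagnostic peak intensities (defaults: 1266, 1452, 1660,
#' 2850, 2880, 2930 cm^-1; 2955 is a drop-in alternate) and the
#' I(2930)/I(2850) peak ratio — the headline discriminant of injured versus
#' control retina. The ratio is invariant to global intensity scaling.
#'
#' @param spectrum A `"raman_spectrum"` covering all feature bands,
#'   baseline-corrected.
#' @param bands Feature band centres (cm^-1).
#' @param half_window Peak window half width (cm^-1). Default 10.
#' @return A `"barcode_features"` list: named `peaks` and `ratio`.
#' @export
barcode <- function(spectrum, bands = c(1266, 1452, 1660, 2850, 2880, 2930),
                    half_window = 10) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  lo <- min(spectrum$wavenumber); hi <- max(spectrum$wavenumber)
  missing <- bands[bands - half_window < lo | bands + half_window > hi]
  if (length(missing))
    stop("spectrum does not cover feature band(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  peaks <- vapply(bands, function(b)
    peak_intensity(spectrum, b, half_window), numeric(1))
  names(peaks) <- paste0("I", bands)
  i2930 <- peak_intensity(spectrum, 2930, half_window)
  i2850 <- peak_intensity(spectrum, 2850, half_window)
  if (i2850 <= 0)
    stop("2850 cm^-1 peak intensity is nonpositive; ratio undefined",
         call. = FALSE)
  structure(list(peaks = peaks, ratio = i2930 / i2850),
            class = "barcode_features")
}

#' @export
print.barcode_features <- function(x, ...) {
  cat("Barcode features:\n")
  print(round(x$peaks, 5))
  cat("2930/2850 ratio: ", format(x$ratio, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Box-plot summary of a sample
#'
#' Quartiles by linear interpolation of order statistics (type-7
#' convention); whiskers at `Q1 - 1.5 IQR` and `Q3 + 1.5 IQR` clipped to
#' the data extremes; values strictly beyond the whiskers are outliers.
#'
#' @param values Numeric vector, length >= 4.
#' @return A `"boxplot_summary"` list: `median`, `q1`, `q3`, `iqr`,
#'   `whisker_lo`, `whisker_hi`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 4) stop("need >= 4 values", call. = FALSE)
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  wlo <- max(min(values), q[1] - 1.5 * iqr)
  whi <- min(max(values), q[3] + 1.5 * iqr)
  structure(list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
                 whisker_lo = wlo, whisker_hi = whi,
                 outliers = values[values < wlo | values > whi]),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat("median ", format(x$median, digits = 5),
      ", IQR ", format(x$iqr, digits = 5),
      " [Q1 ", format(x$q1, digits = 5), ", Q3 ", format(x$q3, digits = 5),
      "], whiskers [", format(x$whisker_lo, digits = 5), ", ",
      format(x$whisker_hi, digits = 5), "], ",
      length(x$outliers), " outlier(s)\n", sep = "")
  invisible(x)
}

#' Nonparametric ROC curve and AUC
#'
#' Sweeps a decision threshold over the unique score values (predicting
#' positive when `score >= threshold`) to produce the
#' sensitivity-specificity pairs, and computes the area under the curve two
#' ways: by the Mann-Whitney U statistic with ties contributing 1/2, and by
#' trapezoidal integration of the swept curve. The two agree to numerical
#' precision by construction; both are returned so the identity is
#' assertable.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Class labels.
#' @param positive The positive-class label. Default: last sorted label.
#' @return A `"roc_result"`: data frame `curve` (threshold, sensitivity,
#'   specificity), `auc` (U-based), `auc_trapezoid`, `n_pos`, `n_neg`.
#' @export
roc_auc <- function(scores, labels, positive = NULL) {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  stopifnot(length(scores) == length(labels))
  classes <- sort(unique(labels))
  if (is.null(positive)) positive <- classes[length(classes)]
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("need at least one positive and one negative", call. = FALSE)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- spec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred_pos <- scores >= thr[i]
    sens[i] <- sum(pred_pos & pos) / n_pos
    spec[i] <- sum(!pred_pos & !pos) / n_neg
  }
  fpr <- 1 - spec
  auc_trap <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  r <- rank(scores)  # average ranks handle ties with weight 1/2
  u <- sum(r[pos]) - n_pos * (n_pos + 1) / 2
  auc_u <- u / (n_pos * n_neg)
  structure(list(curve = data.frame(threshold = thr, sensitivity = sens,
                                    specificity = spec),
                 auc = auc_u, auc_trapezoid = auc_trap,
                 n_pos = n_pos, n_neg = n_neg, positive = positive),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("ROC: ", x$n_pos, " positive (", x$positive, ") vs ", x$n_neg,
      " negative; AUC = ", format(x$auc, digits = 5), "\n", sep = "")
  invisible(x)
}

#' Plot an ROC curve
#' @param x A `"roc_result"`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(1 - x$curve$specificity, x$curve$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  graphics::legend("bottomright",
                   legend = paste0("AUC = ", format(x$auc, digits = 4)),
                   bty = "n")
  invisible(x)
}

#' Diagnostic metrics from a 2x2 confusion matrix
#'
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/(TP+TN+FN+FP). A metric with a zero denominator is
#' flagged undefined (returned as NA with its name listed in `undefined`)
#' rather than silently propagating NaN.
#'
#' @param cm 2x2 counts matrix, rows = true class, columns = predicted,
#'   with the positive class identified by `positive` (a row/col name) or
#'   taken as the second row.
#' @param positive Positive-class name. Default: second row name.
#' @return List: `sensitivity`, `specificity`, `accuracy`, `undefined`.
#' @export
confusion_metrics <- function(cm, positive = NULL) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(2, 2))) stop("need a 2x2 matrix", call. = FALSE)
  if (any(cm < 0)) stop("negative counts", call. = FALSE)
  cls <- rownames(cm) %||% c("negative", "positive")
  if (is.null(positive)) positive <- cls[2]
  p <- match(positive, cls)
  if (is.na(p)) stop("unknown positive class: ", positive, call. = FALSE)
  n <- 3 - p
  tp <- cm[p, p]; fn <- cm[p, n]; tn <- cm[n, n]; fp <- cm[n, p]
  undefined <- character(0)
  sens <- if (tp + fn == 0) { undefined <- c(undefined, "sensitivity"); NA_real_
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { undefined <- c(undefined, "specificity"); NA_real_
  } else tn / (tn + fp)
  acc <- if (sum(cm) == 0) { undefined <- c(undefined, "accuracy"); NA_real_
  } else (tp + tn) / sum(cm)
  list(sensitivity = sens, specificity = spec, accuracy = acc,
       undefined = undefined)
}
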