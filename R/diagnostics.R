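#' Diagnostic-test evaluation of a binary prediction
#'
#' Cross-tabulates a predicted LVSI status against the pathological truth
#' and derives the five standard diagnostic proportions:
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), PPV = TP/(TP+FP),
#' NPV = TN/(TN+FN), accuracy = (TP+TN)/(TP+FP+FN+TN). A metric with a zero
#' denominator is `NA` and listed in the `undefined` field — never silently
#' zero.
#'
#' @param predicted,truth `"positive"`/`"negative"` character vectors (or
#'   logical, `TRUE` = positive) over the same samples; when named, samples
#'   are matched by name and the sets must coincide.
#' @return An object of class `"confusion_metrics"`: list with counts `tp`,
#'   `fp`, `fn`, `tn`, the five metrics, and `undefined` (names of metrics
#'   with zero denominator).
#' @examples
#' cm <- confusion_from_counts(tp = 24, fp = 23, fn = 2, tn = 39)
#' cm$sensitivity
#' @export
confusion <- function(predicted, truth) {
  p <- as_binary(predicted, "predicted")
  t <- as_binary(truth, "truth")
  if (!is.null(names(p)) && !is.null(names(t))) {
    if (!setequal(names(p), names(t)))
      stop("predicted and truth cover different sample sets")
    t <- t[names(p)]
  } else if (length(p) != length(t)) {
    stop("predicted and truth must cover the same samples")
  }
  confusion_from_counts(tp = sum(p & t), fp = sum(p & !t),
                        fn = sum(!p & t), tn = sum(!p & !t))
}

as_binary <- function(x, what) {
  if (is.logical(x)) return(x)
  if (!all(x %in% c("positive", "negative")))
    stop("`", what, "` must be 'positive'/'negative' or logical")
  stats::setNames(x == "positive", names(x))
}

#' @rdname confusion
#' @param tp,fp,fn,tn non-negative integer counts of true positives, false
#'   positives, false negatives and true negatives.
#' @export
confusion_from_counts <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  m <- list(tp = tp, fp = fp, fn = fn, tn = tn,
            sensitivity = ratio(tp, tp + fn),
            specificity = ratio(tn, tn + fp),
            ppv = ratio(tp, tp + fp),
            npv = ratio(tn, tn + fn),
            accuracy = ratio(tp + tn, tp + fp + fn + tn))
  m$undefined <- names(which(vapply(
    m[c("sensitivity", "specificity", "ppv", "npv", "accuracy")],
    is.na, logical(1))))
  structure(m, class = "confusion_metrics")
}

#' @export
print.confusion_metrics <- function(x, ...) {
  cat("          truth+  truth-\n")
  cat(sprintf("pred A  %6d  %6d\n", x$tp, x$fp))
  cat(sprintf("pred B  %6d  %6d\n", x$fn, x$tn))
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    cat(sprintf("%-12s %s\n", nm, format_percent(x[[nm]])))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Format a proportion as a one-decimal percentage
#'
#' Report-style formatting (92.3% and the like); internal values stay exact
#' fractions.
#'
#' @param p proportion in `[0, 1]` or `NA`.
#' @return Character scalar such as `"92.3%"`, or `"undefined"` for `NA`.
#' @export
format_percent <- function(p) {
  if (is.na(p)) "undefined" else sprintf("%.1f%%", 100 * p)
}

#' Incidence of a binary outcome in a subset
#'
#' @param labels `"positive"`/`"negative"` character or logical vector.
#' @param subset optional logical or index vector restricting the samples
#'   (e.g. early-stage only); the subset must be non-empty.
#' @return Proportion of positives.
#' @examples
#' incidence(rep(c("positive", "negative"), c(26, 62)))  # 26/88
#' @export
incidence <- function(labels, subset = NULL) {
  lab <- as_binary(labels, "labels")
  if (!is.null(subset)) lab <- lab[subset]
  if (length(lab) == 0L) stop("empty subset")
  mean(lab)
}

#' Write a diagnostic performance report
#'
#' Tab-delimited 2x2 cross-tabulation plus the metric block, percentages at
#' one decimal.
#'
#' @param cm a `"confusion_metrics"` object.
#' @param path output path.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_diagnostics_report <- function(cm, path, header = NULL) {
  stopifnot(inherits(cm, "confusion_metrics"))
  lines <- c(
    if (length(header)) paste0("# ", header),
    "clustering\tLVSI-positive\tLVSI-negative\tmetric",
    sprintf("group_A\t%d\t%d\tPPV %s", cm$tp, cm$fp, format_percent(cm$ppv)),
    sprintf("group_B\t%d\t%d\tNPV %s", cm$fn, cm$tn, format_percent(cm$npv)),
    sprintf("\tsensitivity %s\tspecificity %s\taccuracy %s",
            format_percent(cm$sensitivity), format_percent(cm$specificity),
            format_percent(cm$accuracy))
  )
  writeLines(lines, path)
  invisible(path)
}
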