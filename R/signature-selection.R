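#' Parameters of the three-stage gene selection procedure
#'
#' The signature is selected by composing three per-gene filters, in order:
#'
#' 1. **Detection filter** — a gene is excluded when its below-detection
#'    fraction exceeds `max_missing_frac_pos` among LVSI-positive samples
#'    *or* `max_missing_frac_neg` among LVSI-negative samples (strict `>`).
#'    At the reference design (26 positive / 62 negative) and fractions of
#'    0.25 this reproduces the absolute exclusion rules "7 or more of 26"
#'    and "16 or more of 62" exactly, while generalising to other sample
#'    sizes.
#' 2. **Mean-difference filter** — the difference of detected-value class
#'    means, positive minus negative, must be at least `min_mean_diff` log2
#'    units. With `signed = TRUE` (the default, matching the original rule)
#'    only up-shifts in the positive class qualify; with `signed = FALSE`
#'    the absolute difference is used.
#' 3. **t-test filter** — a two-sided two-sample Student t test on the
#'    detected values must give `p < alpha` (strict). The default is the
#'    pooled-variance (equal-variance) statistic, which is what "Student's
#'    t test" denotes; Welch is available via `var_equal = FALSE`.
#'
#' @param max_missing_frac_pos,max_missing_frac_neg maximum tolerated
#'   below-detection fraction per class, in `[0, 1)`; exceeding either
#'   (strictly) excludes the gene.
#' @param min_mean_diff minimum class mean difference, log2 units (>= 0).
#' @param alpha p-value threshold, in (0, 1).
#' @param signed if `TRUE`, only positive mean differences pass the filter.
#' @param var_equal if `TRUE`, pooled-variance t test; otherwise Welch.
#' @return An object of class `"selection_params"`.
#' @export
selection_params <- function(max_missing_frac_pos = 0.25,
                             max_missing_frac_neg = 0.25,
                             min_mean_diff = 1, alpha = 0.005,
                             signed = TRUE, var_equal = TRUE) {
  stopifnot(max_missing_frac_pos >= 0, max_missing_frac_pos < 1,
            max_missing_frac_neg >= 0, max_missing_frac_neg < 1,
            min_mean_diff >= 0, alpha > 0, alpha < 1,
            is.logical(signed), is.logical(var_equal))
  structure(list(max_missing_frac_pos = max_missing_frac_pos,
                 max_missing_frac_neg = max_missing_frac_neg,
                 min_mean_diff = min_mean_diff, alpha = alpha,
                 signed = signed, var_equal = var_equal),
            class = "selection_params")
}

# Per-gene detected counts, means and variances by class, vectorised over
# genes. Masked cells contribute nothing (complete-case per gene).
.class_stats <- function(x, pos) {
  stopifnot(inherits(x, "expr_matrix"))
  if (!any(pos) || all(pos)) stop("both LVSI classes must be non-empty")
  det <- !x$below_detection
  v <- x$values
  v[!det] <- 0
  stats_for <- function(cols) {
    n <- rowSums(det[, cols, drop = FALSE])
    s <- rowSums(v[, cols, drop = FALSE])
    ss <- rowSums(v[, cols, drop = FALSE]^2)
    m <- ifelse(n > 0, s / n, NA_real_)
    va <- ifelse(n > 1, (ss - n * m^2) / (n - 1), NA_real_)
    va <- pmax(va, 0)  # guard tiny negative values from cancellation
    list(n = n, mean = m, var = va)
  }
  list(pos = stats_for(which(pos)), neg = stats_for(which(!pos)))
}

#' Detection filter
#'
#' Flags genes whose below-detection fraction stays within the tolerated
#' fraction in both classes. See [selection_params()] for the rule.
#'
#' @param x an [expr_matrix].
#' @param labels LVSI labels: a sample annotation `data.frame`, a
#'   `"positive"`/`"negative"` character vector, or a logical vector
#'   (`TRUE` = positive), aligned with the samples of `x`.
#' @param params a [selection_params()].
#' @return Named logical vector, `TRUE` for retained genes.
#' @export
detection_filter <- function(x, labels, params = selection_params()) {
  pos <- lvsi_logical(labels, x)
  if (!any(pos) || all(pos)) stop("both LVSI classes must be non-empty")
  below <- x$below_detection
  frac_pos <- rowMeans(below[, pos, drop = FALSE])
  frac_neg <- rowMeans(below[, !pos, drop = FALSE])
  keep <- !(frac_pos > params$max_missing_frac_pos |
              frac_neg > params$max_missing_frac_neg)
  stats::setNames(keep, gene_ids(x))
}

#' Class means and the mean-difference filter
#'
#' Computes per-gene detected-value means in each class and flags genes
#' whose positive-minus-negative mean difference reaches `min_mean_diff`
#' (signed by default).
#'
#' @inheritParams detection_filter
#' @return A `data.frame` with columns `gene_id`, `mean_pos`, `mean_neg`,
#'   `mean_diff`, `passed_diff`.
#' @export
mean_diff_filter <- function(x, labels, params = selection_params()) {
  pos <- lvsi_logical(labels, x)
  cs <- .class_stats(x, pos)
  diff <- cs$pos$mean - cs$neg$mean
  eff <- if (params$signed) diff else abs(diff)
  data.frame(gene_id = gene_ids(x),
             mean_pos = cs$pos$mean, mean_neg = cs$neg$mean,
             mean_diff = diff,
             passed_diff = !is.na(eff) & eff >= params$min_mean_diff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene two-sample t test on detected values
#'
#' Pooled-variance (or Welch) two-sided t test of positive vs negative
#' class, per gene, using detected values only. A gene with fewer than two
#' detected values in either class is untestable (`NA` statistic and
#' p-value, never selected). When both class variances are zero the
#' statistic degenerates: an exact mean tie gives `t = 0, p = 1`; any mean
#' difference gives `t = +/-Inf, p = 0`.
#'
#' @inheritParams detection_filter
#' @return A `data.frame` with columns `gene_id`, `n_detected_pos`,
#'   `n_detected_neg`, `t_stat`, `p_value`, `passed_test`.
#' @export
two_sample_t <- function(x, labels, params = selection_params()) {
  pos <- lvsi_logical(labels, x)
  cs <- .class_stats(x, pos)
  n1 <- cs$pos$n; n2 <- cs$neg$n
  m1 <- cs$pos$mean; m2 <- cs$neg$mean
  v1 <- cs$pos$var; v2 <- cs$neg$var
  testable <- n1 >= 2 & n2 >= 2
  diff <- m1 - m2
  if (params$var_equal) {
    df <- n1 + n2 - 2
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    a <- v1 / n1; b <- v2 / n2
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (n1 - 1) + b^2 / (n2 - 1))
  }
  t <- diff / se
  # zero-variance degeneracies: tied means -> t = 0; separated means -> Inf
  zero_se <- testable & !is.na(se) & se == 0
  t[zero_se & diff == 0] <- 0
  t[zero_se & diff != 0] <- sign(diff[zero_se & diff != 0]) * Inf
  p <- 2 * stats::pt(-abs(t), df)
  p[zero_se & diff == 0] <- 1
  p[zero_se & diff != 0] <- 0
  t[!testable] <- NA_real_
  p[!testable] <- NA_real_
  data.frame(gene_id = gene_ids(x),
             n_detected_pos = n1, n_detected_neg = n2,
             t_stat = t, p_value = p,
             passed_test = !is.na(p) & p < params$alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the gene signature
#'
#' Applies the three filters of [selection_params()] in order (detection,
#' mean difference, t test) and returns the full per-gene table together
#' with the ordered signature: selected genes sorted by ascending p-value,
#' ties broken by gene id.
#'
#' @inheritParams detection_filter
#' @return An object of class `"selection_result"`: a `data.frame` with one
#'   row per gene (`gene_id`, detected counts, class means, `mean_diff`,
#'   `t_stat`, `p_value`, the three filter flags, `selected`) carrying the
#'   signature in `attr(, "signature")` and the parameters in
#'   `attr(, "params")`.
#' @examples
#' ds <- simulate_expression(sim_config(n_genes = 300, n_signature = 20))
#' sel <- select_signature(ds$expression, ds$samples)
#' head(signature_genes(sel))
#' @export
select_signature <- function(x, labels, params = selection_params()) {
  passed_detection <- detection_filter(x, labels, params)
  md <- mean_diff_filter(x, labels, params)
  tt <- two_sample_t(x, labels, params)
  res <- data.frame(gene_id = md$gene_id,
                    n_detected_pos = tt$n_detected_pos,
                    n_detected_neg = tt$n_detected_neg,
                    mean_pos = md$mean_pos, mean_neg = md$mean_neg,
                    mean_diff = md$mean_diff,
                    t_stat = tt$t_stat, p_value = tt$p_value,
                    passed_detection = unname(passed_detection),
                    passed_diff = md$passed_diff,
                    passed_test = tt$passed_test,
                    stringsAsFactors = FALSE, row.names = NULL)
  res$selected <- res$passed_detection & res$passed_diff & res$passed_test
  sel <- res[res$selected, c("gene_id", "p_value")]
  sig <- sel$gene_id[order(sel$p_value, sel$gene_id)]
  structure(res, signature = sig, params = params,
            class = c("selection_result", "data.frame"))
}

#' Signature genes of a selection result
#'
#' @param result a `"selection_result"` from [select_signature()].
#' @return Character vector of selected gene ids, ordered by ascending
#'   p-value then gene id.
#' @export
signature_genes <- function(result) {
  stopifnot(inherits(result, "selection_result"))
  attr(result, "signature")
}

#' @export
print.selection_result <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf(paste0("selection_result: %d genes; %d passed detection, ",
                     "%d passed mean-diff (>= %g), %d passed t test ",
                     "(p < %g); %d selected\n"),
              nrow(x), sum(x$passed_detection), sum(x$passed_diff),
              p$min_mean_diff, sum(x$passed_test), p$alpha,
              sum(x$selected)))
  invisible(x)
}

#' Write a selection result and its signature list
#'
#' The per-gene table goes to a tab-delimited file; the signature to a
#' plain-text file with one gene id per line.
#'
#' @param result a `"selection_result"`.
#' @param table_path,signature_path output file paths (`NULL` skips one).
#' @param header optional comment lines for both files.
#' @return Invisibly, the paths written.
#' @export
write_selection <- function(result, table_path = NULL, signature_path = NULL,
                            header = NULL) {
  stopifnot(inherits(result, "selection_result"))
  if (!is.null(table_path)) {
    con <- file(table_path, "w")
    if (length(header)) writeLines(paste0("# ", header), con)
    utils::write.table(as.data.frame(result), con, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(signature_path)) {
    writeLines(c(if (length(header)) paste0("# ", header),
                 signature_genes(result)), signature_path)
  }
  invisible(c(table_path, signature_path))
}
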