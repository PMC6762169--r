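#' Fisher exact test on a 2x2 table
#'
#' Two-sided p-value under the conditional hypergeometric model: the sum of
#' the probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table (the convention
#' of mainstream statistical software). A table with a zero row or column
#' margin admits only itself, so its p-value is 1.
#'
#' @param a,b,c,d non-negative counts; rows are the covariate levels,
#'   columns LVSI-positive / LVSI-negative. Alternatively pass a 2x2 matrix
#'   as `a`.
#' @return List with `p_value`, `odds_ratio` (conditional MLE, `NA` for
#'   degenerate tables) and the table.
#' @examples
#' fisher_exact(9, 50, 17, 12)$p_value  # stage I/II vs III/IV by LVSI
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL) {
  tab <- if (is.matrix(a)) a else matrix(c(a, c, b, d), 2L, 2L)
  if (!identical(dim(tab), c(2L, 2L)))
    stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (sum(tab) == 0L) stop("empty table")
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L))
    return(list(p_value = 1, odds_ratio = NA_real_, table = tab))
  ft <- stats::fisher.test(tab)
  list(p_value = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two continuous samples (age, BMI, ...). The exact
#' distribution is used when both samples have at most 20 observations and
#' there are no ties; otherwise the normal approximation with continuity
#' and tie correction.
#'
#' @param x,y numeric vectors, both non-empty.
#' @return List with `U` (the Mann-Whitney statistic for `x`), `p_value`
#'   (two-sided) and `exact` (whether the exact distribution was used).
#' @export
mann_whitney <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- length(x) <= 20L && length(y) <= 20L && !ties
  wt <- stats::wilcox.test(x, y, exact = exact, correct = TRUE)
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Kaplan-Meier curves with a log-rank test
#'
#' Product-limit survival estimate per group and the two-group log-rank
#' chi-square test (1 df). When no events occur in either group the curves
#' are flat at 1 and the log-rank statistic is undefined; this is flagged
#' rather than reported as a number.
#'
#' @param time follow-up times, months, `>= 0`.
#' @param event event indicator: logical, 0/1, or `"death"`/`"censored"`.
#' @param group two-level grouping (e.g. LVSI status); both groups must be
#'   non-empty.
#' @return Object of class `"km_logrank"`: list with `curves` (data.frame:
#'   `group`, `time`, `n_risk`, `n_event`, `n_censor`, `surv`), `chisq`,
#'   `p_value` (`NA` with `undefined = TRUE` when no events), and `fit`
#'   (the underlying [survival::survfit] object).
#' @export
kaplan_meier <- function(time, event, group) {
  if (any(time < 0)) stop("negative survival time")
  ev <- if (is.character(event) || is.factor(event)) {
    if (!all(event %in% c("death", "censored")))
      stop("event must be 'death'/'censored', logical, or 0/1")
    as.integer(event == "death")
  } else as.integer(as.logical(event))
  g <- factor(group)
  if (nlevels(g) != 2L) stop("exactly two groups required")
  if (any(table(g) == 0L)) stop("a group has no subjects")
  fit <- survival::survfit(survival::Surv(time, ev) ~ g)
  sf <- summary(fit, censored = TRUE)
  curves <- data.frame(
    group = sub("^g=", "", as.character(sf$strata)),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    n_censor = sf$n.censor, surv = sf$surv,
    stringsAsFactors = FALSE)
  if (sum(ev) == 0L) {
    res <- list(curves = curves, chisq = NA_real_, p_value = NA_real_,
                undefined = TRUE, fit = fit)
  } else {
    sd <- survival::survdiff(survival::Surv(time, ev) ~ g)
    res <- list(curves = curves, chisq = unname(sd$chisq),
                p_value = stats::pchisq(sd$chisq, df = 1L,
                                        lower.tail = FALSE),
                undefined = FALSE, fit = fit)
  }
  structure(res, class = "km_logrank")
}

#' @export
print.km_logrank <- function(x, ...) {
  cat("Kaplan-Meier / log-rank:",
      if (x$undefined) "no events; log-rank undefined"
      else sprintf("chisq = %.3f (1 df), p = %.4g", x$chisq, x$p_value),
      "\n")
  invisible(x)
}

#' Plot Kaplan-Meier curves
#'
#' @param x a `"km_logrank"` object.
#' @param ... passed to `plot.survfit`.
#' @return `x`, invisibly.
#' @export
plot.km_logrank <- function(x, ...) {
  graphics::plot(x$fit, col = c("steelblue", "firebrick"), mark.time = TRUE,
                 xlab = "Months", ylab = "Overall survival", ...)
  groups <- sub("^g=", "", names(x$fit$strata))
  graphics::legend("bottomleft", legend = groups, bty = "n",
                   col = c("steelblue", "firebrick"), lty = 1)
  invisible(x)
}

#' Clinicopathological association table
#'
#' Rebuilds the usual characteristics table: Mann-Whitney p-values for the
#' continuous covariates (age, BMI) and Fisher exact p-values for each
#' two-level categorical covariate against LVSI status. Lymph-node
#' metastasis is tested on evaluated patients only (`not_evaluated`
#' excluded). A covariate column absent from `samples` is skipped.
#'
#' @param samples sample annotation `data.frame` with `lvsi` plus any of
#'   `age`, `bmi`, `stage`, `histology`, `grade`, `myoinvasion`,
#'   `ln_metastasis`, `recurrence`. Stage is collapsed to early (I/II) vs
#'   advanced (III/IV) and grade to 1 vs 2/3 when given at full resolution.
#' @return A `data.frame` with one row per covariate: `covariate`, `test`,
#'   the per-class summaries, and `p_value`.
#' @export
clinical_associations <- function(samples) {
  validate_sample_table(samples)
  pos <- samples$lvsi == "positive"
  rows <- list()
  num_row <- function(name, v) {
    mw <- mann_whitney(v[pos], v[!pos])
    data.frame(covariate = name, test = "mann_whitney",
               summary_pos = sprintf("%.1f±%.1f", mean(v[pos]), stats::sd(v[pos])),
               summary_neg = sprintf("%.1f±%.1f", mean(v[!pos]), stats::sd(v[!pos])),
               p_value = mw$p_value, stringsAsFactors = FALSE)
  }
  cat_row <- function(name, v, keep = rep(TRUE, length(v))) {
    v <- v[keep]; p <- pos[keep]
    lev <- sort(unique(v))
    if (length(lev) != 2L)
      stop("covariate '", name, "' must have exactly two levels, got: ",
           paste(lev, collapse = ", "))
    tab <- matrix(c(sum(v == lev[1] & p), sum(v == lev[1] & !p),
                    sum(v == lev[2] & p), sum(v == lev[2] & !p)),
                  2L, 2L, byrow = TRUE)
    fe <- fisher_exact(tab)
    data.frame(covariate = name, test = "fisher_exact",
               summary_pos = sprintf("%s %d / %s %d", lev[1], tab[1, 1], lev[2], tab[2, 1]),
               summary_neg = sprintf("%s %d / %s %d", lev[1], tab[1, 2], lev[2], tab[2, 2]),
               p_value = fe$p_value, stringsAsFactors = FALSE)
  }
  collapse <- function(v, map) {
    out <- v
    for (nm in names(map)) out[v %in% map[[nm]]] <- nm
    out
  }
  if ("age" %in% names(samples)) rows$age <- num_row("age", samples$age)
  if ("bmi" %in% names(samples)) rows$bmi <- num_row("bmi", samples$bmi)
  if ("stage" %in% names(samples))
    rows$stage <- cat_row("stage", collapse(samples$stage,
      list("I/II" = c("I", "II"), "III/IV" = c("III", "IV"))))
  if ("histology" %in% names(samples))
    rows$histology <- cat_row("histology", samples$histology)
  if ("grade" %in% names(samples))
    rows$grade <- cat_row("grade", collapse(as.character(samples$grade),
      list("1" = "1", "2/3" = c("2", "3"))))
  if ("myoinvasion" %in% names(samples))
    rows$myoinvasion <- cat_row("myoinvasion", samples$myoinvasion)
  if ("ln_metastasis" %in% names(samples))
    rows$ln_metastasis <- cat_row("ln_metastasis", samples$ln_metastasis,
                                  keep = samples$ln_metastasis != "not_evaluated")
  if ("recurrence" %in% names(samples))
    rows$recurrence <- cat_row("recurrence", samples$recurrence)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write the clinical association report and risk table
#'
#' @param assoc output of [clinical_associations()].
#' @param path output path (tab-delimited).
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_clinical_report <- function(assoc, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(assoc, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
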