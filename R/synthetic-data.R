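#' Simulation configuration for the synthetic study
#'
#' Describes a synthetic two-channel microarray experiment with the design of
#' the reference cohort: a fixed number of LVSI-positive and LVSI-negative
#' samples, a planted set of signature genes whose log2 ratios are shifted
#' upward in the positive class, Gaussian noise on the log2 scale, and
#' missing-at-random below-detection dropout.
#'
#' Defaults are the study conditions of the reference cohort: 26 positive vs
#' 62 negative samples and 55 planted genes; effect size 1.5 log2 units with
#' per-gene SD 0.5 and 5% dropout are the package's stated assumptions for a
#' selectable signature (the selection rule requires a class mean difference
#' of at least one log2 unit).
#'
#' @param n_pos,n_neg LVSI-positive / LVSI-negative sample counts (> 0).
#' @param n_genes total genes on the array (> 0).
#' @param n_signature planted differentially expressed genes (>= 0; zero
#'   yields pure null data for calibration studies).
#' @param effect_size mean log2-ratio shift of planted genes in the positive
#'   class.
#' @param noise_sd per-gene Gaussian SD of log2 ratios (> 0).
#' @param dropout_rate probability that any cell is below detection, in
#'   `[0, 1)`.
#' @param seed RNG seed; the same seed and configuration give bit-identical
#'   output.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_pos = 26L, n_neg = 62L, n_genes = 1000L,
                       n_signature = 55L, effect_size = 1.5,
                       noise_sd = 0.5, dropout_rate = 0.05, seed = 1L) {
  chk <- function(ok, field, msg) if (!isTRUE(ok)) stop("invalid `", field, "`: ", msg)
  chk(is.numeric(n_pos) && length(n_pos) == 1 && n_pos >= 1, "n_pos", "must be a positive count")
  chk(is.numeric(n_neg) && length(n_neg) == 1 && n_neg >= 1, "n_neg", "must be a positive count")
  chk(is.numeric(n_genes) && length(n_genes) == 1 && n_genes >= 1, "n_genes", "must be a positive count")
  chk(is.numeric(n_signature) && length(n_signature) == 1 && n_signature >= 0,
      "n_signature", "must be a non-negative count")
  chk(n_signature <= n_genes, "n_signature", "cannot exceed n_genes")
  chk(is.numeric(effect_size) && length(effect_size) == 1 && is.finite(effect_size),
      "effect_size", "must be a finite number")
  chk(is.numeric(noise_sd) && length(noise_sd) == 1 && noise_sd > 0, "noise_sd", "must be > 0")
  chk(is.numeric(dropout_rate) && length(dropout_rate) == 1 &&
        dropout_rate >= 0 && dropout_rate < 1, "dropout_rate", "must be in [0, 1)")
  chk(is.numeric(seed) && length(seed) == 1 && is.finite(seed), "seed", "must be a finite number")
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 n_genes = as.integer(n_genes),
                 n_signature = as.integer(n_signature),
                 effect_size = effect_size, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_pos, "positive +", x$n_neg, "negative samples,",
      x$n_genes, "genes (", x$n_signature, "planted ), effect",
      x$effect_size, ", sd", x$noise_sd, ", dropout", x$dropout_rate,
      ", seed", x$seed, "\n")
  invisible(x)
}

# Core generator, no seeding: callers control the RNG stream.
.simulate_expression <- function(config) {
  n <- config$n_pos + config$n_neg
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  samples <- c(sprintf("P%03d", seq_len(config$n_pos)),
               sprintf("N%03d", seq_len(config$n_neg)))
  lvsi <- rep(c("positive", "negative"), c(config$n_pos, config$n_neg))
  vals <- matrix(stats::rnorm(config$n_genes * n, 0, config$noise_sd),
                 config$n_genes, n, dimnames = list(genes, samples))
  truth <- sort(sample(genes, config$n_signature))
  vals[truth, lvsi == "positive"] <-
    vals[truth, lvsi == "positive"] + config$effect_size
  below <- matrix(stats::runif(config$n_genes * n) < config$dropout_rate,
                  config$n_genes, n, dimnames = list(genes, samples))
  list(expression = expr_matrix(vals, below),
       labels = stats::setNames(lvsi, samples),
       truth = truth)
}

#' Simulate a planted-signature expression matrix
#'
#' Background genes have class-independent mean 0; planted genes have mean
#' `effect_size` in the positive class and 0 in the negative class. All
#' values are Gaussian on the log2 scale. Every cell is independently masked
#' as below detection with probability `dropout_rate`; the underlying value
#' is kept in the matrix, so tests can vary dropout independently of signal.
#'
#' @param config a [sim_config()].
#' @return A list of class `"synthetic_dataset"` with elements `expression`
#'   (an [expr_matrix]), `samples` (annotation `data.frame` with `sample_id`
#'   and `lvsi`), and `truth` (planted gene ids).
#' @examples
#' ds <- simulate_expression(sim_config(n_genes = 200, n_signature = 10))
#' length(ds$truth)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  raw <- .simulate_expression(config)
  structure(list(expression = raw$expression,
                 samples = data.frame(sample_id = names(raw$labels),
                                      lvsi = unname(raw$labels),
                                      stringsAsFactors = FALSE),
                 truth = raw$truth),
            class = "synthetic_dataset")
}

#' Per-covariate 2x2 margins of the reference cohort
#'
#' Cross-tabulations of the clinicopathological covariates against LVSI
#' status in the 88-sample reference cohort (26 LVSI-positive, 62
#' LVSI-negative), used as the default target margins of
#' [simulate_clinical()]. Lymph-node metastasis carries a third
#' `not_evaluated` level for the eight patients without lymphadenectomy.
#' Recurrence counts are a package assumption (the cohort reports only that
#' the association is significant).
#'
#' @return A named list; each element is a list with integer vectors `pos`
#'   and `neg` giving per-level counts conditional on LVSI status.
#' @export
cohort_margins <- function() {
  list(
    stage = list(pos = c("I/II" = 9L, "III/IV" = 17L),
                 neg = c("I/II" = 50L, "III/IV" = 12L)),
    histology = list(pos = c(endometrioid = 22L, nonendometrioid = 4L),
                     neg = c(endometrioid = 56L, nonendometrioid = 6L)),
    grade = list(pos = c("1" = 6L, "2/3" = 20L),
                 neg = c("1" = 48L, "2/3" = 14L)),
    myoinvasion = list(pos = c("<50%" = 20L, ">=50%" = 6L),
                       neg = c("<50%" = 10L, ">=50%" = 52L)),
    ln_metastasis = list(pos = c(yes = 10L, no = 9L, not_evaluated = 7L),
                         neg = c(yes = 1L, no = 60L, not_evaluated = 1L)),
    recurrence = list(pos = c(yes = 9L, no = 17L),
                      neg = c(yes = 4L, no = 58L))
  )
}

#' Simulate the clinical annotation table
#'
#' Categorical covariates are allocated to match `margins` — exactly, in
#' deterministic mode (level blocks in sample order, then independently
#' permuted within class in random mode). Age and BMI are Gaussian per class.
#' Survival is exponential per class with hazard ratio `hazard_ratio` for the
#' LVSI-positive group and administrative censoring at `censor_horizon`
#' months.
#'
#' Defaults emulate the reference cohort: age 63±12.1 vs 57±13.1 years and
#' BMI 22.7±4.7 vs 27.0±9.3 kg/m² (positive vs negative); median survival of
#' 120 months for LVSI-negative patients, hazard ratio 3, and a 72-month
#' follow-up horizon are stated package assumptions.
#'
#' @param config a [sim_config()] (only the sample counts and seed are used).
#' @param margins per-covariate margins as produced by [cohort_margins()];
#'   each covariate's `pos`/`neg` counts must sum to `n_pos`/`n_neg`.
#' @param deterministic if `TRUE`, covariate levels are assigned in fixed
#'   blocks reproducing the margins exactly; if `FALSE`, the block assignment
#'   is randomly permuted within each class (margins still exact).
#' @param age_mean_sd,bmi_mean_sd lists with `pos`/`neg` c(mean, sd) pairs.
#' @param median_surv_neg median survival of the negative class, months.
#' @param hazard_ratio positive-class hazard ratio (1 = no survival
#'   difference).
#' @param censor_horizon administrative censoring time, months.
#' @return A sample annotation `data.frame` (one row per sample) with the
#'   columns of the annotation-table format.
#' @export
simulate_clinical <- function(config, margins = cohort_margins(),
                              deterministic = TRUE,
                              age_mean_sd = list(pos = c(63, 12.1), neg = c(57, 13.1)),
                              bmi_mean_sd = list(pos = c(22.7, 4.7), neg = c(27.0, 9.3)),
                              median_surv_neg = 120, hazard_ratio = 3,
                              censor_horizon = 72) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  .simulate_clinical(config, margins, deterministic, age_mean_sd, bmi_mean_sd,
                     median_surv_neg, hazard_ratio, censor_horizon)
}

.simulate_clinical <- function(config, margins, deterministic,
                               age_mean_sd, bmi_mean_sd,
                               median_surv_neg, hazard_ratio, censor_horizon) {
  n_pos <- config$n_pos; n_neg <- config$n_neg
  alloc <- function(counts, n, class) {
    if (sum(counts) != n)
      stop(sprintf("margins inconsistent: %s counts sum to %d, expected %d",
                   class, sum(counts), n))
    v <- rep(names(counts), counts)
    if (!deterministic) v <- sample(v)
    v
  }
  cov <- lapply(names(margins), function(nm) {
    m <- margins[[nm]]
    c(alloc(m$pos, n_pos, paste0(nm, " positive")),
      alloc(m$neg, n_neg, paste0(nm, " negative")))
  })
  names(cov) <- names(margins)
  rate_neg <- log(2) / median_surv_neg
  rate <- rep(c(rate_neg * hazard_ratio, rate_neg), c(n_pos, n_neg))
  t_event <- stats::rexp(n_pos + n_neg, rate)
  df <- data.frame(
    sample_id = c(sprintf("P%03d", seq_len(n_pos)),
                  sprintf("N%03d", seq_len(n_neg))),
    lvsi = rep(c("positive", "negative"), c(n_pos, n_neg)),
    age = round(c(stats::rnorm(n_pos, age_mean_sd$pos[1], age_mean_sd$pos[2]),
                  stats::rnorm(n_neg, age_mean_sd$neg[1], age_mean_sd$neg[2])), 1),
    bmi = round(c(stats::rnorm(n_pos, bmi_mean_sd$pos[1], bmi_mean_sd$pos[2]),
                  stats::rnorm(n_neg, bmi_mean_sd$neg[1], bmi_mean_sd$neg[2])), 1),
    stringsAsFactors = FALSE
  )
  for (nm in names(cov)) df[[nm]] <- cov[[nm]]
  df$surv_time <- pmin(t_event, censor_horizon)
  df$surv_event <- ifelse(t_event <= censor_horizon, "death", "censored")
  df
}

#' Simulate a complete synthetic dataset
#'
#' Combines [simulate_expression()] and [simulate_clinical()] under a single
#' RNG stream so that one seed fixes the whole dataset.
#'
#' @param config a [sim_config()].
#' @inheritParams simulate_clinical
#' @return A `"synthetic_dataset"` list: `expression`, `samples` (full
#'   clinical table), `truth`.
#' @export
simulate_dataset <- function(config, margins = cohort_margins(),
                             deterministic = TRUE,
                             age_mean_sd = list(pos = c(63, 12.1), neg = c(57, 13.1)),
                             bmi_mean_sd = list(pos = c(22.7, 4.7), neg = c(27.0, 9.3)),
                             median_surv_neg = 120, hazard_ratio = 3,
                             censor_horizon = 72) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  raw <- .simulate_expression(config)
  clin <- .simulate_clinical(config, margins, deterministic, age_mean_sd,
                             bmi_mean_sd, median_surv_neg, hazard_ratio,
                             censor_horizon)
  stopifnot(identical(clin$sample_id, sample_ids(raw$expression)))
  structure(list(expression = raw$expression, samples = clin,
                 truth = raw$truth),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic_dataset: %d genes x %d samples, %d planted genes\n",
              nrow(x$expression$values), ncol(x$expression$values),
              length(x$truth)))
  invisible(x)
}
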