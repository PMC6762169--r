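---
title: "Methods: the LVSI gene-signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the LVSI gene-signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvsisig)
```

## The problem and the model

Lymphovascular space invasion (LVSI) — tumour cells inside lymphatic or
blood vessels of the primary tumour — is a strong adverse prognostic factor
in endometrial cancer, but it is established only on the surgical specimen.
`lvsisig` implements a transcriptomic surrogate: a gene signature selected
from two-channel microarray log ratios that separates LVSI-positive from
LVSI-negative tumours, with the separation read off a hierarchical
clustering of the samples and evaluated as a diagnostic test.

All expression values are log ratios
$x_{gs} = \log_2(\text{Cy5}_{gs}/\text{Cy3}_{gs})$ of a sample channel over
a common-reference channel. Probes whose fluorescence falls under the
scanner's detection limit are carried as a boolean *below-detection* mask
and excluded from every mean, median, and test (complete-case per gene); no
imputation is done during selection, because the detection filter is
applied first and the design never states an imputation model.

### Normalisation contract

Array normalisation in the original workflow is internal to the scanner
software. The package replaces it with a minimal documented contract:
per-sample median centering of the detected log ratios
(`median_center()`), which is idempotent and leaves the mask untouched.
The synthetic generator produces data that is already centred in
expectation, so no pipeline conclusion hinges on this choice.

### Signature selection

`select_signature()` composes three per-gene filters, in this order:

1. **Detection filter.** A gene is excluded when its below-detection
   fraction exceeds 0.25 (strictly) among the positive samples *or* among
   the negative samples. At the study design of $n_+ = 26$ and $n_- = 62$
   this is exactly the absolute rule "7 or more of 26, or 16 or more of
   62"; stated as a strict fraction, the rule transfers to other sample
   sizes.
2. **Mean-difference filter.** The difference of detected-value class
   means, $\bar{x}_+ - \bar{x}_-$, must be $\ge 1$ log2 unit. The rule is
   *signed*: only genes up-shifted in the LVSI-positive class qualify
   (an unsigned variant is exposed via `signed = FALSE`).
3. **t-test filter.** A two-sided two-sample Student $t$ test on the
   detected values must reach $p < 0.005$ (strict). "Student's t test" is
   read as the pooled-variance statistic with $n_+ + n_- - 2$ degrees of
   freedom — that is what the name denotes; Welch is available through
   `var_equal = FALSE` but is not the default. No multiple-testing
   correction is applied: the fixed $p < 0.005$ cutoff *is* the rule.

Degenerate cases are pinned down explicitly: a gene with fewer than two
detected values in a class is untestable (`NA`, never selected); when both
class variances are zero, an exact mean tie gives $t = 0, p = 1$ and any
separation gives $t = \pm\infty, p = 0$. The signature is ordered by
ascending $p$, ties broken lexicographically by gene id, so output is
deterministic.

### Clustering as a classifier

Samples are clustered on their signature-gene vectors with Euclidean
distance and the dendrogram is cut at the root into exactly two groups —
the simplest reading of "divided into two groups". The linkage of the
original analysis software is unknown; the package defaults to **average
(UPGMA)**, the historical default of microarray clustering tools, with
complete, Ward (on Euclidean distances, i.e. `ward.D2`) and single
selectable, all covered by an exhaustive small-instance oracle in the test
suite. Residual below-detection cells among signature genes are imputed
with the gene's across-sample mean of detected values — Euclidean distance
needs complete vectors, and the detection filter caps per-class missingness
near 25%, so the perturbation is mild. Genes are not rescaled by default
(log ratios already share a scale); standardisation is exposed as an
option.

Group **A** is the cluster with the higher proportion of LVSI-positive
samples (ties: higher positive count, then the cluster containing the
first sample in input order) and is the "test-positive" call; group B
predicts negative. `confusion()` then derives sensitivity, specificity,
PPV, NPV and accuracy from the 2×2 cross-tabulation, with zero-denominator
metrics flagged `undefined` rather than silently zeroed. Reports format
percentages to one decimal; internal values stay exact fractions.

### Clinicopathological statistics

`clinical_associations()` reproduces the characteristics-table statistics:
Mann-Whitney U for age and BMI (exact distribution when both groups have
≤ 20 observations and no ties, otherwise the tie- and
continuity-corrected normal approximation — the study's 26/62 design is in
the approximate regime), and the Fisher exact test for the categorical
covariates, with the two-sided p defined by the "probability ≤ observed"
enumeration convention of mainstream statistical software. Lymph-node
metastasis is tested among evaluated patients only, reflecting the
patients without lymphadenectomy. Survival uses the Kaplan-Meier
product-limit estimator and the two-group log-rank test (1 df);
significance is read at $\alpha = 0.05$.

## The synthetic generator

No raw data accompanies the reference cohort, so a generator
(`simulate_dataset()`) defines the study conditions every test runs under:

* 26 LVSI-positive and 62 LVSI-negative samples; 55 planted signature
  genes among 1000.
* Background genes are Gaussian with mean 0 on the log2 scale in both
  classes; planted genes are shifted **upward only** in the positive class
  (matching the signed selection rule) by `effect_size`. The study states
  no distributional model; Gaussian log ratios with `effect_size = 1.5`
  and `noise_sd = 0.5` are the package's stated assumptions for a
  selectable signature ($\ge 1$ log2 unit with margin, per-gene power near
  1 at the design sizes).
* Below-detection dropout is missing-at-random at rate 0.05 per cell; the
  underlying value is generated and then masked, so tests can vary dropout
  independently of signal.
* Clinical covariates are allocated to per-covariate 2×2 margins
  (`cohort_margins()`), exactly in deterministic mode. The margins copy
  the reference cohort's characteristics table as printed, including its
  myometrial-invasion rows; the package reports whatever margins it is
  given and does not second-guess them. Recurrence counts (9/26 vs 4/62)
  are a package assumption — the cohort reports only that the association
  is significant. Age and BMI are Gaussian with the cohort's per-class
  mean ± SD.
* Survival is exponential per class with administrative censoring:
  median 120 months in the negative class, hazard ratio 3 for LVSI-positive,
  72-month horizon. These are assumptions chosen to give the qualitative
  picture (clearly worse survival with LVSI, moderate censoring); the
  source reports a survival figure but no numbers. The simple model is
  exactly what the log-rank power and null-uniformity checks need.

What the generator does **not** emulate: probe-level two-colour
intensities, dye bias, spatial artifacts, gene-gene correlation,
heavy-tailed noise, or class-dependent dropout. Passing tests therefore
show that the *procedure* is implemented correctly and calibrated under
its stated assumptions — not that the published 55-gene list or the
published confusion counts would be recovered from the real arrays, which
were never deposited.

## Numerical choices

* Filters use strict inequalities where the rules state them
  (`> 0.25` missingness, `p < 0.005`), and `>=` for the mean difference.
* The per-gene $t$ statistics are computed vectorised from masked sums;
  the suite checks them against `t.test()` per gene at $10^{-10}$
  relative tolerance.
* Matrix round-trips format doubles as `%.17g`, which reproduces every
  IEEE double bit-exactly on re-read.
* Cluster output, group labelling and signature ordering have documented
  deterministic tie-breaks, so a seed fixes every artifact byte-for-byte.

## Problem sizes used by the checks

The suite and the acceptance script run at the study design: the
calibration check uses $10^5$ pure-noise genes (nominal rate 0.005,
checked within 3 binomial SDs), recovery averages 20 generator seeds,
Fisher's test is compared with exhaustive enumeration on all 46,375 tables
with total ≤ 30, the clustering cut is compared with explicit
Lance-Williams agglomeration on 5-sample fixtures for all four linkages,
and the log-rank null uses 500 replicates.

## Limitations

* The real cohort's linkage, gene standardisation and array-system
  handling are unknown; the published confusion counts may depend on them.
  The package exposes the choices and fixes defaults rather than claiming
  to reproduce the unpublished configuration.
* The mean-difference filter plus $p$ cutoff is a fixed-rule selection with
  no error-rate control across genes; that is faithful to the procedure,
  not a recommendation.
* Diagnostic metrics are reported without confidence intervals, and no
  ROC analysis is possible because the cluster cut yields no continuous
  score.
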