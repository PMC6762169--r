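# Fixture at the reference design: 26 positive + 62 negative samples, with
# per-gene below-detection counts chosen per class.
detection_fixture <- function(counts_pos, counts_neg) {
  n_genes <- length(counts_pos)
  vals <- matrix(rnorm(n_genes * 88), n_genes, 88)
  below <- matrix(FALSE, n_genes, 88)
  for (g in seq_len(n_genes)) {
    if (counts_pos[g] > 0) below[g, seq_len(counts_pos[g])] <- TRUE
    if (counts_neg[g] > 0) below[g, 26 + seq_len(counts_neg[g])] <- TRUE
  }
  make_em(vals, below)
}

test_that("detection filter reproduces the 7-of-26 / 16-of-62 boundaries", {
  set.seed(1)
  em <- detection_fixture(counts_pos = c(7, 6, 6, 0, 0),
                          counts_neg = c(0, 16, 15, 16, 0))
  keep <- detection_filter(em, make_labels(26, 62))
  expect_equal(unname(keep), c(FALSE,  # 7 masked positives -> excluded
                               FALSE,  # 16 masked negatives -> excluded
                               TRUE,   # 6 and 15: both within tolerance
                               FALSE,  # 16 masked negatives alone suffices
                               TRUE))  # fully detected -> retained
})

test_that("detection filter generalises as a strict fraction rule", {
  set.seed(2)
  em <- make_em(matrix(rnorm(40), 4, 10),
                matrix(FALSE, 4, 10))
  em$below_detection[2, 1] <- TRUE        # 1/4 positives = 0.25, not > 0.25
  em$below_detection[3, 1:2] <- TRUE      # 2/4 positives > 0.25
  em$below_detection[4, 5:7] <- TRUE      # 3/6 negatives > 0.25
  keep <- detection_filter(em, make_labels(4, 6))
  expect_equal(unname(keep), c(TRUE, TRUE, FALSE, FALSE))
  expect_error(detection_filter(em, rep("positive", 10)), "non-empty")
})

test_that("mean-difference filter applies the signed >= 1 rule at the boundary", {
  vals <- rbind(c(rep(1, 4), rep(0, 6)),     # diff exactly 1 -> pass
                c(rep(0.99, 4), rep(0, 6)),  # diff 0.99 -> fail
                c(rep(0, 4), rep(1.5, 6)))   # down in positives -> fail (signed)
  em <- make_em(vals)
  md <- mean_diff_filter(em, make_labels(4, 6))
  expect_equal(md$mean_diff, c(1, 0.99, -1.5))
  expect_equal(md$passed_diff, c(TRUE, FALSE, FALSE))
  expect_equal(md$mean_pos - md$mean_neg, md$mean_diff)
  md2 <- mean_diff_filter(em, make_labels(4, 6),
                          selection_params(signed = FALSE))
  expect_equal(md2$passed_diff, c(TRUE, FALSE, TRUE))
})

test_that("means and tests use detected values only", {
  vals <- rbind(c(5, 1, 2, 0, 0, 0))  # first positive value masked
  below <- rbind(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
  em <- make_em(vals, below)
  md <- mean_diff_filter(em, make_labels(3, 3))
  expect_equal(md$mean_pos, 1.5)  # mean of {1, 2}, the 5 is ignored
  tt <- two_sample_t(em, make_labels(3, 3))
  expect_equal(tt$n_detected_pos, 2L)
  expect_equal(tt$n_detected_neg, 3L)
})

test_that("degenerate t-test cases follow the documented conventions", {
  em <- make_em(rbind(c(1, 2, 3, 1, 2, 3),   # identical classes -> t=0, p=1
                      c(0, 0, 0, 1, 1, 1),   # zero variance, separated
                      c(2, 2, 2, 2, 2, 2)))  # zero variance, tied
  tt <- two_sample_t(em, make_labels(3, 3))
  expect_equal(tt$t_stat[1], 0)
  expect_equal(tt$p_value[1], 1)
  expect_equal(tt$t_stat[2], -Inf)
  expect_equal(tt$p_value[2], 0)
  expect_true(tt$passed_test[2])
  expect_equal(tt$t_stat[3], 0)
  expect_equal(tt$p_value[3], 1)
})

test_that("genes with fewer than two detected values per class are untestable", {
  below <- rbind(c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE))
  em <- make_em(rbind(c(9, 9, 1, 0, 0, 0)), below)
  tt <- two_sample_t(em, make_labels(3, 3))
  expect_true(is.na(tt$t_stat[1]))
  expect_true(is.na(tt$p_value[1]))
  expect_false(tt$passed_test[1])
  sel <- select_signature(em, make_labels(3, 3))
  expect_false(sel$selected[1])
})

test_that("vectorised t statistics match the per-gene textbook oracle", {
  for (var_equal in c(TRUE, FALSE)) {
    set.seed(7)
    ds <- quick_dataset(seed = 7, dropout_rate = 0.1)
    em <- ds$expression
    pos <- ds$samples$lvsi == "positive"
    tt <- two_sample_t(em, ds$samples,
                       selection_params(var_equal = var_equal))
    for (g in sample(nrow(em$values), 40)) {
      det <- !em$below_detection[g, ]
      xp <- em$values[g, pos & det]
      xn <- em$values[g, !pos & det]
      orc <- oracle_t_gene(xp, xn, var_equal)
      expect_equal(tt$t_stat[g], orc$t, tolerance = 1e-10)
      expect_equal(tt$p_value[g], orc$p, tolerance = 1e-10)
    }
  }
})

test_that("selection composes the three filters and orders the signature", {
  ds <- quick_dataset(seed = 3)
  sel <- select_signature(ds$expression, ds$samples)
  expect_identical(sel$selected,
                   sel$passed_detection & sel$passed_diff & sel$passed_test)
  sig <- signature_genes(sel)
  p <- sel$p_value[match(sig, sel$gene_id)]
  expect_true(all(diff(p) >= 0))
  ties <- split(sig, p)  # ids sorted within equal p
  expect_true(all(vapply(ties, function(v) !is.unsorted(v), logical(1))))
})

test_that("extreme parameters behave as limits", {
  ds <- quick_dataset(seed = 4)
  none <- select_signature(ds$expression, ds$samples,
                           selection_params(min_mean_diff = Inf))
  expect_length(signature_genes(none), 0L)
  big <- make_em(matrix(rep(c(10, 0), c(8, 12)), 5, 20, byrow = TRUE) +
                   rnorm(100, 0, 0.01))
  all_sel <- select_signature(big, make_labels(8, 12))
  expect_length(signature_genes(all_sel), 5L)
})

test_that("relaxing thresholds never shrinks the selected set", {
  ds <- quick_dataset(seed = 5, effect_size = 1.1, noise_sd = 0.8)
  base <- signature_genes(select_signature(ds$expression, ds$samples,
                                           selection_params()))
  looser_alpha <- signature_genes(select_signature(
    ds$expression, ds$samples, selection_params(alpha = 0.05)))
  looser_diff <- signature_genes(select_signature(
    ds$expression, ds$samples, selection_params(min_mean_diff = 0.5)))
  expect_true(all(base %in% looser_alpha))
  expect_true(all(base %in% looser_diff))
  expect_gt(length(looser_diff), length(base))
})

test_that("planted genes are recovered at the study effect size", {
  cfg <- sim_config(seed = 9)  # 55 planted, effect 1.5, sd 0.5, dropout 0.05
  ds <- simulate_expression(cfg)
  sel <- select_signature(ds$expression, ds$samples)
  sig <- signature_genes(sel)
  expect_gte(mean(ds$truth %in% sig), 50 / 55)
  expect_lte(length(setdiff(sig, ds$truth)), 2L)
})

test_that("selection tables and signature lists are written", {
  ds <- quick_dataset(seed = 6)
  sel <- select_signature(ds$expression, ds$samples)
  tf <- withr::local_tempfile(); sf <- withr::local_tempfile()
  write_selection(sel, tf, sf, header = "seed=6")
  tab <- read.delim(tf, comment.char = "#")
  expect_equal(nrow(tab), 300L)
  expect_identical(readLines(sf)[-1], signature_genes(sel))
})
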