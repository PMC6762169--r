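test_that("well-separated blobs are recovered exactly by the two-group cut", {
  set.seed(1)
  v <- cbind(matrix(rnorm(20 * 5, 0, 1), 20, 5),
             matrix(rnorm(20 * 7, 10, 1), 20, 7))
  em <- make_em(v)
  for (linkage in c("average", "complete", "ward", "single")) {
    ca <- cluster_samples(em, linkage = linkage)
    expect_equal(length(unique(ca$cluster[1:5])), 1L)
    expect_equal(length(unique(ca$cluster[6:12])), 1L)
    expect_false(ca$cluster[1] == ca$cluster[6])
  }
})

test_that("duplicated samples always co-cluster", {
  set.seed(2)
  v <- matrix(rnorm(10 * 6), 10, 6)
  v <- cbind(v, v[, 3])  # duplicate of sample 3
  em <- make_em(v)
  ca <- cluster_samples(em)
  expect_equal(ca$cluster[3], ca$cluster[7], ignore_attr = TRUE)
})

test_that("small instances match the explicit agglomeration oracle", {
  for (linkage in c("average", "complete", "ward", "single")) {
    for (seed in 1:8) {
      set.seed(seed * 100 + match(linkage, c("average", "complete", "ward", "single")))
      n <- sample(5:8, 1)
      X <- matrix(rnorm(n * 4), n, 4)
      em <- make_em(t(X))
      ca <- cluster_samples(em, linkage = linkage)
      expect_true(same_partition(unname(ca$cluster),
                                 oracle_two_groups(X, linkage)),
                  info = paste(linkage, "seed", seed))
    }
  }
})

test_that("merge heights are non-decreasing for the supported linkages", {
  set.seed(3)
  em <- make_em(matrix(rnorm(200), 10, 20))
  for (linkage in c("average", "complete", "ward")) {
    ca <- cluster_samples(em, linkage = linkage)
    expect_true(all(diff(ca$hclust$height) >= -1e-12))
  }
})

test_that("sample order does not change the partition", {
  set.seed(4)
  v <- matrix(rnorm(15 * 9), 15, 9)
  em <- make_em(v)
  perm <- sample(9)
  ca1 <- cluster_samples(em)
  ca2 <- cluster_samples(em[, perm])
  expect_true(same_partition(unname(ca1$cluster[perm]), unname(ca2$cluster)))
})

test_that("residual below-detection cells are mean-imputed before distances", {
  set.seed(5)
  v <- matrix(rnorm(30), 5, 6)
  below <- matrix(FALSE, 5, 6); below[1, 1] <- TRUE
  em <- make_em(v, below)
  ca <- cluster_samples(em)
  # equivalent to clustering the explicitly imputed matrix
  v2 <- v; v2[1, 1] <- mean(v[1, -1])
  ca2 <- cluster_samples(make_em(v2))
  expect_true(same_partition(unname(ca$cluster), unname(ca2$cluster)))
  below_all <- matrix(FALSE, 5, 6); below_all[2, ] <- TRUE
  expect_error(cluster_samples(make_em(v, below_all)), "no detected values")
})

test_that("degenerate inputs are rejected", {
  em <- make_em(matrix(rnorm(10), 5, 2))
  expect_error(cluster_samples(em[, 1]), "at least 2 samples")
  expect_error(cluster_samples(em, genes = character(0)), "empty")
  expect_error(cluster_samples(em, genes = "nope"), "absent")
})

test_that("group A is the LVSI-enriched cluster (study cross-tabulation)", {
  # clusters of 47 and 41 samples with 24 and 2 positives respectively
  cl <- rep(c(1L, 2L), c(47, 41))
  names(cl) <- sprintf("s%03d", 1:88)
  lab <- c(rep("positive", 24), rep("negative", 23),
           rep("positive", 2), rep("negative", 39))
  names(lab) <- names(cl)
  ca <- structure(list(hclust = NULL, cluster = cl, linkage = "average",
                       genes = "g", group_of = NULL),
                  class = "cluster_assignment")
  ca <- label_groups(ca, lab)
  expect_equal(unname(table(ca$group_of)[["A"]]), 47L)
  pred <- predict(ca)
  expect_equal(sum(pred == "positive"), 47L)
  expect_equal(sum(pred == "negative"), 41L)
})

test_that("group-label ties follow the documented rule", {
  mk <- function(cl, lab) {
    names(lab) <- names(cl) <- sprintf("s%d", seq_along(cl))
    label_groups(structure(list(cluster = cl, group_of = NULL),
                           class = "cluster_assignment"), lab)
  }
  # equal proportions (50%), sizes 4 vs 2: positive count 2 > 1 wins
  ca <- mk(rep(c(1L, 2L), c(4, 2)),
           c("positive", "positive", "negative", "negative",
             "positive", "negative"))
  expect_equal(unname(ca$group_of[1]), "A")
  # full tie: cluster of the first input sample wins
  ca2 <- mk(c(2L, 2L, 1L, 1L),
            c("positive", "negative", "positive", "negative"))
  expect_equal(unname(ca2$group_of[1]), "A")
  # all positives in one cluster
  ca3 <- mk(c(1L, 1L, 2L, 2L),
            c("negative", "negative", "positive", "positive"))
  expect_equal(unname(ca3$group_of[3]), "A")
  expect_error(predict(structure(list(group_of = NULL),
                                 class = "cluster_assignment")),
               "label_groups")
})

test_that("synthetic separable data is predicted at the planted labels", {
  ds <- simulate_expression(sim_config(n_genes = 200, n_signature = 30,
                                       effect_size = 4, noise_sd = 0.4,
                                       dropout_rate = 0.02, seed = 8))
  ca <- cluster_samples(ds$expression, genes = ds$truth)
  ca <- label_groups(ca, ds$samples)
  pred <- predict(ca)
  truth <- setNames(ds$samples$lvsi, ds$samples$sample_id)
  expect_identical(unname(pred[names(truth)]), unname(truth))
})

test_that("the dendrogram serialises to Newick with merge-derived lengths", {
  set.seed(9)
  em <- make_em(matrix(rnorm(40), 5, 8))
  ca <- cluster_samples(em)
  txt <- write_dendrogram(ca)
  phy <- ape::read.tree(text = txt)
  expect_setequal(phy$tip.label, sample_ids(em))
  expect_true(all(is.finite(phy$edge.length)))
  f <- withr::local_tempfile()
  ca <- label_groups(ca, make_labels(3, 5, sample_ids(em)))
  write_assignment(ca, f, header = "seed=9")
  df <- read.delim(f, comment.char = "#")
  expect_equal(sort(unique(df$group)), c("A", "B"))
})
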