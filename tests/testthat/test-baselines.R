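test_that("one-condition MANOVA reduces to the ANOVA F test", {
  set.seed(101)
  n <- 20
  x <- rbinom(n, 1, 0.5)
  y <- matrix(0.5 * x + rnorm(n), n, 1)
  p_manova <- manova_pair_test(y, x)
  p_anova <- anova(lm(y ~ x))[["Pr(>F)"]][1]
  expect_equal(p_manova, p_anova, tolerance = 1e-10)
})

test_that("pairwise MANOVA matches the stats::manova Wilks test", {
  set.seed(102)
  n <- 25; r <- 3
  x <- rbinom(n, 1, 0.5)
  Y <- matrix(0.4 * x, n, r) + matrix(rnorm(n * r), n, r)
  ours <- manova_pair_test(Y, x)
  fit <- stats::manova(Y ~ x)
  ref <- summary(fit, test = "Wilks")$stats["x", "Pr(>F)"]
  expect_equal(ours, ref, tolerance = 1e-9)
  expect_error(manova_pair_test(Y, rep(1, n)), "constant")
})

test_that("MANOVA null p-values are uniform", {
  set.seed(103)
  n <- 29
  pv <- replicate(2000, {
    manova_pair_test(matrix(rnorm(n * 3), n, 3), rbinom(n, 1, 0.5))
  })
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.01)
  # strong planted signal is detected nearly always
  hits <- replicate(100, {
    x <- rbinom(n, 1, 0.5)
    while (var(x) == 0) x <- rbinom(n, 1, 0.5)
    manova_pair_test(matrix(1.5 * x, n, 3) + matrix(rnorm(n * 3), n, 3),
                     x) < 0.01
  })
  expect_gt(mean(hits), 0.95)
})

test_that("manova_scores agrees with the single-pair test", {
  d <- make_tiny_data(n = 15, p = 3, q = 2, r = 2, seed = 104)
  sc <- manova_scores(d$X, d$stacks)
  expect_equal(10^(-sc$values[2, 3]),
               manova_pair_test(d$stacks[[2]], d$X[, 3]), tolerance = 1e-9)
  expect_true(sc$higher_is_stronger)
})

test_that("intersection scoring is exactly the all-tissues-exceed rule", {
  set.seed(105)
  mats <- lapply(1:3, function(i) matrix(runif(30), 5, 6))
  mn <- ist_hess_scores(mats)$values
  for (c in c(0.2, 0.5, 0.6, 0.9)) {
    rule <- Reduce(`&`, lapply(mats, function(m) m > c))
    expect_identical(mn > c, rule)
  }
  expect_equal(ist_hess_scores(list(mats[[1]], mats[[1]]))$values, mats[[1]])
  zero <- ist_hess_scores(list(mats[[1]], matrix(0, 5, 6)))$values
  expect_true(all(zero == 0))
  expect_error(ist_hess_scores(list(mats[[1]], matrix(0, 2, 2))),
               "differ in shape")
})

test_that("ROC points match hand enumeration and AUC limits", {
  truth <- structure(list(gamma_true = matrix(c(1, 0, 1, 0), 1)),
                     class_names = NULL, class = "mthess_sim_truth")
  scores <- matrix(c(0.9, 0.8, 0.4, 0.1), 1)
  roc <- roc_points(scores, truth)
  expect_equal(roc$fpr, c(0, 0, 0.5, 0.5, 1))
  expect_equal(roc$tpr, c(0, 0.5, 0.5, 1, 1))
  expect_equal(attr(roc, "auc"), 0.75)
  # perfect separation
  perfect <- roc_points(matrix(c(5, 1, 6, 0), 1), truth)
  expect_equal(attr(perfect, "auc"), 1)
  # random scores: AUC near 1/2
  set.seed(106)
  big <- structure(list(gamma_true = matrix(rbinom(4000, 1, 0.05), 40)),
                   class = "mthess_sim_truth")
  rnd <- roc_points(matrix(runif(4000), 40), big)
  expect_equal(attr(rnd, "auc"), 0.5, tolerance = 0.06)
})

test_that("true-FDR calibration picks the most permissive admissible cut", {
  truth <- structure(list(gamma_true = matrix(c(1, 0, 1, 1), 1)),
                     class = "mthess_sim_truth")
  scores <- matrix(c(0.9, 0.8, 0.7, 0.6), 1)
  # top-4 realizes FDR 1/4 = 0.25: admissible at level 0.25
  res <- true_fdr_threshold(scores, truth, 0.25)
  expect_equal(res$n_called, 4L)
  expect_equal(res$fdr, 0.25)
  expect_lt(res$threshold, 0.6)
  # at level 0: calls stop before the false positive
  res0 <- true_fdr_threshold(scores, truth, 0)
  expect_equal(res0$n_called, 1L)
  expect_equal(res0$fdr, 0)
  # oracle scores: everything called at FDR 0
  res1 <- true_fdr_threshold(truth$gamma_true + 0, truth, 0.1)
  expect_equal(res1$n_called, 3L)
  expect_equal(res1$fdr, 0)
})

test_that("classification table columns sum to the true class sizes", {
  cfg <- sim_config(n = 29, p = 80, q = 50, r = 3, n_chrom = 10, seed = 41)
  set.seed(41)
  truth <- simulate_effects(build_pattern(cfg), cfg)
  set.seed(42)
  fake_scores <- matrix(runif(50 * 80), 50, 80)
  ct <- classification_table(fake_scores, truth, 0.1)
  expect_equal(unname(colSums(ct$counts)),
               unname(as.numeric(table(factor(truth$class_labels,
                 levels = c("negative", "cis_isolated", "cis_other",
                            "trans"))))))
  # oracle scores recover the classes exactly
  ct2 <- classification_table(truth$gamma_true + 0, truth, 0.1)
  expect_equal(unname(ct2$counts["positive_call", ]),
               c(0, 5, 5, sum(truth$class_labels == "trans")))
  # all-zero scores: no positives, hotspot sizes zero
  ct3 <- classification_table(matrix(0, 50, 80), truth, 0.1)
  expect_true(all(ct3$counts["positive_call", ] == 0))
  hs <- hotspot_size_summary(matrix(0, 50, 80), truth, 0.1)
  expect_true(all(hs$mean_called == 0))
  hs2 <- hotspot_size_summary(truth$gamma_true + 0, truth, 0.1)
  expect_equal(hs2$mean_called, hs2$true_size)
})
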