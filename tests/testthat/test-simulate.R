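test_that("RI genotype simulator has the Markov-chain LD structure", {
  # theta = 0: all markers within a chromosome identical before dedupe; the
  # deduped panel keeps one marker per chromosome
  cfg0 <- sim_config(n = 20, p = 40, n_chrom = 5, switch_prob = 0,
                     q = 150, seed = 2)
  set.seed(2)
  pan0 <- simulate_ri_genotypes(cfg0)
  expect_lte(ncol(pan0$values), 5)
  # theta = 0.05: adjacent-marker correlation near 1 - 2*theta
  cfg <- sim_config(n = 200, p = 300, n_chrom = 5, switch_prob = 0.05,
                    seed = 3)
  set.seed(3)
  pan <- simulate_ri_genotypes(cfg)
  same_chrom <- diff(pan$marker_pos$chrom) == 0
  cors <- vapply(which(same_chrom), function(j)
    cor(pan$values[, j], pan$values[, j + 1]), numeric(1))
  expect_equal(mean(cors), 1 - 2 * 0.05, tolerance = 0.06)
  # theta = 0.5: independence
  cfg5 <- sim_config(n = 500, p = 100, n_chrom = 4, switch_prob = 0.5,
                     seed = 4)
  set.seed(4)
  pan5 <- simulate_ri_genotypes(cfg5)
  same5 <- diff(pan5$marker_pos$chrom) == 0
  cors5 <- vapply(which(same5), function(j)
    cor(pan5$values[, j], pan5$values[, j + 1]), numeric(1))
  expect_lt(abs(mean(cors5)), 0.1)
  expect_equal(ncol(pan5$values), 100)
})

test_that("the cis/trans pattern has the stated class structure", {
  cfg <- sim_config(seed = 9)        # full scale: q = 150, p = 1304
  set.seed(9)
  pan <- simulate_ri_genotypes(sim_config(n = 29, p = 200, n_chrom = 20,
                                          seed = 9))
  cfg$p <- ncol(pan$values)
  truth <- build_pattern(cfg, pan)
  tab <- table(truth$class_labels)
  expect_equal(unname(tab[["trans"]]), 120)          # 2*(10+20+30)
  expect_equal(unname(tab[["cis_isolated"]]), 5)
  expect_equal(unname(tab[["cis_other"]]), 5)
  expect_equal(unname(tab[["negative"]]), 150 * cfg$p - 130)
  expect_equal(sum(truth$gamma_true), 130)
  # labels live exactly on the support of gamma_true
  expect_true(all((truth$class_labels != "negative") ==
                  (truth$gamma_true == 1)))
  # hotspot markers on distinct chromosomes; cis markers elsewhere
  expect_equal(anyDuplicated(pan$marker_pos$chrom[truth$hotspot_markers]), 0)
  expect_false(any(truth$cis_markers %in% truth$hotspot_markers))
  # scaled-down variant keeps proportions
  cfg50 <- sim_config(q = 50, p = 100, seed = 1)
  t50 <- build_pattern(cfg50)
  expect_equal(t50$hotspot_sizes, c(3L, 3L, 7L, 7L, 10L, 10L))
})

test_that("effect sizes follow their class means", {
  cfg <- sim_config(q = 150, p = 200, seed = 12)
  set.seed(12)
  truth <- build_pattern(cfg)
  truth <- simulate_effects(truth, cfg)
  lam_trans <- truth$lambda[truth$class_labels == "trans"]
  lam_cis <- truth$lambda[truth$class_labels %in% c("cis_isolated",
                                                    "cis_other")]
  expect_equal(mean(lam_trans), 0.15, tolerance = 3 * 0.001 / sqrt(120))
  expect_equal(mean(lam_cis), 0.6, tolerance = 3 * 0.001 / sqrt(10))
  expect_true(all(truth$lambda[truth$gamma_true == 0] == 0))
  # degenerate SD: all effects exactly at the class mean
  cfg0 <- cfg; cfg0$lambda_sd <- 0
  t0 <- simulate_effects(build_pattern(cfg0), cfg0)
  expect_true(all(t0$lambda[t0$class_labels == "trans"] == 0.15))
})

test_that("noise decomposition reproduces total SDs and shared correlation", {
  cfg <- sim_config(n = 400, p = 30, q = 40, r = 3, n_chrom = 5,
                    sigma_total = c(0.1, 0.1, 0.1), sigma_shared = 0.04,
                    seed = 21)
  set.seed(21)
  pan <- simulate_ri_genotypes(cfg)
  cfg$p <- ncol(pan$values)
  truth <- build_pattern(cfg, pan)
  truth$gamma_true[] <- 0L                  # null signal
  truth$class_labels[] <- "negative"
  truth <- simulate_effects(truth, cfg)
  Y <- simulate_responses(pan, truth, cfg)
  flat <- sapply(1:3, function(l)
    as.numeric(vapply(Y$stacks, function(s) s[, l], numeric(cfg$n))))
  sds <- apply(flat, 2, sd)
  expect_equal(sds, rep(0.1, 3), tolerance = 0.02)
  cors <- cor(flat)[upper.tri(diag(3))]
  expect_equal(mean(cors), 0.04^2 / 0.1^2, tolerance = 0.02)
  # degenerate decomposition: all noise shared, conditions identical
  cfg2 <- cfg; cfg2$sigma_shared <- 0.1
  set.seed(5)
  Y2 <- simulate_responses(pan, truth, cfg2)
  expect_equal(Y2$stacks[[1]][, 1], Y2$stacks[[1]][, 3])
  # invalid decomposition is rejected
  expect_error(sim_config(sigma_total = c(0.1, 0.1, 0.1),
                          sigma_shared = 0.2),
               "must not exceed")
})

test_that("dataset simulation is reproducible from its seed", {
  cfg <- sim_config(n = 15, p = 40, q = 25, r = 2, n_chrom = 4,
                    sigma_total = rep(0.1, 2), seed = 33)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$X$values, d2$X$values)
  expect_identical(d1$truth$lambda, d2$truth$lambda)
  expect_identical(d1$Y$stacks, d2$Y$stacks)
})
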