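test_that("the sampler is exactly reproducible from its seed", {
  d <- make_tiny_data(n = 10, p = 5, q = 2, r = 2, seed = 31)
  hp <- tiny_hp(q = 2, n = 10, p = 5)
  cfg <- sampler_config(n_sweeps = 600, burn_in = 100, seed = 99,
                        trace_thin = 10)
  t1 <- run_sampler(d$X, d$stacks, hp, cfg, ladder_config(n_chains = 3))
  t2 <- run_sampler(d$X, d$stacks, hp, cfg, ladder_config(n_chains = 3))
  expect_identical(t1$inclusion_counts, t2$inclusion_counts)
  expect_identical(t1$g_samples, t2$g_samples)
  expect_identical(t1$omega_trace, t2$omega_trace)
  cfg2 <- sampler_config(n_sweeps = 600, burn_in = 100, seed = 100)
  t3 <- run_sampler(d$X, d$stacks, hp, cfg2, ladder_config(n_chains = 3))
  expect_false(identical(t1$inclusion_counts, t3$inclusion_counts))
})

test_that("fixed-hyperparameter MPPIs match exhaustive enumeration", {
  # single chain, local moves only
  d <- make_tiny_data(n = 8, p = 4, q = 2, r = 2, seed = 42)
  hp <- tiny_hp(q = 2, n = 8)
  om <- rep(0.25, 2); rho <- rep(1, 4); g <- 5
  exact <- exact_enumeration(d$X, d$stacks, hp, om, rho, g)
  cfg <- sampler_config(n_sweeps = 50000, burn_in = 2000, seed = 7,
                        trace_thin = 100, global_moves = FALSE)
  tr <- run_sampler(d$X, d$stacks, hp, cfg, ladder_config(n_chains = 1),
                    fixed = list(omega = om, rho = rho, g = g))
  mp <- tr$inclusion_counts / tr$recorded_sweeps
  expect_lt(max(abs(mp - exact)), 0.02)
  # full EMC with crossover and exchange converges to the same answer
  tr4 <- run_sampler(d$X, d$stacks, hp, cfg, ladder_config(n_chains = 4),
                     fixed = list(omega = om, rho = rho, g = g))
  mp4 <- tr4$inclusion_counts / tr4$recorded_sweeps
  expect_lt(max(abs(mp4 - exact)), 0.02)
  expect_lt(max(abs(mp4 - mp)), 0.02)
})

test_that("enumeration oracle has the exchangeability and expectation identities", {
  # zero-signal data with a symmetric prior: all MPPIs equal
  set.seed(5)
  n <- 8; p <- 4
  X <- matrix(rep(rbinom(n, 1, 0.5), p), n, p)
  X <- X + 0 # identical columns give exact exchangeability
  Y <- list(matrix(rnorm(n * 2), n, 2))
  hp <- tiny_hp(q = 1, n = n)
  # identical columns are collinear in pairs; with max size 1 they never
  # co-occur, so symmetry is exact
  hp1 <- hyperparams(h = hp$h, a_g = hp$a_g, b_g = hp$b_g,
                     a_omega = hp$a_omega, b_omega = hp$b_omega,
                     max_model_size = 1L)
  mp <- exact_enumeration(X, Y, hp1, 0.2, rep(1, p), 3)
  expect_lt(diff(range(mp)), 1e-12)
  # dominant predictor gets MPPI near 1
  d <- make_tiny_data(n = 12, p = 4, q = 1, r = 2, beta = 3,
                      noise_sd = 0.05, seed = 8)
  hp2 <- tiny_hp(q = 1, n = 12)
  mp2 <- exact_enumeration(d$X, d$stacks, hp2, 0.2, rep(1, 4), 20)
  expect_gt(mp2[1, 1], 0.99)
  # E(|gamma|) identity: sum of MPPIs equals the posterior mean model size
  d3 <- make_tiny_data(n = 8, p = 3, q = 1, r = 2, seed = 10)
  hp3 <- tiny_hp(q = 1, p = 3)
  om <- 0.3; rho <- c(1, 0.5, 2); g <- 4
  mp3 <- exact_enumeration(d3$X, d3$stacks, hp3, om, rho, g)
  scores <- vapply(0:7, function(m) {
    gam <- as.integer(bitwAnd(m, 2^(0:2)) > 0)
    log_marginal(d3$stacks[[1]], d3$X, gam, g, hp3, 1) +
      log_prior_gamma_row(gam, om, rho)
  }, numeric(1))
  w <- exp(scores - max(scores)); w <- w / sum(w)
  esize <- sum(w * vapply(0:7, function(m)
    sum(bitwAnd(m, 2^(0:2)) > 0), numeric(1)))
  expect_equal(sum(mp3), esize, tolerance = 1e-10)
})

test_that("hierarchical updates keep constraints and track the g posterior", {
  d <- make_tiny_data(n = 10, p = 4, q = 3, r = 2, seed = 20)
  hp <- tiny_hp(q = 3, n = 10)
  cfg <- sampler_config(n_sweeps = 4000, burn_in = 1000, seed = 3,
                        trace_thin = 5)
  tr <- run_sampler(d$X, d$stacks, hp, cfg, ladder_config(n_chains = 3))
  expect_true(all(tr$g_samples > 0))
  expect_true(all(tr$omega_trace > 0 & tr$omega_trace < 1))
  expect_true(all(tr$rho_trace > 0))
  # constraint omega_k * rho_j <= 1 on every recorded joint state
  mx <- apply(tr$omega_trace, 1, max) * apply(tr$rho_trace, 1, max)
  expect_true(all(mx <= 1 + 1e-9))
  # acceptance bookkeeping: accepted <= proposed, all move types tallied
  acc <- tr$acceptance
  expect_true(all(acc$accepted <= acc$proposed))
  expect_setequal(acc$move, c("add", "delete", "swap", "crossover",
                              "exchange", "omega", "rho", "g"))
  expect_gt(acc$proposed[acc$move == "exchange"], 0)
})

test_that("ladder tuning moves the geometric ratio toward the target rate", {
  lad <- ladder_config(n_chains = 3, ratio = 2, target_swap_rate = 0.5)
  expect_equal(tune_ladder(0.5, lad)$ratio, 2, tolerance = 1e-12)
  shrunk <- tune_ladder(0, lad)
  expect_lt(shrunk$ratio, 2)          # no swaps: temperatures move closer
  grown <- tune_ladder(1, lad)
  expect_gt(grown$ratio, 2)
  expect_equal(shrunk$temperatures[1], 1)
  expect_equal(shrunk$temperatures, shrunk$ratio^(0:2))
})
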