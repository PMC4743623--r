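# Shared fixtures: tiny random datasets, and memoised benchmark runs reused
# by several acceptance checks so the heavy simulations run once.

make_tiny_data <- function(n = 8, p = 4, q = 2, r = 2, signal = c(1),
                           beta = 1, noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  while (any(apply(X, 2, stats::var) == 0))
    X <- matrix(rbinom(n * p, 1, 0.5), n, p)
  stacks <- lapply(seq_len(q), function(k) {
    mu <- if (k == 1 && length(signal)) X[, signal, drop = FALSE] %*%
      rep(beta, length(signal)) else matrix(0, n, 1)
    matrix(rep(mu, r), n, r) + matrix(rnorm(n * r, 0, noise_sd), n, r)
  })
  list(X = X, stacks = stacks, n = n, p = p, q = q, r = r)
}

tiny_hp <- function(q, n = 8, h = 0.25, e = 1, v = NULL, p = 4) {
  # midway between the binomial bound and the maximal beta-binomial variance
  if (is.null(v)) v <- e * (1 - e / p) * (1 + (p - 1) / 2)
  spec <- prior_spec(e, v, n, q, p)
  ab <- elicit_omega_hyperparams(spec)
  gp <- g_prior_params(n, q)
  hyperparams(h = rep(h, q), a_g = gp[["a_g"]], b_g = gp[["b_g"]],
              a_omega = ab$a_omega, b_omega = ab$b_omega)
}

# ---- memoised scaled-down benchmark replicates -----------------------------
# Scaled-down version of the cis/trans simulation design: p = 300, q = 50,
# n = 29, r = 3, three replicates; balanced (all total noise SD 0.1) and
# unbalanced (0.1, 0.2, 0.4) scenarios, independent residuals.

.bench_env <- new.env(parent = emptyenv())

bench_sampler_cfg <- function(seed) {
  sampler_config(n_sweeps = 10000, burn_in = 3000, seed = seed,
                 trace_thin = 50)
}

bench_st_cfg <- function(seed) {
  sampler_config(n_sweeps = 8000, burn_in = 2500, seed = seed,
                 trace_thin = 50)
}

bench_replicates <- function(scenario = c("balanced", "unbalanced"),
                             methods, n_reps = 3) {
  scenario <- match.arg(scenario)
  key <- paste(scenario, paste(sort(methods), collapse = "+"), n_reps,
               sep = "_")
  if (!is.null(.bench_env[[key]])) return(.bench_env[[key]])
  sig <- if (scenario == "balanced") rep(0.1, 3) else c(0.1, 0.2, 0.4)
  reps <- lapply(seq_len(n_reps), function(i) {
    cfg <- sim_config(n = 29, p = 300, q = 50, r = 3, sigma_total = sig,
                      sigma_shared = 0, seed = 1000 + i)
    run_benchmark_replicate(cfg, bench_sampler_cfg(seed = 2000 + i),
                            ladder_config(n_chains = 3), methods = methods,
                            st_sampler_cfg = bench_st_cfg(seed = 2000 + i))
  })
  .bench_env[[key]] <- reps
  reps
}
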