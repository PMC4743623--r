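#' Temperature-ladder configuration
#'
#' The sampler runs `n_chains` tempered chains; the coldest chain has
#' temperature 1 and targets the posterior. The ladder is geometric with the
#' given initial `ratio` and is rescaled during burn-in so the adjacent-swap
#' acceptance rate approaches `target_swap_rate`.
#'
#' @param n_chains Number of chains, default 3.
#' @param ratio Initial geometric ratio between adjacent temperatures,
#'   default 2.
#' @param adapt_interval Sweeps between tuning events during burn-in,
#'   default 100.
#' @param target_swap_rate Target adjacent-swap acceptance rate, default 0.5.
#' @return Object of class `mthess_ladder`.
#' @export
ladder_config <- function(n_chains = 3L, ratio = 2, adapt_interval = 100L,
                          target_swap_rate = 0.5) {
  stopifnot(n_chains >= 1, ratio > 1, adapt_interval >= 1,
            target_swap_rate > 0, target_swap_rate < 1)
  structure(list(n_chains = as.integer(n_chains), ratio = ratio,
                 temperatures = ratio^(seq_len(n_chains) - 1),
                 adapt_interval = as.integer(adapt_interval),
                 target_swap_rate = target_swap_rate),
            class = "mthess_ladder")
}

#' Sampler configuration
#'
#' @param n_sweeps Total sweeps `T`, default 15000.
#' @param burn_in Burn-in sweeps, default 5000; must be `< n_sweeps`.
#' @param response_update_fraction Fraction of responses updated per sweep,
#'   default 1.
#' @param seed Integer seed; every source of randomness in the run derives
#'   from it.
#' @param move_probabilities Named numeric vector with elements `add`,
#'   `delete`, `swap` summing to 1.
#' @param trace_thin Thinning interval for stored omega/rho samples,
#'   default 10.
#' @param n_local Local (add/delete/swap) Metropolis-Hastings updates of each
#'   selected row per chain per sweep, default 3. The hyperparameter updates
#'   dominate the sweep cost at realistic p and q, so several cheap row
#'   updates per sweep speed up mixing of Gamma at almost no extra cost.
#' @param global_moves Enable crossover and temperature-exchange moves,
#'   default TRUE.
#' @return Object of class `mthess_sampler_config`.
#' @export
sampler_config <- function(n_sweeps = 15000L, burn_in = 5000L,
                           response_update_fraction = 1,
                           seed = 1L,
                           move_probabilities = c(add = 0.35, delete = 0.35,
                                                  swap = 0.30),
                           trace_thin = 10L, global_moves = TRUE,
                           n_local = 3L) {
  stopifnot(n_sweeps >= 2, burn_in >= 0, burn_in < n_sweeps,
            response_update_fraction > 0, response_update_fraction <= 1,
            trace_thin >= 1, n_local >= 1)
  mp <- move_probabilities[c("add", "delete", "swap")]
  if (anyNA(mp) || abs(sum(mp) - 1) > 1e-8)
    stop("move_probabilities must have add/delete/swap summing to 1")
  structure(list(n_sweeps = as.integer(n_sweeps),
                 burn_in = as.integer(burn_in),
                 response_update_fraction = response_update_fraction,
                 seed = as.integer(seed),
                 move_probabilities = mp,
                 trace_thin = as.integer(trace_thin),
                 global_moves = isTRUE(global_moves),
                 n_local = as.integer(n_local)),
            class = "mthess_sampler_config")
}

#' Run the Evolutionary Monte Carlo sampler
#'
#' Samples the joint posterior of the inclusion matrix `Gamma`, the
#' per-response sparsity probabilities `omega_k`, the hotspot propensities
#' `rho_j` and the shared shrinkage factor `g`. Each sweep updates a uniform
#' subset of responses with per-chain local add/delete/swap moves and a
#' cross-chain crossover move, updates `omega` and `rho` by tempered
#' Metropolis-Hastings, proposes one temperature-exchange move, and updates
#' `g` against the cold chain. Only cold-chain, post-burn-in states are
#' recorded.
#'
#' @param X A [genotype_panel()] (or bare numeric matrix).
#' @param Y A [response_panel()] (or list of `n x r` matrices).
#' @param hp A [hyperparams()] object.
#' @param cfg A [sampler_config()].
#' @param ladder A [ladder_config()].
#' @param fixed Optional list pinning hyperparameters for validation runs:
#'   elements `omega` (length-q), `rho` (length-p), `g` (scalar). When
#'   `omega`/`rho` are supplied they are held fixed (no updates); same for
#'   `g`.
#' @return Object of class `mthess_trace` with inclusion counts, recorded
#'   sweep count, g/omega/rho summaries and thinned traces, per-response
#'   visited models, acceptance statistics and the final temperature ladder.
#' @export
run_sampler <- function(X, Y, hp, cfg = sampler_config(),
                        ladder = ladder_config(), fixed = NULL) {
  Xm <- if (inherits(X, "genotype_panel")) X$values else as.matrix(X)
  stacks <- if (inherits(Y, "response_panel")) Y$stacks else Y
  stopifnot(inherits(hp, "mthess_hyperparams"),
            inherits(cfg, "mthess_sampler_config"),
            inherits(ladder, "mthess_ladder"))
  q <- length(stacks)
  n <- nrow(Xm); p <- ncol(Xm)
  stopifnot(length(hp$h) == q, nrow(stacks[[1]]) == n)

  Xc <- center_columns(Xm)
  Ycs <- lapply(stacks, center_columns)

  fix_hyper <- !is.null(fixed) && !is.null(fixed$omega) && !is.null(fixed$rho)
  fix_g <- !is.null(fixed) && !is.null(fixed$g)
  omega_init <- if (fix_hyper) rep_len(fixed$omega, q) else
    pmin(hp$a_omega / (hp$a_omega + hp$b_omega), 0.9)
  rho_init <- if (fix_hyper) rep_len(fixed$rho, p) else rep(1, p)
  if (any(outer(omega_init, rho_init) > 1 + 1e-12))
    stop("initial state violates omega_k * rho_j <= 1")
  g_init <- if (fix_g) fixed$g else hp$b_g / (hp$a_g + 1)

  ccfg <- list(n_sweeps = cfg$n_sweeps, burn_in = cfg$burn_in,
               n_chains = ladder$n_chains,
               temperatures = ladder$temperatures,
               response_update_fraction = cfg$response_update_fraction,
               move_probabilities = unname(cfg$move_probabilities),
               adapt_interval = ladder$adapt_interval,
               target_swap_rate = ladder$target_swap_rate,
               trace_thin = cfg$trace_thin,
               n_local = cfg$n_local,
               fix_hyper = fix_hyper, fix_g = fix_g,
               g_init = g_init, omega_init = omega_init,
               rho_init = rho_init,
               global_moves = cfg$global_moves)
  chyp <- list(d = hp$d, h = hp$h, a_g = hp$a_g, b_g = hp$b_g,
               a_omega = hp$a_omega, b_omega = hp$b_omega,
               c_rho = hp$c_rho, d_rho = hp$d_rho,
               max_model_size = hp$max_model_size)

  set.seed(cfg$seed)
  out <- mthess_emc_cpp(Xc, Ycs, chyp, ccfg)
  out$n <- n; out$p <- p; out$q <- q; out$r <- ncol(stacks[[1]])
  out$marker_ids <- if (inherits(X, "genotype_panel")) X$marker_ids else
    colnames(Xm)
  out$response_ids <- if (inherits(Y, "response_panel")) Y$response_ids else
    names(stacks)
  out$hp <- hp
  out$fixed <- fixed
  out$config <- cfg
  class(out) <- "mthess_trace"
  out
}

#' @export
print.mthess_trace <- function(x, ...) {
  cat(sprintf("mthess_trace: %d recorded sweeps, q = %d responses, p = %d markers\n",
              x$recorded_sweeps, x$q, x$p))
  cat(sprintf("  posterior mean g = %.3f\n", x$g_mean))
  invisible(x)
}

#' Exact posterior inclusion probabilities by enumeration
#'
#' For fixed `(omega, rho, g)` the responses are independent and the
#' posterior over each row `gamma_k` can be enumerated exactly over all
#' models up to the size cap (`p <= 12`). Serves as the correctness oracle
#' for the sampler.
#'
#' @param X,Y,hp As in [run_sampler()].
#' @param omega Length-q sparsity probabilities.
#' @param rho Length-p propensities.
#' @param g Shrinkage factor.
#' @return `q x p` matrix of exact marginal posterior inclusion
#'   probabilities.
#' @export
exact_enumeration <- function(X, Y, hp, omega, rho, g) {
  Xm <- if (inherits(X, "genotype_panel")) X$values else as.matrix(X)
  stacks <- if (inherits(Y, "response_panel")) Y$stacks else Y
  p <- ncol(Xm); q <- length(stacks); n <- nrow(Xm)
  if (p > 12) stop("exact enumeration is limited to p <= 12")
  omega <- rep_len(omega, q)
  cap <- min(hp$max_model_size, n - 2L)
  models <- lapply(0:(2^p - 1), function(m) which(bitwAnd(m, 2^(0:(p - 1))) > 0))
  models <- models[vapply(models, length, 1L) <= cap]
  mppi <- matrix(0, q, p)
  for (k in seq_len(q)) {
    scores <- vapply(models, function(sel) {
      gam <- integer(p); gam[sel] <- 1L
      ml <- tryCatch(log_marginal(stacks[[k]], Xm, sel, g, hp, k,
                                  indices = TRUE),
                     error = function(e) -Inf)
      ml + log_prior_gamma_row(gam, omega[k], rho)
    }, numeric(1))
    w <- exp(scores - max(scores[is.finite(scores)]))
    w[!is.finite(w)] <- 0
    w <- w / sum(w)
    for (m in seq_along(models)) mppi[k, models[[m]]] <-
        mppi[k, models[[m]]] + w[m]
  }
  mppi
}

#' Rescale a geometric temperature ladder from observed swap rates
#'
#' During burn-in the common ratio of the geometric ladder is moved up or
#' down so the observed adjacent-swap acceptance rate approaches the target:
#' a low rate brings the temperatures closer together, a high rate spreads
#' them. The coldest temperature stays exactly 1.
#'
#' @param observed_rate Observed adjacent-swap acceptance rate in the last
#'   tuning window.
#' @param ladder A [ladder_config()].
#' @return An updated `mthess_ladder`.
#' @export
tune_ladder <- function(observed_rate, ladder) {
  stopifnot(inherits(ladder, "mthess_ladder"),
            observed_rate >= 0, observed_rate <= 1)
  ratio <- ladder$ratio^exp(0.5 * (observed_rate - ladder$target_swap_rate))
  ratio <- min(max(ratio, 1.3), 16)
  ladder$ratio <- ratio
  ladder$temperatures <- ratio^(seq_len(ladder$n_chains) - 1)
  ladder
}
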