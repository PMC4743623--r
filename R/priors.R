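#' Prior specification from expected model sizes
#'
#' Users specify, per response, the a-priori expected number of included
#' predictors `E(|gamma_k|)` and its variance `Var(|gamma_k|)`; the Beta
#' hyperparameters of `omega_k` are back-calculated from these moments.
#'
#' @param e_gamma Expected model size per response; scalar (broadcast) or
#'   length-`q` vector. Must be `< p`.
#' @param v_gamma Variance of the model size; scalar or length-`q`. Must
#'   exceed the binomial variance `E (1 - E/p)`.
#' @param n,q,p Sample, response and predictor counts.
#' @return Object of class `mthess_prior_spec`.
#' @export
prior_spec <- function(e_gamma, v_gamma, n, q, p) {
  e_gamma <- rep_len(as.numeric(e_gamma), q)
  v_gamma <- rep_len(as.numeric(v_gamma), q)
  stopifnot(n >= 3, q >= 1, p >= 1, all(e_gamma > 0), all(v_gamma > 0))
  if (any(e_gamma >= p)) stop("e_gamma must be smaller than p")
  structure(list(e_gamma = e_gamma, v_gamma = v_gamma, n = n, q = q, p = p),
            class = "mthess_prior_spec")
}

#' Back-calculate Beta hyperparameters for the sparsity probabilities
#'
#' Treating the hotspot propensities `rho_j` at their prior center of 1,
#' the model size `|gamma_k|` given `omega_k` is Binomial(p, omega_k), so
#' marginally it is beta-binomial. The Beta parameters `(a_k, b_k)` of
#' `omega_k` are obtained by matching the beta-binomial mean and variance to
#' the user-specified `E(|gamma_k|)` and `Var(|gamma_k|)`:
#' `E = p mu` and `Var = p mu (1-mu) [1 + (p-1)/(a+b+1)]` with
#' `mu = a/(a+b)`.
#'
#' @param spec A [prior_spec()].
#' @return List with numeric vectors `a_omega` and `b_omega` of length `q`.
#' @export
elicit_omega_hyperparams <- function(spec) {
  stopifnot(inherits(spec, "mthess_prior_spec"))
  p <- spec$p
  mu <- spec$e_gamma / p
  binom_var <- spec$e_gamma * (1 - mu)
  if (any(spec$v_gamma <= binom_var)) {
    k <- which(spec$v_gamma <= binom_var)[1L]
    stop(sprintf(paste0(
      "cannot elicit omega prior for response %d: Var(|gamma|) = %.4g is at ",
      "or below the binomial bound E(|gamma|)(1 - E(|gamma|)/p) = %.4g; ",
      "over-dispersion is required"), k, spec$v_gamma[k], binom_var[k]))
  }
  phi <- spec$v_gamma / binom_var - 1          # = (p-1)/(a+b+1)
  s <- (p - 1) / phi - 1                       # a + b
  if (any(s <= 0)) {
    k <- which(s <= 0)[1L]
    stop(sprintf(paste0(
      "cannot elicit omega prior for response %d: Var(|gamma|) = %.4g ",
      "exceeds the maximal beta-binomial variance at p = %d"),
      k, spec$v_gamma[k], p))
  }
  list(a_omega = mu * s, b_omega = (1 - mu) * s)
}

#' Inverse-gamma hyperparameters for the shrinkage factor g
#'
#' Returns `(a_g, b_g) = (q/2 + q - 1, n q / 2)`, the q-response adaptation
#' of the Zellner--Siow prior `InvGamma(1/2, n/2)`: the prior mode
#' `b/(a+1) = n/3` is the same for every `q`, while the prior precision
#' grows with the number of responses.
#'
#' @param n Sample size.
#' @param q Number of responses.
#' @return Named numeric vector with elements `a_g`, `b_g`.
#' @export
g_prior_params <- function(n, q) {
  stopifnot(n >= 1, q >= 1)
  c(a_g = q / 2 + q - 1, b_g = n * q / 2)
}

#' Log prior of one inclusion row
#'
#' `sum_j [gamma_kj log(omega_k rho_j) + (1 - gamma_kj) log(1 - omega_k
#' rho_j)]`, the independent-Bernoulli row prior under the multiplicative
#' decomposition `omega_kj = omega_k * rho_j`.
#'
#' @param gamma Binary vector of length `p`.
#' @param omega_k Sparsity probability in (0, 1).
#' @param rho Positive propensities of length `p`; every product
#'   `omega_k * rho_j` must lie in `[0, 1]`.
#' @return Scalar log prior.
#' @export
log_prior_gamma_row <- function(gamma, omega_k, rho) {
  w <- omega_k * rho
  if (any(w > 1 + 1e-12) || any(w < 0))
    stop("constraint violated: omega_k * rho_j must lie in [0, 1]")
  w <- pmin(w, 1)
  g1 <- gamma != 0
  sum(log(w[g1])) + sum(log1p(-w[!g1]))
}

#' Log prior densities of omega, rho and g
#'
#' `omega_k ~ Beta(a, b)`; `rho_j ~ Gamma(shape c, rate d)` (so the prior
#' mean is `c/d`, equal to 1 at the default 1.2/1.2); `g ~ InvGamma(shape a,
#' scale b)` with density proportional to `g^{-a-1} exp(-b/g)` and mode
#' `b/(a+1)`.
#'
#' @param omega_k,rho_j,g Evaluation points, strictly inside the support.
#' @param a_omega_k,b_omega_k,c_rho,d_rho,a_g,b_g Prior parameters.
#' @return Scalar log density.
#' @export
log_prior_omega <- function(omega_k, a_omega_k, b_omega_k) {
  if (omega_k <= 0 || omega_k >= 1) stop("omega_k outside (0, 1)")
  stats::dbeta(omega_k, a_omega_k, b_omega_k, log = TRUE)
}

#' @rdname log_prior_omega
#' @export
log_prior_rho <- function(rho_j, c_rho, d_rho) {
  if (rho_j <= 0) stop("rho_j must be positive")
  stats::dgamma(rho_j, shape = c_rho, rate = d_rho, log = TRUE)
}

#' @rdname log_prior_omega
#' @export
log_prior_g <- function(g, a_g, b_g) {
  if (g <= 0) stop("g must be positive")
  a_g * log(b_g) - lgamma(a_g) - (a_g + 1) * log(g) - b_g / g
}

#' Empirical-Bayes residual scale h_k
#'
#' For each condition, runs forward-stepwise least squares of the response
#' column on the marker columns (entry when the partial F-test p-value is
#' below `alpha / p`, Bonferroni-adjusted for scanning all p candidates; at
#' most `max_steps` predictors) and estimates the residual variance with the
#' unbiased denominator. Returns the median of the condition-specific
#' estimates, a rough scale for the likely error variance.
#'
#' @param Y A [response_panel()].
#' @param X A [genotype_panel()].
#' @param k Response index.
#' @param alpha Entry p-value threshold, default 0.05.
#' @param max_steps Maximum number of predictors entered, default 5.
#' @return Positive scalar `h_k`.
#' @export
empirical_h <- function(Y, X, k, alpha = 0.05, max_steps = 5L) {
  stopifnot(inherits(Y, "response_panel"), inherits(X, "genotype_panel"))
  Yk <- Y$stacks[[k]]
  Xm <- X$values
  n <- nrow(Yk)
  Xc <- center_columns(Xm)
  ests <- vapply(seq_len(ncol(Yk)), function(l) {
    y <- Yk[, l]
    if (stats::var(y) == 0) stop("zero-variance response column")
    # forward selection by Gram-Schmidt: residualize y and the candidate
    # columns against the selected set; the RSS drop for adding column j is
    # (x_j' y)^2 / (x_j' x_j) in the residualized metric
    yr <- y - mean(y)
    Xr <- Xc
    rss <- sum(yr^2)
    n_sel <- 0L
    while (n_sel < max_steps && n_sel < n - 3L) {
      den <- colSums(Xr^2)
      num <- as.numeric(crossprod(Xr, yr))^2
      red <- ifelse(den > 1e-10 * max(den, 1), num / den, 0)
      j <- which.max(red)
      df2 <- n - n_sel - 2L
      if (red[j] <= 0 || red[j] >= rss) break
      f <- red[j] / ((rss - red[j]) / df2)
      # Bonferroni-adjusted entry: the step scans all p candidates, so the
      # raw best-of-p F test would always admit spurious predictors at
      # large p and bias h_k downward
      if (stats::pf(f, 1, df2, lower.tail = FALSE) >= alpha / ncol(Xm)) break
      u <- Xr[, j] / sqrt(den[j])
      yr <- yr - u * sum(u * yr)
      Xr <- Xr - u %*% crossprod(u, Xr)
      rss <- rss - red[j]
      n_sel <- n_sel + 1L
    }
    rss / (n - n_sel - 1L)
  }, numeric(1))
  stats::median(ests)
}
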