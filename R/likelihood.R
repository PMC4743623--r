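#' Hyperparameters of the hierarchical model
#'
#' Collects the fixed hyperparameters: the inverse-Wishart degrees `d`
#' (default 3, which makes the prior mean of each residual covariance equal
#' `h_k I_r` under the convention used here), the per-response scales `h_k`,
#' the inverse-gamma parameters of the shrinkage factor `g`, the per-response
#' Beta parameters of the sparsity probabilities `omega_k`, the Gamma
#' parameters of the hotspot propensities `rho_j`, and the cap on model size.
#'
#' @param h Numeric vector of length `q` (positive); per-response residual
#'   scale `h_k`.
#' @param a_g,b_g Inverse-gamma shape and scale for `g` (see
#'   [g_prior_params()]).
#' @param a_omega,b_omega Numeric vectors of length `q`; Beta parameters for
#'   `omega_k` (see [elicit_omega_hyperparams()]).
#' @param d Inverse-Wishart degrees of freedom, default 3.
#' @param c_rho,d_rho Gamma shape and rate for each `rho_j`, default 1.2 and
#'   1.2 so the prior mean is 1.
#' @param max_model_size Cap on the number of predictors per response,
#'   default 15; the effective cap is `min(n - 2, max_model_size)`.
#' @return Object of class `mthess_hyperparams`.
#' @export
hyperparams <- function(h, a_g, b_g, a_omega, b_omega, d = 3,
                        c_rho = 1.2, d_rho = 1.2, max_model_size = 15L) {
  stopifnot(all(h > 0), a_g > 0, b_g > 0, all(a_omega > 0), all(b_omega > 0),
            d > 2, c_rho > 0, d_rho > 0, max_model_size >= 1)
  stopifnot(length(a_omega) == length(h), length(b_omega) == length(h))
  structure(list(d = d, h = h, a_g = a_g, b_g = b_g,
                 a_omega = a_omega, b_omega = b_omega,
                 c_rho = c_rho, d_rho = d_rho,
                 max_model_size = as.integer(max_model_size)),
            class = "mthess_hyperparams")
}

#' Residual cross-product matrix R(gamma)
#'
#' Computes `R(gamma) = Y'Y - Y'X_g (X_g'X_g)^{-1} X_g'Y` for the markers
#' selected by `gamma`: the cross-product of residuals from least-squares
#' regression of each (centered) response column on the selected design.
#'
#' @param Yc Column-centered `n x r` response matrix.
#' @param X `n x p` design matrix (centered or not; only selected columns are
#'   used).
#' @param gamma Binary vector of length `p`, or integer vector of selected
#'   column indices when `indices = TRUE`.
#' @param indices Interpret `gamma` as column indices.
#' @return Symmetric positive semi-definite r-by-r matrix.
#' @export
residual_quadratic <- function(Yc, X, gamma, indices = FALSE) {
  Yc <- as.matrix(Yc)
  yty <- crossprod(Yc)
  sel <- if (indices) as.integer(gamma) else which(gamma != 0)
  if (length(sel) == 0L) return(yty)
  Xg <- X[, sel, drop = FALSE]
  Xg <- center_columns(Xg)
  xtx <- crossprod(Xg)
  ch <- tryCatch(chol(xtx), error = function(e) NULL)
  if (is.null(ch) || any(diag(ch) < sqrt(.Machine$double.eps) * max(diag(ch))))
    stop("singular design: selected markers are collinear")
  xty <- crossprod(Xg, Yc)
  R <- yty - crossprod(backsolve(ch, xty, transpose = TRUE))
  (R + t(R)) / 2
}

#' Log conditional marginal likelihood of one response
#'
#' Closed-form log of `p(Y_k | X, gamma_k, g)` up to an additive constant not
#' depending on `(gamma_k, g)`:
#' \deqn{-\frac{r|\gamma|}{2}\log(1+g) - \frac{d+n+r-2}{2}
#'   \log\det\Big(h_k I_r + \tfrac{1}{1+g} Y_c'Y_c +
#'   \tfrac{g}{1+g} R(\gamma)\Big),}
#' where `Y_c` is the column-centered response stack. This arises from
#' integrating the intercept (flat prior), the effects (g-prior, covariance
#' `g (X_g'X_g)^{-1}` by `Sigma_k`) and the residual covariance
#' (inverse-Wishart with degrees `d` and scale `h_k I_r`).
#'
#' @param Y `n x r` response stack (centered internally).
#' @param X `n x p` design matrix.
#' @param gamma Binary inclusion vector of length `p` (or indices with
#'   `indices = TRUE`).
#' @param g Positive shrinkage factor.
#' @param hp [hyperparams()] object.
#' @param k Response index (selects `h_k`), default 1.
#' @param indices Interpret `gamma` as indices.
#' @return Scalar log marginal likelihood (up to a `(gamma, g)`-free
#'   constant).
#' @export
log_marginal <- function(Y, X, gamma, g, hp, k = 1L, indices = FALSE) {
  stopifnot(g > 0)
  Yc <- center_columns(Y)
  n <- nrow(Yc); r <- ncol(Yc)
  sel <- if (indices) as.integer(gamma) else which(gamma != 0)
  psize <- length(sel)
  yty <- crossprod(Yc)
  R <- if (psize == 0L) yty else residual_quadratic(Yc, X, sel, indices = TRUE)
  M <- hp$h[k] * diag(r) + yty / (1 + g) + (g / (1 + g)) * R
  ch <- chol((M + t(M)) / 2)
  logdet <- 2 * sum(log(diag(ch)))
  -(r * psize / 2) * log1p(g) - ((hp$d + n + r - 2) / 2) * logdet
}

#' Monte-Carlo integration oracle for the marginal likelihood
#'
#' Estimates `log p(Y | X, gamma, g)` by direct Monte-Carlo integration over
#' the effects `B` (g-prior) and the residual covariance `Sigma`
#' (inverse-Wishart), with the intercept integrated analytically by
#' column-centering. Intended as an independent correctness check of
#' [log_marginal()] on tiny problems: only differences across `(gamma, g)`
#' are meaningful, and the analytic intercept integration contributes the
#' same constant to every model.
#'
#' @param Y,X,gamma,g,hp,k,indices As in [log_marginal()].
#' @param n_draws Number of Monte-Carlo draws.
#' @param seed Optional seed applied locally.
#' @return List with `estimate` (log of the mean integrand, plus the same
#'   centering constant for every model) and `se` (delta-method standard
#'   error of the log estimate).
#' @export
oracle_log_marginal_mc <- function(Y, X, gamma, g, hp, k = 1L,
                                   n_draws = 1e5, seed = NULL,
                                   indices = FALSE) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  Yc <- center_columns(Y)
  n <- nrow(Yc); r <- ncol(Yc)
  stopifnot(n <= 8, r <= 3)
  sel <- if (indices) as.integer(gamma) else which(gamma != 0)
  psize <- length(sel)
  stopifnot(psize <= 2)
  Xg <- if (psize) center_columns(X[, sel, drop = FALSE]) else NULL
  # Sigma ~ IW with degrees d: standard shape nu = d + r - 1, scale h_k I_r
  nu <- hp$d + r - 1
  hI_inv <- diag(r) / hp$h[k]
  V <- if (psize) g * solve(crossprod(Xg)) else NULL
  Tv <- if (psize) t(chol(V)) else NULL          # lower factor of V
  # log N(Yc | Xg B, P, Sigma) after integrating the intercept: effective
  # rank n-1 in the row space; the n-dependent constant is model-free.
  logw <- if (r <= 2 && psize <= 2) {
    .oracle_logw_vec(Yc, Xg, Tv, nu, hI_inv, n_draws)
  } else {
    out <- numeric(n_draws)
    W <- stats::rWishart(n_draws, df = nu, Sigma = hI_inv)
    for (it in seq_len(n_draws)) {
      Sigma <- solve(W[, , it])
      cholS <- chol(Sigma)
      Resid <- Yc
      if (psize) {
        B <- Tv %*% matrix(stats::rnorm(psize * r), psize, r) %*% cholS
        Resid <- Yc - Xg %*% B
      }
      out[it] <- -((n - 1) / 2) * 2 * sum(log(diag(cholS))) -
        0.5 * sum(W[, , it] * crossprod(Resid))
    }
    out
  }
  m <- max(logw)
  w <- exp(logw - m)
  est <- m + log(mean(w))
  se <- stats::sd(w) / (mean(w) * sqrt(n_draws))
  list(estimate = est, se = se)
}

# vectorized Monte-Carlo integrand for r <= 2, |gamma| <= 2: all draw-wise
# quantities are computed with componentwise vector arithmetic
.oracle_logw_vec <- function(Yc, Xg, Tv, nu, hI_inv, n_draws) {
  n <- nrow(Yc); r <- ncol(Yc)
  s <- if (is.null(Xg)) 0L else ncol(Xg)
  W <- stats::rWishart(n_draws, df = nu, Sigma = hI_inv)
  if (r == 1L) {
    w11 <- W[1, 1, ]
    logdet_sigma <- -log(w11)
  } else {
    w11 <- W[1, 1, ]; w12 <- W[1, 2, ]; w22 <- W[2, 2, ]
    dW <- w11 * w22 - w12^2
    logdet_sigma <- -log(dW)
    # upper Cholesky factor U of Sigma = W^{-1} (U'U = Sigma)
    S11 <- w22 / dW; S12 <- -w12 / dW; S22 <- w11 / dW
    U11 <- sqrt(S11); U12 <- S12 / U11; U22 <- sqrt(S22 - U12^2)
  }
  if (s == 0L) {
    Q <- crossprod(Yc)
    trWQ <- if (r == 1L) w11 * Q[1, 1] else
      w11 * Q[1, 1] + 2 * w12 * Q[1, 2] + w22 * Q[2, 2]
    return(-((n - 1) / 2) * logdet_sigma - 0.5 * trWQ)
  }
  # B = Tv Z U: components b[i,j] as length-n_draws vectors
  Z <- array(stats::rnorm(s * r * n_draws), dim = c(s, r, n_draws))
  A <- array(0, dim = c(s, r, n_draws))          # A = Tv Z
  for (i in seq_len(s)) for (j in seq_len(r))
    for (l in seq_len(i)) A[i, j, ] <- A[i, j, ] + Tv[i, l] * Z[l, j, ]
  B <- array(0, dim = c(s, r, n_draws))          # B = A U
  if (r == 1L) {
    for (i in seq_len(s)) B[i, 1, ] <- A[i, 1, ] / sqrt(w11)
  } else {
    for (i in seq_len(s)) {
      B[i, 1, ] <- A[i, 1, ] * U11
      B[i, 2, ] <- A[i, 1, ] * U12 + A[i, 2, ] * U22
    }
  }
  # residual quadratic Q_jl = y_j'y_l - b_j't_l - b_l't_j + b_j'G b_l
  G <- crossprod(Xg)                              # s x s
  Tt <- crossprod(Xg, Yc)                         # s x r
  yty <- crossprod(Yc)                            # r x r
  Qel <- function(j, l) {
    bj <- B[, j, , drop = FALSE]; bl <- B[, l, , drop = FALSE]
    out <- rep(yty[j, l], n_draws)
    for (i in seq_len(s)) out <- out - bj[i, 1, ] * Tt[i, l] -
        bl[i, 1, ] * Tt[i, j]
    for (i in seq_len(s)) for (m2 in seq_len(s))
      out <- out + bj[i, 1, ] * G[i, m2] * bl[m2, 1, ]
    out
  }
  trWQ <- if (r == 1L) w11 * Qel(1, 1) else
    w11 * Qel(1, 1) + 2 * w12 * Qel(1, 2) + w22 * Qel(2, 2)
  -((n - 1) / 2) * logdet_sigma - 0.5 * trWQ
}
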