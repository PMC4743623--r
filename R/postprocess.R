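#' Marginal posterior probabilities of inclusion
#'
#' MPPI for pair (k, j) is the fraction of recorded (post-burn-in,
#' cold-chain) sweeps in which `gamma_kj = 1`.
#'
#' @param trace An `mthess_trace` from [run_sampler()].
#' @return `q x p` matrix with entries in `[0, 1]`.
#' @export
compute_mppi <- function(trace) {
  stopifnot(inherits(trace, "mthess_trace"))
  if (trace$recorded_sweeps < 1) stop("trace has no recorded sweeps")
  m <- trace$inclusion_counts / trace$recorded_sweeps
  dimnames(m) <- list(trace$response_ids, trace$marker_ids)
  m
}

#' Bayesian false discovery rate at a threshold
#'
#' `bFDR(c) = sum (1 - pi) I[pi > c] / sum I[pi > c]`: the mean posterior
#' probability of being a false call among the pairs whose MPPI exceeds the
#' threshold. Returns 0 (with a warning) when no MPPI exceeds `c`.
#'
#' @param mppi Numeric vector or matrix of MPPI values.
#' @param c Threshold in `[0, 1)`.
#' @return Scalar bFDR.
#' @export
bayes_fdr <- function(mppi, c) {
  stopifnot(c >= 0, c < 1)
  pi <- as.numeric(mppi)
  sel <- pi > c
  if (!any(sel)) {
    warning("no MPPI exceeds the threshold; bFDR defined as 0")
    return(0)
  }
  sum(1 - pi[sel]) / sum(sel)
}

#' MPPI threshold achieving a target Bayesian FDR
#'
#' Scans the observed MPPI values as candidate thresholds and returns the
#' smallest (most permissive) one whose bFDR is at or below the target. The
#' declared set is every pair with MPPI strictly above the returned
#' threshold.
#'
#' @param mppi Numeric vector or matrix of MPPI values.
#' @param target Required bFDR level in (0, 1).
#' @return List with `threshold` (or `NA` when no threshold attains the
#'   target — "no calls"), `bfdr` at that threshold, and `n_called`.
#' @export
threshold_for_bfdr <- function(mppi, target) {
  stopifnot(target > 0, target < 1)
  pi <- as.numeric(mppi)
  cand <- sort(unique(pi))
  # thresholding strictly above; candidate cut just below each distinct value
  cand <- c(0, cand)
  for (c in cand) {
    if (!any(pi > c)) next
    b <- sum((1 - pi)[pi > c]) / sum(pi > c)
    if (b <= target)
      return(list(threshold = c, bfdr = b, n_called = sum(pi > c)))
  }
  list(threshold = NA_real_, bfdr = NA_real_, n_called = 0L)
}

#' Tabulate associations called at a threshold
#'
#' @param mppi `q x p` MPPI matrix (from [compute_mppi()]).
#' @param threshold MPPI threshold; pairs strictly above it are called.
#' @return Data frame with columns `response_id`, `marker_id`, `mppi`,
#'   `called`, `threshold_used`, sorted by decreasing MPPI.
#' @export
association_calls <- function(mppi, threshold) {
  q <- nrow(mppi); p <- ncol(mppi)
  rid <- rownames(mppi); if (is.null(rid)) rid <- paste0("Y", seq_len(q))
  mid <- colnames(mppi); if (is.null(mid)) mid <- paste0("M", seq_len(p))
  df <- data.frame(response_id = rep(rid, times = p),
                   marker_id = rep(mid, each = q),
                   mppi = as.numeric(mppi),
                   stringsAsFactors = FALSE)
  df$called <- df$mppi > threshold
  df$threshold_used <- threshold
  df[order(-df$mppi), ]
}

#' Hotspot table: number of responses called per marker
#'
#' Counts, for each marker, the responses whose association with it is
#' called at the given threshold, and sorts the markers by decreasing count
#' (ties keep marker order).
#'
#' @param calls Data frame from [association_calls()].
#' @return Data frame with columns `marker_id`, `n_responses`.
#' @export
hotspot_table <- function(calls) {
  stopifnot(all(c("marker_id", "called") %in% names(calls)))
  ids <- unique(calls$marker_id)
  cnt <- vapply(ids, function(m)
    sum(calls$called[calls$marker_id == m]), integer(1))
  df <- data.frame(marker_id = ids, n_responses = cnt,
                   stringsAsFactors = FALSE)
  df[order(-df$n_responses), ]
}

# score every visited model of response k at posterior means of (omega, rho, g)
.visited_scores <- function(trace, X, Y, k) {
  Xm <- if (inherits(X, "genotype_panel")) X$values else as.matrix(X)
  stacks <- if (inherits(Y, "response_panel")) Y$stacks else Y
  vm <- trace$visited_models[[k]]
  if (length(vm$model) == 0L) stop("no visited models recorded for response")
  om <- if (!is.null(trace$fixed$omega)) rep_len(trace$fixed$omega, trace$q)[k]
        else trace$omega_mean[k]
  rho <- if (!is.null(trace$fixed$rho)) rep_len(trace$fixed$rho, trace$p)
         else as.numeric(trace$rho_mean)
  g <- if (!is.null(trace$fixed$g)) trace$fixed$g else trace$g_mean
  sels <- lapply(vm$model, function(s)
    if (nzchar(s)) as.integer(strsplit(s, ",")[[1]]) else integer(0))
  scores <- vapply(seq_along(sels), function(i) {
    sel <- sels[[i]]
    gam <- integer(trace$p); gam[sel] <- 1L
    ml <- tryCatch(log_marginal(stacks[[k]], Xm, sel, g, trace$hp, k,
                                indices = TRUE), error = function(e) -Inf)
    ml + log_prior_gamma_row(gam, om, rho)
  }, numeric(1))
  list(sels = sels, scores = scores, counts = vm$count)
}

#' Best model visited for one response
#'
#' Returns the visited inclusion vector with the highest log posterior score
#' (marginal likelihood plus row prior, evaluated at the posterior means of
#' `omega_k`, `rho` and `g`). Ties are broken in favour of the smaller
#' model, then lexicographically.
#'
#' @param trace An `mthess_trace`.
#' @param X,Y The data the trace was computed from.
#' @param k Response index.
#' @return List with `included` (binary length-p vector), `indices`, `size`
#'   and `score`.
#' @export
best_model <- function(trace, X, Y, k) {
  vs <- .visited_scores(trace, X, Y, k)
  ord <- order(-vs$scores,
               vapply(vs$sels, length, 1L),
               vapply(vs$sels, function(s) paste(sprintf("%06d", s),
                                                 collapse = ","), ""))
  best <- ord[1L]
  sel <- vs$sels[[best]]
  gam <- integer(trace$p); gam[sel] <- 1L
  list(included = gam, indices = sel, size = length(sel),
       score = vs$scores[best])
}

#' Re-normalized posterior model probabilities
#'
#' Exponentiates the log posterior score of every model visited for response
#' `k` and normalizes over the visited set.
#'
#' @inheritParams best_model
#' @return Data frame with columns `model` (comma-separated 1-based marker
#'   indices; empty string for the null model), `visits`, `prob`, sorted by
#'   decreasing probability.
#' @export
renormalized_model_probs <- function(trace, X, Y, k) {
  vs <- .visited_scores(trace, X, Y, k)
  w <- exp(vs$scores - max(vs$scores[is.finite(vs$scores)]))
  w[!is.finite(w)] <- 0
  pr <- w / sum(w)
  df <- data.frame(model = vapply(vs$sels, paste, "", collapse = ","),
                   visits = vs$counts, prob = pr,
                   stringsAsFactors = FALSE)
  df[order(-df$prob), ]
}

#' Leave-one-out model-adequacy check for one response
#'
#' For each held-out individual `i` and condition, draws from the posterior
#' predictive density of `y_ik` given the remaining individuals and the best
#' model: `g` is integrated numerically by sampling from its posterior draws,
#' the residual covariance from its conjugate inverse-Wishart conditional,
#' the effects from the conjugate matrix-normal conditional, and the
#' intercept from its flat-prior conditional. The checking function is the
#' standardized prediction error (observed minus predictive mean, divided by
#' the predictive standard deviation); the adequacy score is its sum of
#' squares over individuals and conditions, so under a well-specified model
#' it is approximately `n * r`.
#'
#' @param X,Y Data (genotype panel / response panel or bare matrices/list).
#' @param trace An `mthess_trace` (provides posterior `g` draws).
#' @param k Response index.
#' @param best Optional model as returned by [best_model()]; computed when
#'   omitted.
#' @param n_draws Posterior predictive draws per held-out observation,
#'   default 200.
#' @return List with `per_observation` (`n x r` standardized errors, using
#'   predictive means/SDs) and `adequacy` (sum of squared standardized
#'   errors).
#' @export
loo_checking_function <- function(X, Y, trace, k, best = NULL,
                                  n_draws = 200L) {
  Xm <- if (inherits(X, "genotype_panel")) X$values else as.matrix(X)
  stacks <- if (inherits(Y, "response_panel")) Y$stacks else Y
  Yk <- stacks[[k]]
  n <- nrow(Yk); r <- ncol(Yk)
  if (is.null(best)) best <- best_model(trace, X, Y, k)
  sel <- best$indices
  if (n < length(sel) + 3L) stop("too few observations for leave-one-out")
  hp <- trace$hp
  gs <- trace$g_samples
  if (!length(gs)) gs <- trace$g_mean
  nu0 <- hp$d + r - 1
  err <- matrix(NA_real_, n, r)
  for (i in seq_len(n)) {
    idx <- setdiff(seq_len(n), i)
    m <- length(idx)
    Ytr <- Yk[idx, , drop = FALSE]
    ybar <- colMeans(Ytr)
    Yc <- sweep(Ytr, 2L, ybar, "-")
    yty <- crossprod(Yc)
    if (length(sel)) {
      Xtr <- Xm[idx, sel, drop = FALSE]
      xbar <- colMeans(Xtr)
      Xc <- sweep(Xtr, 2L, xbar, "-")
      xtx <- crossprod(Xc)
      xtx_inv <- solve(xtx)
      xty <- crossprod(Xc, Yc)
      Rq <- yty - crossprod(xty, xtx_inv %*% xty)
      xi <- Xm[i, sel] - xbar
    }
    draws <- matrix(NA_real_, n_draws, r)
    gdraw <- sample(gs, n_draws, replace = TRUE)
    for (s in seq_len(n_draws)) {
      g <- gdraw[s]
      Sg <- if (length(sel)) yty / (1 + g) + (g / (1 + g)) * Rq else yty
      Psi <- hp$h[k] * diag(r) + Sg
      nu <- nu0 + m - 1
      Sigma <- solve(stats::rWishart(1, nu, solve(Psi))[, , 1])
      cholS <- chol((Sigma + t(Sigma)) / 2)
      mu <- ybar + crossprod(cholS, stats::rnorm(r)) / sqrt(m)  # intercept
      if (length(sel)) {
        Bstar <- (g / (1 + g)) * xtx_inv %*% xty
        chV <- chol((g / (1 + g)) * xtx_inv)
        Bdraw <- Bstar + crossprod(chV,
                   matrix(stats::rnorm(length(sel) * r), length(sel), r)) %*%
                 cholS
        mu <- mu + crossprod(Bdraw, xi)
      }
      draws[s, ] <- mu + crossprod(cholS, stats::rnorm(r))
    }
    err[i, ] <- (Yk[i, ] - colMeans(draws)) / apply(draws, 2L, stats::sd)
  }
  list(per_observation = err, adequacy = sum(err^2))
}

#' Model adequacy across responses
#'
#' Applies [loo_checking_function()] to each requested response and returns
#' the per-response adequacy scores (sums of squared standardized
#' leave-one-out prediction errors).
#'
#' @inheritParams loo_checking_function
#' @param responses Response indices, default all.
#' @return Named numeric vector of adequacy scores.
#' @export
model_adequacy <- function(X, Y, trace, responses = NULL, n_draws = 200L) {
  if (is.null(responses)) responses <- seq_len(trace$q)
  out <- vapply(responses, function(k)
    loo_checking_function(X, Y, trace, k, n_draws = n_draws)$adequacy,
    numeric(1))
  names(out) <- trace$response_ids[responses]
  out
}
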