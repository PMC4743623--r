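#' MANOVA test of one response stack against one marker
#'
#' Wilks'-lambda MANOVA of the r-variate response on a single regressor
#' (with intercept). With one regressor the Rao F transform is exact:
#' `F = ((1 - L)/L) * (n - r - 1)/r` on `(r, n - r - 1)` degrees of
#' freedom; for r = 1 this is the usual one-regressor ANOVA F test.
#'
#' @param Yk `n x r` response stack.
#' @param xj Length-n regressor; must be non-constant.
#' @return P-value.
#' @export
manova_pair_test <- function(Yk, xj) {
  Yk <- as.matrix(Yk)
  n <- nrow(Yk); r <- ncol(Yk)
  if (n <= r + 2) stop("need n > r + 2 for the MANOVA F approximation")
  if (stats::var(xj) == 0) stop("constant regressor: MANOVA undefined")
  Yc <- center_columns(Yk)
  xc <- xj - mean(xj)
  E_tot <- crossprod(Yc)
  bhat <- crossprod(Yc, xc) / sum(xc^2)
  Eres <- E_tot - tcrossprod(bhat) * sum(xc^2)
  L <- det(Eres) / det(E_tot)
  L <- min(max(L, .Machine$double.xmin), 1)
  Fstat <- (1 - L) / L * (n - r - 1) / r
  stats::pf(Fstat, r, n - r - 1, lower.tail = FALSE)
}

#' MANOVA p-values for every response-marker pair
#'
#' Vectorized sweep of [manova_pair_test()] over all `q x p` pairs.
#' Constant markers receive `NA`.
#'
#' @param X Genotype panel or `n x p` matrix.
#' @param Y Response panel or list of stacks.
#' @return A score-matrix object (see [score_matrix()]) holding
#'   `-log10(p)`, higher is stronger.
#' @export
manova_scores <- function(X, Y) {
  Xm <- if (inherits(X, "genotype_panel")) X$values else as.matrix(X)
  stacks <- if (inherits(Y, "response_panel")) Y$stacks else Y
  q <- length(stacks); p <- ncol(Xm); n <- nrow(Xm)
  r <- ncol(stacks[[1]])
  Xc <- center_columns(Xm)
  ss_x <- colSums(Xc^2)
  pv <- matrix(NA_real_, q, p)
  for (k in seq_len(q)) {
    Yc <- center_columns(stacks[[k]])
    E_tot <- crossprod(Yc)
    det_tot <- det(E_tot)
    XtY <- crossprod(Xc, Yc)               # p x r
    for (j in seq_len(p)) {
      if (ss_x[j] == 0) next
      b <- XtY[j, ] / ss_x[j]
      Eres <- E_tot - tcrossprod(b) * ss_x[j]
      L <- min(max(det(Eres) / det_tot, .Machine$double.xmin), 1)
      Fstat <- (1 - L) / L * (n - r - 1) / r
      pv[k, j] <- stats::pf(Fstat, r, n - r - 1, lower.tail = FALSE)
    }
  }
  score_matrix(-log10(pmax(pv, .Machine$double.xmin)),
               method_name = "MANOVA")
}

#' Score matrix container
#'
#' Holds a `q x p` matrix of association scores with its orientation
#' (whether larger values mean stronger evidence) and the method name.
#'
#' @param values `q x p` numeric matrix.
#' @param higher_is_stronger Orientation flag, default TRUE.
#' @param method_name Label.
#' @return Object of class `mthess_scores`.
#' @export
score_matrix <- function(values, higher_is_stronger = TRUE,
                         method_name = "scores") {
  values <- as.matrix(values)
  structure(list(values = values, higher_is_stronger = higher_is_stronger,
                 method_name = method_name),
            class = "mthess_scores")
}

#' Single-tissue HESS run
#'
#' Runs the sampler on one condition slice (r = 1; the model specializes
#' automatically) and returns the MPPI score matrix.
#'
#' @param X Genotype panel or matrix.
#' @param Y Response panel.
#' @param condition Condition index to slice out.
#' @param prior [prior_spec()]-style expected model size/variance; passed to
#'   [default_hyperparams()].
#' @param cfg,ladder Sampler configuration.
#' @param h_mode `"empirical"` or a fixed numeric value for all `h_k`.
#' @return An `mthess_scores` MPPI matrix.
#' @export
run_st_hess <- function(X, Y, condition, prior = list(e = 1, v = 4),
                        cfg = sampler_config(), ladder = ladder_config(),
                        h_mode = "empirical") {
  stopifnot(inherits(Y, "response_panel"))
  slice <- lapply(Y$stacks, function(m) m[, condition, drop = FALSE])
  Ys <- response_panel(slice, response_ids = Y$response_ids,
                       condition_ids = Y$condition_ids[condition],
                       sample_ids = Y$sample_ids)
  hp <- default_hyperparams(X, Ys, e_gamma = prior$e, v_gamma = prior$v,
                            h_mode = h_mode)
  tr <- run_sampler(X, Ys, hp, cfg, ladder)
  score_matrix(compute_mppi(tr),
               method_name = sprintf("ST-HESS[%s]",
                                     Y$condition_ids[condition]))
}

#' Intersection scores across single-tissue runs
#'
#' The intersection rule declares a pair at threshold `c` only when every
#' tissue's MPPI exceeds `c`; thresholding the elementwise minimum across
#' tissues is exactly equivalent.
#'
#' @param score_list List of `mthess_scores` (or matrices) of identical
#'   shape, one per tissue.
#' @return An `mthess_scores` with the elementwise minimum.
#' @export
ist_hess_scores <- function(score_list) {
  stopifnot(length(score_list) >= 2L)
  mats <- lapply(score_list, function(s)
    if (inherits(s, "mthess_scores")) s$values else as.matrix(s))
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) identical(dim(m), d), logical(1))))
    stop("score matrices differ in shape")
  mn <- Reduce(pmin, mats)
  score_matrix(mn, method_name = "iST-HESS")
}

# oriented scores as a plain matrix, larger = stronger
.oriented <- function(scores) {
  if (inherits(scores, "mthess_scores")) {
    v <- scores$values
    if (!scores$higher_is_stronger) v <- -v
    v
  } else as.matrix(scores)
}

#' ROC curve of a score matrix against the simulation truth
#'
#' Sweeps every distinct score value as a threshold; TPR over all true
#' pairs, FPR over all true negatives.
#'
#' @param scores `mthess_scores` or matrix (higher = stronger).
#' @param truth `mthess_sim_truth`.
#' @return Data frame with columns `fpr`, `tpr` (monotone staircase,
#'   including the (0,0) and (1,1) endpoints) and attribute `auc`.
#' @export
roc_points <- function(scores, truth) {
  s <- as.numeric(.oriented(scores))
  y <- as.numeric(truth$gamma_true)
  stopifnot(length(s) == length(y))
  ord <- order(-s)
  y <- y[ord]; s <- s[ord]
  tp <- cumsum(y); fp <- cumsum(1 - y)
  P <- sum(y); N <- length(y) - P
  # collapse tied scores: keep the last index of each tied block
  keep <- c(diff(s) != 0, TRUE)
  tpr <- c(0, tp[keep] / P); fpr <- c(0, fp[keep] / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  out <- data.frame(fpr = fpr, tpr = tpr)
  attr(out, "auc") <- auc
  out
}

#' Threshold calibrated to a realized (true) FDR level
#'
#' Evaluation-only device that uses the simulation ground truth: returns the
#' most permissive threshold whose realized false discovery proportion
#' `FP / (FP + TP)` is at or below `level`. Tied scores are called
#' all-or-none. Returns `NA` ("no calls") when no cut attains the level.
#'
#' @param scores `mthess_scores` or matrix.
#' @param truth `mthess_sim_truth`.
#' @param level Target realized FDR, e.g. 0.1.
#' @return List with `threshold` (call strictly above it), `fdr`,
#'   `n_called`.
#' @export
true_fdr_threshold <- function(scores, truth, level) {
  s <- as.numeric(.oriented(scores))
  y <- as.numeric(truth$gamma_true)
  if (sum(y) == 0) stop("truth contains no positive pair")
  ord <- order(-s)
  ys <- y[ord]; ss <- s[ord]
  tp <- cumsum(ys); fp <- cumsum(1 - ys)
  keep <- which(c(diff(ss) != 0, TRUE))    # whole tied blocks
  fdr <- fp[keep] / pmax(fp[keep] + tp[keep], 1)
  ok <- which(fdr <= level & tp[keep] > 0)
  if (!length(ok)) return(list(threshold = NA_real_, fdr = NA_real_,
                               n_called = 0L))
  i <- keep[max(ok)]
  # threshold strictly below the last called (tied) block so that
  # "score > threshold" reproduces exactly the admissible call set
  thr <- if (i < length(ss)) (ss[i] + ss[i + 1]) / 2 else ss[i] - 1
  called <- s > thr
  list(threshold = thr,
       fdr = sum(called & y == 0) / max(sum(called), 1),
       n_called = sum(called))
}

#' Classification table at a true-FDR-calibrated threshold
#'
#' Cross-tabulates called status against the four truth classes
#' (negative, cis isolated, cis other, trans) at the threshold returned by
#' [true_fdr_threshold()].
#'
#' @param scores,truth,level As in [true_fdr_threshold()].
#' @return List with `counts` (2 x 4 matrix, rows negative/positive call),
#'   `threshold`, `fdr_level`.
#' @export
classification_table <- function(scores, truth, level) {
  thr <- true_fdr_threshold(scores, truth, level)
  s <- .oriented(scores)
  called <- if (is.na(thr$threshold)) matrix(FALSE, nrow(s), ncol(s))
            else s > thr$threshold
  classes <- c("negative", "cis_isolated", "cis_other", "trans")
  counts <- matrix(0, 2, 4, dimnames = list(c("negative_call",
                                              "positive_call"), classes))
  for (ci in seq_along(classes)) {
    in_class <- truth$class_labels == classes[ci]
    counts[1, ci] <- sum(in_class & !called)
    counts[2, ci] <- sum(in_class & called)
  }
  list(counts = counts, threshold = thr$threshold, fdr_level = level)
}

#' Average declared hotspot sizes
#'
#' For each true hotspot marker, counts the responses called at that marker
#' at the true-FDR-calibrated threshold and averages the counts within each
#' true size class.
#'
#' @param scores,truth,level As in [true_fdr_threshold()].
#' @return Data frame with columns `true_size`, `mean_called` (one row per
#'   distinct true hotspot size), plus `per_hotspot` attribute with the raw
#'   per-marker counts.
#' @export
hotspot_size_summary <- function(scores, truth, level) {
  thr <- true_fdr_threshold(scores, truth, level)
  s <- .oriented(scores)
  called <- if (is.na(thr$threshold)) matrix(FALSE, nrow(s), ncol(s))
            else s > thr$threshold
  per <- vapply(truth$hotspot_markers, function(j) sum(called[, j]),
                numeric(1))
  sizes <- truth$hotspot_sizes
  agg <- tapply(per, sizes, mean)
  out <- data.frame(true_size = as.integer(names(agg)),
                    mean_called = as.numeric(agg))
  attr(out, "per_hotspot") <- per
  out
}

#' Default hyperparameters for a dataset
#'
#' Elicits the Beta parameters of the sparsity probabilities from the
#' expected model size and variance, sets the q-adapted Zellner--Siow
#' inverse-gamma prior on `g`, and chooses `h_k` either empirically (median
#' stepwise residual variance across conditions) or at a fixed value.
#'
#' @param X Genotype panel or matrix.
#' @param Y Response panel or list of stacks.
#' @param e_gamma,v_gamma Prior expected model size and variance (scalar or
#'   per-response), defaults 1 and 4.
#' @param h_mode `"empirical"` or a positive number used for every `h_k`.
#' @param d,c_rho,d_rho,max_model_size Passed to [hyperparams()].
#' @return An [hyperparams()] object.
#' @export
default_hyperparams <- function(X, Y, e_gamma = 1, v_gamma = 4,
                                h_mode = "empirical", d = 3,
                                c_rho = 1.2, d_rho = 1.2,
                                max_model_size = 15L) {
  Xm <- if (inherits(X, "genotype_panel")) X$values else as.matrix(X)
  stacks <- if (inherits(Y, "response_panel")) Y$stacks else Y
  q <- length(stacks); n <- nrow(Xm); p <- ncol(Xm)
  spec <- prior_spec(e_gamma, v_gamma, n, q, p)
  ab <- elicit_omega_hyperparams(spec)
  gp <- g_prior_params(n, q)
  if (identical(h_mode, "empirical")) {
    Yp <- if (inherits(Y, "response_panel")) Y else response_panel(stacks)
    Xp <- if (inherits(X, "genotype_panel")) X else genotype_panel(Xm)
    h <- vapply(seq_len(q), function(k) empirical_h(Yp, Xp, k), numeric(1))
  } else {
    stopifnot(is.numeric(h_mode), h_mode > 0)
    h <- rep(as.numeric(h_mode), q)
  }
  hyperparams(h = h, a_g = gp[["a_g"]], b_g = gp[["b_g"]],
              a_omega = ab$a_omega, b_omega = ab$b_omega, d = d,
              c_rho = c_rho, d_rho = d_rho, max_model_size = max_model_size)
}

#' Run the full evaluation harness on one simulated replicate
#'
#' Simulates one dataset, runs the multi-tissue sampler, the per-tissue
#' single-tissue runs (intersected), and the pairwise MANOVA, and returns
#' score matrices with the truth.
#'
#' @param cfg A [sim_config()].
#' @param sampler_cfg,ladder Sampler settings for the multi-tissue run.
#' @param st_sampler_cfg Sampler settings for the per-tissue runs; defaults
#'   to `sampler_cfg`.
#' @param methods Character subset of `c("mt", "ist", "manova")`.
#' @param prior Expected model size/variance list as in [run_st_hess()].
#' @param h_mode Passed to [default_hyperparams()].
#' @return List with `scores` (named list of `mthess_scores`), `truth`,
#'   `data`.
#' @export
run_benchmark_replicate <- function(cfg, sampler_cfg = sampler_config(),
                                    ladder = ladder_config(),
                                    methods = c("mt", "ist", "manova"),
                                    prior = list(e = 1, v = 4),
                                    h_mode = "empirical",
                                    st_sampler_cfg = sampler_cfg) {
  dat <- simulate_dataset(cfg)
  scores <- list()
  if ("mt" %in% methods) {
    hp <- default_hyperparams(dat$X, dat$Y, e_gamma = prior$e,
                              v_gamma = prior$v, h_mode = h_mode)
    tr <- run_sampler(dat$X, dat$Y, hp, sampler_cfg, ladder)
    scores$mt <- score_matrix(compute_mppi(tr), method_name = "MT-HESS")
  }
  if ("ist" %in% methods) {
    per_tissue <- lapply(seq_len(dat$Y$r), function(l) {
      cfg_l <- st_sampler_cfg
      cfg_l$seed <- st_sampler_cfg$seed + l
      run_st_hess(dat$X, dat$Y, l, prior = prior, cfg = cfg_l,
                  ladder = ladder, h_mode = h_mode)
    })
    scores$ist <- ist_hess_scores(per_tissue)
    scores$st <- per_tissue
  }
  if ("manova" %in% methods) scores$manova <- manova_scores(dat$X, dat$Y)
  list(scores = scores, truth = dat$truth, data = dat)
}
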