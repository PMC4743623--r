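#' Simulation configuration
#'
#' Defaults reproduce the multi-tissue simulation design: 29 recombinant
#' inbred individuals, 1304 markers over 20 chromosomes, 150 responses in 3
#' conditions, effect sizes drawn around `mu` with SD 0.001, per-condition
#' total noise SD 0.1 and no shared noise. The `cis_trans` pattern has six
#' hotspot markers (two each with 10, 20 and 30 associated responses,
#' scaled proportionally when `q` differs from 150) plus 10 cis markers, of
#' which half hit otherwise-unassociated responses; the `hotspots` pattern
#' has the six hotspots only.
#'
#' @param n,p,q,r Individuals, markers, responses, conditions.
#' @param n_chrom Number of chromosomes for the genotype simulator.
#' @param switch_prob Per-adjacent-marker recombination probability `theta`.
#' @param mu Signal mean for the `hotspots` pattern (all effects).
#' @param mu_cis,mu_trans Signal means for the `cis_trans` pattern.
#' @param lambda_sd SD of effect sizes around their class mean.
#' @param sigma_total Length-r total noise SDs per condition.
#' @param sigma_shared Shared (between-condition) noise SD; must not exceed
#'   any total SD.
#' @param pattern `"cis_trans"` or `"hotspots"`.
#' @param seed Integer seed.
#' @return Object of class `mthess_sim_config`.
#' @export
sim_config <- function(n = 29L, p = 1304L, q = 150L, r = 3L, n_chrom = 20L,
                       switch_prob = 0.05, mu = 0.15, mu_cis = 0.6,
                       mu_trans = 0.15, lambda_sd = 0.001,
                       sigma_total = rep(0.1, r), sigma_shared = 0,
                       pattern = c("cis_trans", "hotspots"), seed = 1L) {
  pattern <- match.arg(pattern)
  sigma_total <- rep_len(sigma_total, r)
  stopifnot(n >= 3, p >= 2, q >= 1, r >= 1, n_chrom >= 1,
            switch_prob >= 0, switch_prob <= 0.5,
            all(sigma_total >= 0), sigma_shared >= 0, lambda_sd >= 0)
  if (sigma_shared > min(sigma_total) + 1e-12)
    stop("sigma_shared must not exceed any total noise SD")
  structure(list(n = as.integer(n), p = as.integer(p), q = as.integer(q),
                 r = as.integer(r), n_chrom = as.integer(n_chrom),
                 switch_prob = switch_prob, mu = mu, mu_cis = mu_cis,
                 mu_trans = mu_trans, lambda_sd = lambda_sd,
                 sigma_total = sigma_total, sigma_shared = sigma_shared,
                 pattern = pattern, seed = as.integer(seed)),
            class = "mthess_sim_config")
}

#' Simulate a recombinant-inbred genotype panel
#'
#' Genotypes are binary: per individual and chromosome, the first marker is
#' Bernoulli(0.5) and each subsequent marker flips with probability
#' `switch_prob`, independently across chromosomes and individuals. This is
#' a two-state Markov chain whose adjacent-marker correlation is
#' `1 - 2 theta`, a qualitative surrogate for the block-wise linkage
#' disequilibrium of a real RI panel. Redundant markers (duplicate or
#' perfectly anticorrelated columns) are removed and replaced until `p`
#' unique markers survive.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_panel()] with `marker_pos` carrying chromosome
#'   assignments.
#' @export
simulate_ri_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "mthess_sim_config"))
  per_chrom <- ceiling(cfg$p / cfg$n_chrom)
  extend_chrom <- function(G, m) {
    # append m markers continuing the Markov chain from the last column
    n <- nrow(G)
    start <- if (ncol(G)) G[, ncol(G)] else stats::rbinom(n, 1, 0.5)
    out <- matrix(0L, n, m)
    prev <- start
    for (j in seq_len(m)) {
      if (ncol(G) == 0L && j == 1L) {
        out[, j] <- prev
      } else {
        flip <- stats::rbinom(n, 1, cfg$switch_prob)
        out[, j] <- ifelse(flip == 1L, 1L - prev, prev)
      }
      prev <- out[, j]
    }
    cbind(G, out)
  }
  chrom_mats <- lapply(seq_len(cfg$n_chrom), function(ch)
    extend_chrom(matrix(0L, cfg$n, 0), per_chrom))
  assemble <- function(mats) {
    X <- do.call(cbind, mats)
    chroms <- rep(seq_along(mats), vapply(mats, ncol, 1L))
    pan <- genotype_panel(X, marker_pos = data.frame(chrom = chroms,
                                                     pos = seq_along(chroms)))
    dedupe_markers(pan)
  }
  pan <- assemble(chrom_mats)
  guard <- 0L
  while (ncol(pan$values) < cfg$p && guard < 50L) {
    need <- cfg$p - ncol(pan$values)
    extra_per <- ceiling(need / cfg$n_chrom) + 1L
    chrom_mats <- lapply(chrom_mats, extend_chrom, m = extra_per)
    pan <- assemble(chrom_mats)
    guard <- guard + 1L
  }
  keep <- seq_len(min(cfg$p, ncol(pan$values)))
  genotype_panel(pan$values[, keep, drop = FALSE],
                 sample_ids = paste0("S", seq_len(cfg$n)),
                 marker_ids = paste0("M", keep),
                 marker_pos = data.frame(
                   chrom = pan$marker_pos$chrom[keep],
                   pos = seq_along(keep)))
}

#' Build the true association pattern
#'
#' Lays out the ground-truth inclusion matrix and the class label of every
#' response-marker pair: `negative`, `cis_isolated` (cis association on an
#' otherwise-unassociated response), `cis_other` (cis association on a
#' response that is also in a hotspot block) or `trans` (part of a hotspot).
#' Hotspot markers are placed one per chromosome where possible; cis markers
#' go on chromosomes without hotspots.
#'
#' @param cfg A [sim_config()].
#' @param panel A [genotype_panel()] with `marker_pos` (for chromosome-aware
#'   placement); optional.
#' @return List (`mthess_sim_truth` skeleton) with `gamma_true` (`q x p`),
#'   `class_labels` (`q x p` character matrix), `hotspot_markers`,
#'   `hotspot_sizes`, `cis_markers`.
#' @export
build_pattern <- function(cfg, panel = NULL) {
  stopifnot(inherits(cfg, "mthess_sim_config"))
  q <- cfg$q; p <- cfg$p
  base_sizes <- c(10L, 10L, 20L, 20L, 30L, 30L)
  sizes <- if (q >= 150L) base_sizes else
    pmax(1L, as.integer(round(base_sizes * q / 150)))
  n_cis <- if (cfg$pattern == "cis_trans") 10L else 0L
  n_trans_resp <- sum(sizes)
  if (n_trans_resp + ceiling(n_cis / 2) > q)
    stop("q too small for the requested pattern")
  if (6L + n_cis > p) stop("p too small for the requested pattern")
  chrom <- if (!is.null(panel) && !is.null(panel$marker_pos))
    panel$marker_pos$chrom else rep(seq_len(min(20L, p)), length.out = p)
  # hotspots: first marker of six distinct chromosomes where possible
  uch <- unique(chrom)
  hot <- integer(0)
  for (ch in uch) {
    if (length(hot) == 6L) break
    hot <- c(hot, which(chrom == ch)[1L])
  }
  if (length(hot) < 6L)
    hot <- c(hot, setdiff(seq_len(p), hot)[seq_len(6L - length(hot))])
  # cis markers on chromosomes without hotspots (fall back to any free marker)
  free_ch <- setdiff(uch, chrom[hot])
  cis <- integer(0)
  for (ch in free_ch) {
    if (length(cis) == n_cis) break
    cand <- setdiff(which(chrom == ch), c(hot, cis))
    if (length(cand)) cis <- c(cis, cand[1L])
  }
  if (length(cis) < n_cis)
    cis <- c(cis, setdiff(seq_len(p), c(hot, cis))[seq_len(n_cis - length(cis))])
  gamma <- matrix(0L, q, p)
  labels <- matrix("negative", q, p)
  blocks <- split(seq_len(n_trans_resp),
                  rep(seq_along(sizes), times = sizes))
  for (b in seq_along(sizes)) {
    gamma[blocks[[b]], hot[b]] <- 1L
    labels[blocks[[b]], hot[b]] <- "trans"
  }
  if (n_cis > 0L) {
    n_iso <- n_cis %/% 2L            # half isolated, half on hotspot responses
    n_other <- n_cis - n_iso
    resp_other <- seq_len(n_other)   # responses inside hotspot blocks
    resp_iso <- (n_trans_resp + 1L):(n_trans_resp + n_iso)
    for (i in seq_len(n_other)) {
      gamma[resp_other[i], cis[i]] <- 1L
      labels[resp_other[i], cis[i]] <- "cis_other"
    }
    for (i in seq_len(n_iso)) {
      gamma[resp_iso[i], cis[n_other + i]] <- 1L
      labels[resp_iso[i], cis[n_other + i]] <- "cis_isolated"
    }
  }
  structure(list(gamma_true = gamma, class_labels = labels,
                 hotspot_markers = hot, hotspot_sizes = sizes,
                 cis_markers = cis, lambda = NULL),
            class = "mthess_sim_truth")
}

#' Draw effect sizes for a pattern
#'
#' Each true pair receives an effect `lambda_kj ~ N(mu_class, lambda_sd^2)`:
#' `mu_cis` for cis classes and `mu_trans` for trans pairs under the
#' `cis_trans` pattern, the single `mu` under the `hotspots` pattern.
#' Effects are identical across conditions.
#'
#' @param truth Skeleton from [build_pattern()].
#' @param cfg A [sim_config()].
#' @return The truth object with a `lambda` matrix filled in.
#' @export
simulate_effects <- function(truth, cfg) {
  stopifnot(inherits(truth, "mthess_sim_truth"))
  lambda <- matrix(0, nrow(truth$gamma_true), ncol(truth$gamma_true))
  idx <- which(truth$gamma_true == 1L)
  mu_for <- function(lbl) {
    if (cfg$pattern == "hotspots") return(rep(cfg$mu, length(lbl)))
    ifelse(lbl == "trans", cfg$mu_trans, cfg$mu_cis)
  }
  lambda[idx] <- stats::rnorm(length(idx),
                              mean = mu_for(truth$class_labels[idx]),
                              sd = cfg$lambda_sd)
  truth$lambda <- lambda
  truth
}

#' Simulate multi-condition responses
#'
#' `Y_l = X B + E_l + E_shared`, with `B = t(lambda * gamma_true)` shared
#' across conditions, `E_shared` drawn once with SD `sigma_shared`, and
#' per-condition residuals with SD `sqrt(sigma_total_l^2 - sigma_shared^2)`.
#'
#' @param panel A [genotype_panel()].
#' @param truth Truth with effects from [simulate_effects()].
#' @param cfg A [sim_config()].
#' @return A [response_panel()] with `q` stacks of shape `n x r`.
#' @export
simulate_responses <- function(panel, truth, cfg) {
  stopifnot(inherits(panel, "genotype_panel"),
            inherits(truth, "mthess_sim_truth"), !is.null(truth$lambda))
  X <- panel$values
  n <- nrow(X); q <- nrow(truth$gamma_true); r <- cfg$r
  sig2 <- cfg$sigma_total^2 - cfg$sigma_shared^2
  if (any(sig2 < -1e-12)) stop("sigma_shared exceeds a total noise SD")
  sig <- sqrt(pmax(sig2, 0))
  B <- t(truth$lambda * truth$gamma_true)      # p x q
  XB <- X %*% B                                # n x q
  Esh <- matrix(stats::rnorm(n * q, 0, cfg$sigma_shared), n, q)
  Yl <- lapply(seq_len(r), function(l)
    XB + matrix(stats::rnorm(n * q, 0, sig[l]), n, q) + Esh)
  stacks <- lapply(seq_len(q), function(k) {
    m <- vapply(Yl, function(M) M[, k], numeric(n))
    matrix(m, nrow = n)
  })
  response_panel(stacks, sample_ids = panel$sample_ids,
                 condition_ids = paste0("cond", seq_len(r)))
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: seeds the RNG from `cfg$seed`, simulates genotypes,
#' pattern, effects and responses, and returns everything with the ground
#' truth. Regenerating with the same configuration reproduces the dataset
#' exactly.
#'
#' @param cfg A [sim_config()].
#' @return List with `X` ([genotype_panel()]), `Y` ([response_panel()]),
#'   `truth` and `cfg`.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  X <- simulate_ri_genotypes(cfg)
  truth <- build_pattern(cfg, X)
  truth <- simulate_effects(truth, cfg)
  Y <- simulate_responses(X, truth, cfg)
  list(X = X, Y = Y, truth = truth, cfg = cfg)
}
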