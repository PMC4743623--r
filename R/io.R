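#' Load a run configuration and its data
#'
#' The configuration is a flat `key: value` text file (a subset of YAML).
#' Recognized keys: `genotypes` (path), `responses` (comma-separated paths,
#' one per condition), `e_gamma`, `v_gamma`, `c_rho`, `d_rho`, `d`,
#' `h_mode` (`empirical` or `fixed:<value>`), `n_sweeps`, `burn_in`,
#' `n_chains`, `seed`, `bfdr_target`, `out_dir`. Sample IDs are aligned
#' across the genotype file and every condition file; rows are reordered
#' when needed and an error lists any missing IDs.
#'
#' @param path Configuration file path.
#' @return List with `config` (resolved values incl. defaults), `X`
#'   ([genotype_panel()]) and `Y` ([response_panel()]).
#' @export
load_run <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, ":", fixed = FALSE)
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = ":"), ""))
  raw <- stats::setNames(as.list(vals), keys)
  num <- function(key, default) if (is.null(raw[[key]])) default
    else as.numeric(raw[[key]])
  cfg <- list(
    genotypes = raw$genotypes,
    responses = if (!is.null(raw$responses))
      trimws(strsplit(raw$responses, ",")[[1]]) else NULL,
    e_gamma = num("e_gamma", 1), v_gamma = num("v_gamma", 4),
    c_rho = num("c_rho", 1.2), d_rho = num("d_rho", 1.2),
    d = num("d", 3),
    h_mode = if (is.null(raw$h_mode)) "empirical" else raw$h_mode,
    n_sweeps = as.integer(num("n_sweeps", 15000)),
    burn_in = as.integer(num("burn_in", 5000)),
    n_chains = as.integer(num("n_chains", 3)),
    seed = as.integer(num("seed", 1)),
    bfdr_target = num("bfdr_target", 0.05),
    hotspot_min_count = as.integer(num("hotspot_min_count", 5)),
    out_dir = if (is.null(raw$out_dir)) "mthess_out" else raw$out_dir)
  if (is.null(cfg$genotypes) || is.null(cfg$responses))
    stop("config must provide 'genotypes' and 'responses' paths")
  miss <- c(cfg$genotypes, cfg$responses)
  miss <- miss[!file.exists(miss)]
  if (length(miss)) stop("missing input files: ", paste(miss, collapse = ", "))
  X <- read_genotypes(cfg$genotypes)
  Y <- read_responses(cfg$responses)
  if (!setequal(X$sample_ids, Y$sample_ids)) {
    off <- c(setdiff(X$sample_ids, Y$sample_ids),
             setdiff(Y$sample_ids, X$sample_ids))
    stop("sample-ID mismatch between genotypes and responses: ",
         paste(off, collapse = ", "))
  }
  ord <- match(X$sample_ids, Y$sample_ids)
  Y <- response_panel(lapply(Y$stacks, function(m) m[ord, , drop = FALSE]),
                      response_ids = Y$response_ids,
                      condition_ids = Y$condition_ids,
                      sample_ids = Y$sample_ids[ord])
  list(config = cfg, X = X, Y = Y)
}

#' Write a matrix as headered TSV
#'
#' First column holds the row identifiers under the name `id`.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' End-to-end analysis run
#'
#' Elicits hyperparameters, runs the sampler, thresholds MPPIs at the
#' requested Bayesian FDR and writes `mppi.tsv`, `calls.tsv`,
#' `hotspots.tsv` and `run_summary.txt` into the output directory.
#'
#' @param run A list from [load_run()], or a list with elements `config`,
#'   `X`, `Y` assembled in code.
#' @param force Overwrite an existing output directory.
#' @return Invisibly, a list with the trace, MPPI matrix, calls, hotspot
#'   table and threshold information.
#' @export
mthess_run <- function(run, force = FALSE) {
  cfg <- run$config
  if (dir.exists(cfg$out_dir) &&
      length(list.files(cfg$out_dir)) > 0 && !force)
    stop("output directory exists and is non-empty; use force = TRUE")
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  h_mode <- cfg$h_mode
  if (grepl("^fixed:", h_mode)) h_mode <- as.numeric(sub("^fixed:", "", h_mode))
  hp <- default_hyperparams(run$X, run$Y, e_gamma = cfg$e_gamma,
                            v_gamma = cfg$v_gamma, h_mode = h_mode,
                            d = cfg$d, c_rho = cfg$c_rho, d_rho = cfg$d_rho)
  scfg <- sampler_config(n_sweeps = cfg$n_sweeps, burn_in = cfg$burn_in,
                         seed = cfg$seed)
  lad <- ladder_config(n_chains = cfg$n_chains)
  tr <- run_sampler(run$X, run$Y, hp, scfg, lad)
  mppi <- compute_mppi(tr)
  thr <- threshold_for_bfdr(mppi, cfg$bfdr_target)
  calls <- association_calls(mppi, if (is.na(thr$threshold)) 1 else
    thr$threshold)
  hs <- hotspot_table(calls)
  write_matrix_tsv(mppi, file.path(cfg$out_dir, "mppi.tsv"))
  utils::write.table(calls, file.path(cfg$out_dir, "calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(hs, file.path(cfg$out_dir, "hotspots.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  acc <- tr$acceptance
  summary_lines <- c(
    sprintf("mthess run: n=%d p=%d q=%d r=%d", tr$n, tr$p, tr$q, tr$r),
    sprintf("sweeps=%d burn_in=%d chains=%d seed=%d",
            cfg$n_sweeps, cfg$burn_in, cfg$n_chains, cfg$seed),
    sprintf("a_g=%.4g b_g=%.4g", hp$a_g, hp$b_g),
    sprintf("a_omega[1]=%.4g b_omega[1]=%.4g", hp$a_omega[1], hp$b_omega[1]),
    sprintf("h: %s", paste(signif(hp$h, 4), collapse = " ")),
    sprintf("posterior mean g=%.4g", tr$g_mean),
    sprintf("bfdr_target=%.3g threshold=%.4g bfdr=%.4g n_called=%d",
            cfg$bfdr_target, thr$threshold, thr$bfdr, thr$n_called),
    sprintf("final temperatures: %s",
            paste(signif(tr$final_temperatures, 4), collapse = " ")),
    "acceptance rates:",
    sprintf("  %s: %d/%d", acc$move, as.integer(acc$accepted),
            as.integer(acc$proposed)))
  writeLines(summary_lines, file.path(cfg$out_dir, "run_summary.txt"))
  invisible(list(trace = tr, mppi = mppi, calls = calls, hotspots = hs,
                 threshold = thr))
}

#' Write a simulated dataset as the tab-delimited input files
#'
#' Writes `genotypes.tsv`, one `responses_cond<l>.tsv` per condition and
#' `truth.tsv` (response index, marker index, class, effect size).
#'
#' @param dat List from [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths written.
#' @export
write_sim_dataset <- function(dat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, "genotypes.tsv")
  write_matrix_tsv(dat$X$values, paths)
  n <- dat$Y$n; q <- dat$Y$q; r <- dat$Y$r
  for (l in seq_len(r)) {
    M <- vapply(dat$Y$stacks, function(s) s[, l], numeric(n))
    dimnames(M) <- list(dat$Y$sample_ids, dat$Y$response_ids)
    pl <- file.path(dir, sprintf("responses_cond%d.tsv", l))
    write_matrix_tsv(M, pl)
    paths <- c(paths, pl)
  }
  idx <- which(dat$truth$gamma_true == 1L, arr.ind = TRUE)
  tdf <- data.frame(response = idx[, 1], marker = idx[, 2],
                    class = dat$truth$class_labels[idx],
                    lambda = dat$truth$lambda[idx])
  tp <- file.path(dir, "truth.tsv")
  utils::write.table(tdf[order(tdf$response, tdf$marker), ], tp,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, tp))
}
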