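#' Construct a genotype panel
#'
#' A genotype panel holds the `n x p` predictor (dosage) matrix together with
#' sample and marker identifiers. For inbred panels the dosages are typically
#' coded 0/1. Rows are individuals, columns are markers.
#'
#' @param values Numeric matrix, `n x p`, no missing values.
#' @param sample_ids Character vector of length `n`. Defaults to rownames or
#'   `S1..Sn`.
#' @param marker_ids Character vector of length `p`. Defaults to colnames or
#'   `M1..Mp`.
#' @param marker_pos Optional data frame with columns `chrom` and `pos`
#'   (one row per marker) used by the simulator and pattern builder.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(values, sample_ids = NULL, marker_ids = NULL,
                           marker_pos = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (anyNA(values)) stop("genotype matrix contains missing values")
  if (nrow(values) < 3L) stop("need at least 3 individuals")
  if (is.null(sample_ids)) {
    sample_ids <- rownames(values)
    if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  }
  if (is.null(marker_ids)) {
    marker_ids <- colnames(values)
    if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(values)))
  }
  stopifnot(length(sample_ids) == nrow(values),
            length(marker_ids) == ncol(values))
  if (!is.null(marker_pos)) {
    marker_pos <- as.data.frame(marker_pos)
    stopifnot(nrow(marker_pos) == ncol(values),
              all(c("chrom", "pos") %in% names(marker_pos)))
  }
  dimnames(values) <- list(sample_ids, marker_ids)
  structure(list(values = values, sample_ids = as.character(sample_ids),
                 marker_ids = as.character(marker_ids),
                 marker_pos = marker_pos),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d markers\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$values)

#' Construct a response panel
#'
#' A response panel stores, for each of `q` responses, an `n x r` matrix
#' `Y_k` whose columns are the r conditions (tissues) in which the response
#' was measured. All stacks share the sample ordering of the genotype panel.
#'
#' @param stacks List of `q` numeric `n x r` matrices, or a single
#'   three-dimensional `n x q x r` array.
#' @param response_ids,condition_ids,sample_ids Identifier vectors; defaults
#'   are generated when omitted.
#' @return An object of class `response_panel`.
#' @export
response_panel <- function(stacks, response_ids = NULL, condition_ids = NULL,
                           sample_ids = NULL) {
  if (is.array(stacks) && length(dim(stacks)) == 3L) {
    a <- stacks
    stacks <- lapply(seq_len(dim(a)[2]), function(k) a[, k, , drop = TRUE])
    stacks <- lapply(stacks, function(m) matrix(m, nrow = dim(a)[1]))
  }
  stopifnot(is.list(stacks), length(stacks) >= 1L)
  stacks <- lapply(stacks, function(m) {
    m <- as.matrix(m); storage.mode(m) <- "double"; m
  })
  d <- dim(stacks[[1]])
  ok <- vapply(stacks, function(m) identical(dim(m), d), logical(1))
  if (!all(ok)) stop("all response stacks must share the same n x r shape")
  if (any(vapply(stacks, anyNA, logical(1))))
    stop("response matrices contain missing values")
  q <- length(stacks)
  if (is.null(response_ids)) response_ids <- paste0("Y", seq_len(q))
  if (is.null(condition_ids)) condition_ids <- paste0("cond", seq_len(d[2]))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(d[1]))
  stopifnot(length(response_ids) == q, length(condition_ids) == d[2],
            length(sample_ids) == d[1])
  structure(list(stacks = stacks, response_ids = as.character(response_ids),
                 condition_ids = as.character(condition_ids),
                 sample_ids = as.character(sample_ids),
                 n = d[1], q = q, r = d[2]),
            class = "response_panel")
}

#' @export
print.response_panel <- function(x, ...) {
  cat(sprintf("response_panel: %d responses, %d individuals, %d conditions\n",
              x$q, x$n, x$r))
  invisible(x)
}

#' Column-center a matrix
#'
#' Subtracts the column mean from each column. Centering the responses (and
#' the predictors, for numerical stability) implements the flat prior on the
#' per-response intercept, which is integrated out analytically.
#'
#' @param Y Numeric matrix with at least two rows.
#' @return Matrix of the same shape with column means zero.
#' @export
center_columns <- function(Y) {
  Y <- as.matrix(Y)
  if (nrow(Y) < 2L) stop("centering needs at least 2 rows")
  sweep(Y, 2L, colMeans(Y), "-")
}

#' Remove redundant markers
#'
#' Drops any marker column that is identical to, or perfectly anticorrelated
#' with (correlation of magnitude 1, e.g. the 0/1 complement), an earlier
#' column, keeping the first occurrence. Optionally an LD r-squared pruning
#' threshold below 1 can be supplied. Returns the reduced panel together with
#' an alias map from each removed marker to the representative kept.
#'
#' @param panel A [genotype_panel()].
#' @param r2_threshold Squared-correlation threshold at or above which the
#'   later column is removed. Default 1 (exact duplicates and complements
#'   only).
#' @return A `genotype_panel` with attribute `alias_map` (data frame with
#'   columns `removed`, `kept`).
#' @export
dedupe_markers <- function(panel, r2_threshold = 1) {
  stopifnot(inherits(panel, "genotype_panel"))
  X <- panel$values
  p <- ncol(X)
  keep <- logical(p)
  rem <- character(0); rep_of <- character(0)
  # scale columns once; constant columns get NA and match only each other
  sds <- apply(X, 2L, stats::sd)
  Z <- sweep(X, 2L, colMeans(X), "-")
  Z <- sweep(Z, 2L, ifelse(sds > 0, sds, 1), "/")
  kept_idx <- integer(0)
  for (j in seq_len(p)) {
    dup_at <- 0L
    if (length(kept_idx)) {
      if (sds[j] == 0) {
        const_kept <- kept_idx[sds[kept_idx] == 0]
        if (length(const_kept)) dup_at <- const_kept[1L]
      } else {
        cand <- kept_idx[sds[kept_idx] > 0]
        if (length(cand)) {
          r2 <- (crossprod(Z[, cand, drop = FALSE], Z[, j]) / (nrow(X) - 1))^2
          hit <- which(r2 >= r2_threshold - 1e-12)
          if (length(hit)) dup_at <- cand[hit[1L]]
        }
      }
    }
    if (dup_at > 0L) {
      rem <- c(rem, panel$marker_ids[j])
      rep_of <- c(rep_of, panel$marker_ids[dup_at])
    } else {
      keep[j] <- TRUE
      kept_idx <- c(kept_idx, j)
    }
  }
  out <- genotype_panel(X[, keep, drop = FALSE],
                        sample_ids = panel$sample_ids,
                        marker_ids = panel$marker_ids[keep],
                        marker_pos = if (!is.null(panel$marker_pos))
                          panel$marker_pos[keep, , drop = FALSE] else NULL)
  attr(out, "alias_map") <- data.frame(removed = rem, kept = rep_of,
                                       stringsAsFactors = FALSE)
  out
}

#' Read a genotype matrix from tab-delimited text
#'
#' Layout: first row marker IDs, first column sample IDs, numeric cells.
#'
#' @param path File path.
#' @return A [genotype_panel()].
#' @export
read_genotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) {
    bad <- which(!vapply(df, is.numeric, logical(1)))[1L]
    stop(sprintf("non-numeric genotype column: %s", names(df)[bad]))
  }
  genotype_panel(m, sample_ids = rownames(df), marker_ids = colnames(df))
}

#' Read per-condition response matrices
#'
#' Each file holds one condition: first row response IDs, first column sample
#' IDs. Conditions are aligned by sample ID (rows are reordered to match the
#' first file); an error is raised when sample sets differ.
#'
#' @param paths Character vector of file paths, one per condition.
#' @param condition_ids Optional condition names (defaults to file base names).
#' @return A [response_panel()].
#' @export
read_responses <- function(paths, condition_ids = NULL) {
  stopifnot(length(paths) >= 1L)
  if (is.null(condition_ids))
    condition_ids <- sub("\\.[^.]*$", "", basename(paths))
  mats <- lapply(paths, function(p) {
    df <- utils::read.delim(p, header = TRUE, row.names = 1L,
                            check.names = FALSE)
    as.matrix(df)
  })
  ids <- rownames(mats[[1L]])
  for (i in seq_along(mats)[-1L]) {
    mi <- rownames(mats[[i]])
    if (!setequal(mi, ids)) {
      off <- c(setdiff(ids, mi), setdiff(mi, ids))
      stop(sprintf("sample-ID mismatch in %s: %s", paths[i],
                   paste(off, collapse = ", ")))
    }
    mats[[i]] <- mats[[i]][ids, , drop = FALSE]
  }
  resp_ids <- colnames(mats[[1L]])
  q <- length(resp_ids); n <- length(ids); r <- length(mats)
  stacks <- lapply(seq_len(q), function(k) {
    m <- vapply(mats, function(M) M[, k], numeric(n))
    matrix(m, nrow = n, dimnames = list(ids, condition_ids))
  })
  response_panel(stacks, response_ids = resp_ids,
                 condition_ids = condition_ids, sample_ids = ids)
}
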