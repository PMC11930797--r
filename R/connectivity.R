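#' Pairwise Pearson correlation matrix of node time series
#'
#' Each node's series is mean-centred and unit-scaled before the pairwise
#' Pearson correlations are taken (z-scoring leaves Pearson r unchanged
#' but matches the pipeline's stated preprocessing contract).
#'
#' @param timeseries N x T numeric matrix, nodes as rows, T >= 3.
#' @return Symmetric N x N correlation matrix with unit diagonal.
#' @export
compute_correlations <- function(timeseries) {
  ts <- as.matrix(timeseries)
  if (!is.numeric(ts)) stop("time series must be numeric")
  if (nrow(ts) < 2) stop("need at least 2 nodes")
  if (ncol(ts) < 3) stop("need at least 3 volumes")
  if (anyNA(ts)) stop("time series contains missing values")
  sds <- apply(ts, 1, sd)
  if (any(sds == 0)) {
    bad <- which(sds == 0)
    stop("zero-variance (constant) series at node(s): ",
         paste(bad, collapse = ", "))
  }
  z <- (ts - rowMeans(ts)) / sds
  r <- cor(t(z))
  # numeric guard: clamp round-off excursions outside [-1, 1]
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Normalize a correlation matrix into connectivity weights
#'
#' Applies the Fisher Z-transformation (`atanh`) to positive off-diagonal
#' correlations, sets negative correlations to zero, and forces the
#' diagonal to zero. Off-diagonal correlations of magnitude 1 are rejected
#' (infinite z; typically duplicated node series).
#'
#' @param raw Symmetric matrix of correlations in \[-1, 1\].
#' @return A `connectivity_matrix`: symmetric non-negative matrix of
#'   Fisher-z weights with zero diagonal.
#' @export
normalize_connectivity <- function(raw) {
  r <- as.matrix(raw)
  n <- nrow(r)
  if (ncol(r) != n) stop("correlation matrix must be square")
  if (anyNA(r) || any(!is.finite(r))) stop("correlations must be finite")
  if (max(abs(r - t(r))) > 1e-8) stop("correlation matrix must be symmetric")
  if (any(r < -1 - 1e-8) || any(r > 1 + 1e-8))
    stop("correlations must lie in [-1, 1]")
  off <- abs(r) >= 1 - 1e-12
  diag(off) <- FALSE
  if (any(off))
    stop("off-diagonal correlation of magnitude 1 (infinite Fisher z); ",
         "check for duplicated node series")
  z <- atanh(pmax(r, 0))
  diag(z) <- 0
  z <- (z + t(z)) / 2  # exact symmetry against round-off
  connectivity_matrix(z)
}

#' Connectivity matrix constructor / validator
#'
#' @param weights Symmetric non-negative matrix with zero diagonal
#'   (Fisher-z edge weights).
#' @return The validated matrix with class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(weights) {
  w <- as.matrix(weights)
  n <- nrow(w)
  if (ncol(w) != n) stop("weights must be square")
  if (anyNA(w) || any(!is.finite(w))) stop("weights must be finite")
  if (max(abs(w - t(w))) > 1e-8) stop("weights must be symmetric")
  if (any(w < 0)) stop("weights must be non-negative")
  if (any(diag(w) != 0)) stop("diagonal must be exactly zero")
  class(w) <- c("connectivity_matrix", class(matrix()))
  w
}

#' Subject time series to connectivity matrix
#'
#' Convenience wrapper: optionally discards the first `discard_first_k`
#' volumes (steady-state convention for the synthetic path; preprocessed
#' empirical series should arrive already trimmed, use 0), then computes
#' Pearson correlations and normalizes them.
#'
#' @param timeseries N x T matrix, nodes as rows.
#' @param discard_first_k Number of leading volumes to drop (default 5).
#' @return A `connectivity_matrix`.
#' @export
subject_connectivity <- function(timeseries, discard_first_k = 5) {
  ts <- as.matrix(timeseries)
  if (discard_first_k > 0) {
    if (ncol(ts) - discard_first_k < 3)
      stop("fewer than 3 volumes left after discarding ", discard_first_k)
    ts <- ts[, -seq_len(discard_first_k), drop = FALSE]
  }
  normalize_connectivity(compute_correlations(ts))
}

#' Whole-brain functional connectivity
#'
#' The mean of all positive edges in the network: the arithmetic mean of
#' the strictly positive upper-triangle Fisher-z weights. With
#' `include_zeros = TRUE` the zeroed (formerly negative or null) edges are
#' kept in the denominator instead.
#'
#' @param conn A `connectivity_matrix` (or compatible matrix).
#' @param include_zeros Count zero edges in the denominator? Default FALSE
#'   (positive edges only).
#' @return Scalar mean positive edge weight.
#' @export
whole_brain_fc <- function(conn, include_zeros = FALSE) {
  w <- connectivity_matrix(conn)
  ut <- w[upper.tri(w)]
  if (include_zeros) return(mean(ut))
  pos <- ut[ut > 0]
  if (length(pos) == 0)
    stop("no positive edges in the network")
  mean(pos)
}

#' Nodewise connectivity
#'
#' Per node, the average connectivity to all other nodes: the mean of the
#' node's row of the normalized matrix excluding the diagonal (zeroed
#' negative edges included, denominator N - 1).
#'
#' @param conn A `connectivity_matrix` (or compatible matrix).
#' @return Numeric vector of length N.
#' @export
nodewise_connectivity <- function(conn) {
  w <- connectivity_matrix(conn)
  rowSums(w) / (nrow(w) - 1)
}
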