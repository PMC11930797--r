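#' Proportional density grid
#'
#' Default grid of proportional density thresholds: 5% to 45% in steps of
#' 5%, i.e. nine thresholds.
#'
#' @param from,to,by Grid limits and step, proportions in (0, 1].
#' @return Strictly increasing numeric vector of densities.
#' @export
density_grid <- function(from = 0.05, to = 0.45, by = 0.05) {
  d <- seq(from, to, by)
  if (length(d) < 1 || any(d <= 0) || any(d > 1) || any(diff(d) <= 0))
    stop("densities must be strictly increasing proportions in (0, 1]")
  d
}

#' Proportional density thresholding
#'
#' Retains the `round(density * N(N-1)/2)` strongest edges of a weighted
#' undirected network with their original weights; every other
#' off-diagonal entry becomes zero. Ties at the cutoff are broken
#' deterministically by (weight descending, upper-triangle index
#' ascending). If fewer nonzero edges exist than requested, all nonzero
#' edges are retained with a warning.
#'
#' @param conn Symmetric non-negative weight matrix (zero diagonal).
#' @param density Proportion of edges to retain, in (0, 1].
#' @return Thresholded symmetric weight matrix.
#' @export
proportional_threshold <- function(conn, density) {
  w <- connectivity_matrix(conn)
  n <- nrow(w)
  if (density <= 0 || density > 1) stop("density must lie in (0, 1]")
  m_all <- n * (n - 1) / 2
  k <- round(density * m_all)
  if (k < 1) stop("density ", density, " retains zero edges for N = ", n)
  iu <- which(upper.tri(w))
  wt <- w[iu]
  nnz <- sum(wt > 0)
  if (k > nnz) {
    warning("requested ", k, " edges but only ", nnz,
            " nonzero edges available; retaining all nonzero edges")
    k <- nnz
  }
  ord <- order(-wt, iu)
  keep <- ord[seq_len(k)]
  out <- matrix(0, n, n)
  out[iu[keep]] <- wt[keep]
  out <- out + t(out)
  out
}

#' Weighted clustering coefficient (Onnela)
#'
#' Mean over all nodes of the Onnela weighted clustering coefficient: the
#' geometric-mean intensity of the triangles around each node, on weights
#' rescaled by the global maximum weight (keeping the coefficient in
#' \[0, 1\]), divided by the number of possible neighbour pairs. Nodes
#' with degree below 2 contribute 0.
#'
#' @param W Symmetric non-negative weight matrix, zero diagonal.
#' @param binarize Reduce to the binary clustering coefficient by
#'   replacing all nonzero weights with 1? Default FALSE.
#' @return Scalar mean clustering coefficient.
#' @export
clustering_coefficient <- function(W, binarize = FALSE) {
  w <- as.matrix(W)
  n <- nrow(w)
  if (n == 0) stop("empty graph")
  if (ncol(w) != n || any(w < 0)) stop("need a square non-negative matrix")
  diag(w) <- 0
  if (binarize) w <- (w > 0) * 1
  mx <- max(w)
  if (mx == 0) return(0)  # edgeless graph: every node has degree < 2
  k <- rowSums(w > 0)
  w13 <- (w / mx)^(1 / 3)
  tri <- diag(w13 %*% w13 %*% w13)  # 2 x geometric-mean triangle intensity
  ci <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  mean(ci)
}

#' Weighted global efficiency
#'
#' Edge connection length is the inverse weight; shortest path lengths
#' d(i, j) come from Dijkstra's algorithm; global efficiency is the mean
#' over ordered node pairs of 1/d(i, j), with disconnected pairs
#' contributing zero.
#'
#' @param W Symmetric non-negative weight matrix, zero diagonal.
#' @param binarize Use unit lengths on all existing edges? Default FALSE.
#' @return Scalar global efficiency.
#' @export
global_efficiency <- function(W, binarize = FALSE) {
  w <- as.matrix(W)
  n <- nrow(w)
  if (n < 2) stop("need at least 2 nodes")
  if (ncol(w) != n || any(w < 0)) stop("need a square non-negative matrix")
  diag(w) <- 0
  if (binarize) w <- (w > 0) * 1
  len <- ifelse(w > 0, 1 / w, Inf)
  diag(len) <- 0
  d <- cpp_shortest_paths(len)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Modularity by seeded Louvain restarts
#'
#' Greedy Louvain maximization of the Newman-Girvan weighted modularity at
#' resolution `gamma`, repeated `n_restarts` times over randomized node
#' orders; the partition with the highest Q is returned. Deterministic
#' given `seed`.
#'
#' @param W Symmetric non-negative weight matrix with at least one edge.
#' @param gamma Resolution parameter (default 1).
#' @param n_restarts Number of seeded restarts (default 100).
#' @param seed Integer seed for the restart randomization.
#' @param binarize Replace nonzero weights with 1 first? Default FALSE.
#' @return List with `Q` (scalar) and `membership` (integer community
#'   labels, one per node).
#' @export
modularity <- function(W, gamma = 1, n_restarts = 100, seed = 1,
                       binarize = FALSE) {
  w <- as.matrix(W)
  n <- nrow(w)
  if (ncol(w) != n || any(w < 0)) stop("need a square non-negative matrix")
  diag(w) <- 0
  if (binarize) w <- (w > 0) * 1
  if (sum(w) == 0) stop("graph has no edges")
  res <- withr::with_seed(seed, cpp_louvain(w, gamma, as.integer(n_restarts)))
  list(Q = res$Q, membership = as.integer(res$membership))
}

#' Modularity of a given partition
#'
#' Newman-Girvan weighted modularity
#' \deqn{Q = \frac{1}{2m}\sum_{ij}\left(w_{ij} -
#'   \gamma\frac{k_i k_j}{2m}\right)\delta(c_i, c_j)}
#' evaluated for a fixed community assignment.
#'
#' @param W Symmetric non-negative weight matrix.
#' @param membership Integer community label per node.
#' @param gamma Resolution parameter.
#' @return Scalar Q.
#' @export
modularity_value <- function(W, membership, gamma = 1) {
  w <- as.matrix(W)
  diag(w) <- 0
  two_m <- sum(w)
  if (two_m <= 0) stop("graph has no edges")
  k <- rowSums(w)
  q <- 0
  for (c in unique(membership)) {
    i <- membership == c
    q <- q + sum(w[i, i]) / two_m - gamma * (sum(k[i]) / two_m)^2
  }
  q
}

#' Area-under-curve surrogate of a graph measure over the density grid
#'
#' Evaluates a graph measure on the proportionally thresholded network at
#' each density of the grid and integrates the resulting curve by the
#' trapezoidal rule, normalized by the density span so a constant curve
#' returns its constant (the surrogate lives on the measure's own scale).
#'
#' @param conn A `connectivity_matrix`.
#' @param metric `"clustering"`, `"global_efficiency"`, `"modularity"`, or
#'   a function of a thresholded weight matrix returning a scalar.
#' @param densities Density grid (>= 2 values), default [density_grid()].
#' @param gamma,n_restarts,seed Passed to [modularity()].
#' @param binarize Binarize after thresholding? Default FALSE.
#' @return Scalar AUC surrogate, with attribute `curve` (data.frame of
#'   density and metric value).
#' @export
metric_auc <- function(conn, metric, densities = density_grid(),
                       gamma = 1, n_restarts = 100, seed = 1,
                       binarize = FALSE) {
  if (length(densities) < 2) stop("need at least 2 densities")
  if (any(diff(densities) <= 0)) stop("densities must be strictly increasing")
  f <- if (is.function(metric)) metric else switch(
    match.arg(metric, c("clustering", "global_efficiency", "modularity")),
    clustering = function(w) clustering_coefficient(w, binarize = binarize),
    global_efficiency = function(w) global_efficiency(w, binarize = binarize),
    modularity = function(w) modularity(w, gamma = gamma,
                                        n_restarts = n_restarts, seed = seed,
                                        binarize = binarize)$Q
  )
  vals <- vapply(densities, function(d) {
    wd <- proportional_threshold(conn, d)
    tryCatch(f(wd), error = function(e)
      stop("metric failed at density ", d, ": ", conditionMessage(e)))
  }, numeric(1))
  nd <- length(densities)
  auc <- sum(diff(densities) * (vals[-1] + vals[-nd]) / 2) /
    (densities[nd] - densities[1])
  attr(auc, "curve") <- data.frame(density = densities, value = vals)
  auc
}

#' All graph measures for one subject
#'
#' Computes the whole-brain functional connectivity, the AUC surrogates of
#' clustering coefficient, global efficiency and modularity over the
#' density grid, and the nodewise connectivity vector.
#'
#' @inheritParams metric_auc
#' @return List with `whole_brain_fc`, `clustering_auc`,
#'   `global_efficiency_auc`, `modularity_auc`, and `nodewise`.
#' @export
graph_metric_set <- function(conn, densities = density_grid(), gamma = 1,
                             n_restarts = 100, seed = 1, binarize = FALSE) {
  conn <- connectivity_matrix(conn)
  list(
    whole_brain_fc = whole_brain_fc(conn),
    clustering_auc = as.numeric(
      metric_auc(conn, "clustering", densities, binarize = binarize)),
    global_efficiency_auc = as.numeric(
      metric_auc(conn, "global_efficiency", densities, binarize = binarize)),
    modularity_auc = as.numeric(
      metric_auc(conn, "modularity", densities, gamma = gamma,
                 n_restarts = n_restarts, seed = seed, binarize = binarize)),
    nodewise = nodewise_connectivity(conn)
  )
}

#' Graph measures for a whole cohort
#'
#' Applies [subject_connectivity()] and [graph_metric_set()] to every
#' subject of a cohort.
#'
#' @param cohort A `comanet_cohort` (or list of subject records with
#'   `subject_id` and `timeseries`).
#' @param discard_first_k Leading volumes to drop per subject (default 5).
#' @inheritParams metric_auc
#' @return List with `metrics` (data.frame: subject_id, whole_brain_fc,
#'   clustering_auc, global_efficiency_auc, modularity_auc) and `nodewise`
#'   (subjects x nodes matrix).
#' @export
cohort_graph_metrics <- function(cohort, densities = density_grid(),
                                 discard_first_k = 5, gamma = 1,
                                 n_restarts = 100, seed = 1,
                                 binarize = FALSE) {
  subjects <- if (inherits(cohort, "comanet_cohort")) cohort$subjects
              else cohort
  rows <- vector("list", length(subjects))
  nodewise <- NULL
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    conn <- subject_connectivity(s$timeseries, discard_first_k)
    gm <- graph_metric_set(conn, densities, gamma, n_restarts, seed,
                           binarize)
    rows[[i]] <- data.frame(
      subject_id = s$subject_id,
      whole_brain_fc = gm$whole_brain_fc,
      clustering_auc = gm$clustering_auc,
      global_efficiency_auc = gm$global_efficiency_auc,
      modularity_auc = gm$modularity_auc,
      stringsAsFactors = FALSE
    )
    if (is.null(nodewise))
      nodewise <- matrix(NA_real_, length(subjects), length(gm$nodewise))
    nodewise[i, ] <- gm$nodewise
  }
  metrics <- do.call(rbind, rows)
  rownames(nodewise) <- metrics$subject_id
  list(metrics = metrics, nodewise = nodewise)
}
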