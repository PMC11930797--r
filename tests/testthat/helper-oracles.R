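# Independent brute-force oracles and fixture builders used across the
# suite. Everything here is deliberately naive (loops, enumeration) and
# shares no code with the implementation under test.

# random symmetric non-negative weight matrix, zero diagonal
rand_graph <- function(n, p_edge = 0.5) {
  W <- matrix(0, n, n)
  iu <- which(upper.tri(W))
  keep <- runif(length(iu)) < p_edge
  W[iu[keep]] <- runif(sum(keep))
  W + t(W)
}

# Pearson r straight from the covariance formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  sxy / (sqrt(sum((x - mean(x))^2) / (n - 1)) *
         sqrt(sum((y - mean(y))^2) / (n - 1)))
}

# naive O(N^2 T) correlation matrix
oracle_correlation_matrix <- function(ts) {
  n <- nrow(ts)
  r <- diag(n)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      r[i, j] <- r[j, i] <- oracle_pearson(ts[i, ], ts[j, ])
  r
}

# Onnela clustering by explicit triangle enumeration
oracle_clustering <- function(W) {
  n <- nrow(W)
  mx <- max(W)
  if (mx == 0) return(0)
  Wn <- W / mx
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(W[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_len(k - 1))
      for (b in (a + 1):k) {
        j <- nb[a]; h <- nb[b]
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1 / 3)
      }
    ci[i] <- 2 * s / (k * (k - 1))
  }
  mean(ci)
}

# all-pairs shortest paths by Floyd-Warshall on inverse-weight lengths
oracle_shortest_paths <- function(W) {
  n <- nrow(W)
  d <- ifelse(W > 0, 1 / W, Inf)
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

oracle_global_efficiency <- function(W) {
  n <- nrow(W)
  d <- oracle_shortest_paths(W)
  inv <- ifelse(is.finite(d) & d > 0, 1 / d, 0)
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# all set partitions of n elements as restricted growth strings
set_partitions <- function(n) {
  out <- list()
  a <- integer(n)
  rec <- function(i, mx) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (v in 1:(mx + 1)) {
      a[i] <<- v
      rec(i + 1, max(mx, v))
    }
  }
  rec(1, 0L)
  out
}

# maximum modularity by exhaustive enumeration (n <= 8 or so)
oracle_max_modularity <- function(W, gamma = 1, partitions = NULL) {
  if (is.null(partitions)) partitions <- set_partitions(nrow(W))
  max(vapply(partitions, function(m) modularity_value(W, m, gamma),
             numeric(1)))
}

# small cohort config used by calibration and integration tests
small_config <- function(seed, n_good = 30, n_poor = 30,
                         coupling_good = 0.9, coupling_poor = 0.9,
                         n_nodes = 16, n_volumes = 60) {
  cohort_config(n_good = n_good, n_poor = n_poor, n_nodes = n_nodes,
                n_volumes = n_volumes, n_modules = 4,
                coupling_good = coupling_good,
                coupling_poor = coupling_poor, seed = seed)
}

# a deterministic metadata table with both outcome classes and all
# guideline predictor levels, for prediction-module unit tests
toy_metadata <- function(n_good = 44, n_poor = 26, seed = 1) {
  cfg <- cohort_config(n_good = n_good, n_poor = n_poor, n_nodes = 4,
                       n_volumes = 10, n_modules = 2, seed = seed)
  generate_cohort(cfg)$metadata
}
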