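test_that("proportional thresholding keeps the k strongest edges", {
  set.seed(7)
  w <- rand_graph(6, p_edge = 1)

  # density 1 reproduces the input
  expect_equal(proportional_threshold(w, 1), w, ignore_attr = TRUE)

  # 4 nodes, 6 distinct weights, density 0.5 -> the 3 largest survive
  w4 <- matrix(0, 4, 4)
  w4[upper.tri(w4)] <- c(0.1, 0.6, 0.3, 0.2, 0.5, 0.4)
  w4 <- w4 + t(w4)
  thr <- proportional_threshold(w4, 0.5)
  kept <- sort(thr[upper.tri(thr)][thr[upper.tri(thr)] > 0])
  expect_equal(kept, sort(sort(w4[upper.tri(w4)], decreasing = TRUE)[1:3]))

  # retained count equals round(d * N(N-1)/2) across N and densities
  for (n in c(5, 12, 23, 50)) {
    w <- rand_graph(n, p_edge = 1)
    for (d in c(0.1, 0.25, 0.45)) {
      thr <- proportional_threshold(w, d)
      expect_equal(sum(thr[upper.tri(thr)] > 0), round(d * n * (n - 1) / 2))
    }
  }
})

test_that("thresholding edge cases: k = 0 errors, k > nonzero warns", {
  w <- rand_graph(20, p_edge = 1)
  expect_error(proportional_threshold(w, 0.001), "zero edges")
  sparse <- matrix(0, 10, 10)
  sparse[1, 2] <- sparse[2, 1] <- 0.5
  expect_warning(thr <- proportional_threshold(sparse, 0.5), "nonzero")
  expect_equal(sum(thr > 0) / 2, 1)
})

test_that("threshold tie-breaking is deterministic", {
  w <- matrix(0, 4, 4)
  w[upper.tri(w)] <- c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  w <- w + t(w)
  t1 <- proportional_threshold(w, 0.5)
  t2 <- proportional_threshold(w, 0.5)
  expect_identical(t1, t2)
  # first three upper-triangle positions (column-major) retained
  expect_equal(which(t1[upper.tri(t1)] > 0), 1:3)
})

test_that("clustering coefficient matches triangle enumeration", {
  tri <- matrix(0, 3, 3)
  tri[upper.tri(tri)] <- 1
  tri <- tri + t(tri)
  expect_equal(clustering_coefficient(tri), 1)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  expect_equal(clustering_coefficient(star), 0)

  set.seed(8)
  w4 <- rand_graph(4, p_edge = 0.9)
  expect_equal(clustering_coefficient(w4), oracle_clustering(w4))

  expect_error(clustering_coefficient(matrix(0, 0, 0)), "empty")
})

test_that("global efficiency matches hand and Floyd-Warshall oracles", {
  complete <- matrix(1, 4, 4); diag(complete) <- 0
  expect_equal(global_efficiency(complete), 1)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  expect_equal(global_efficiency(path3), 5 / 6)

  set.seed(9)
  for (i in 1:10) {
    w <- rand_graph(8, p_edge = 0.4)
    expect_equal(global_efficiency(w), oracle_global_efficiency(w),
                 tolerance = 1e-12)
  }
})

test_that("modularity recovers exhaustive-search optima and is seeded", {
  w <- rand_graph(6, p_edge = 0.8)
  expect_equal(modularity_value(w, rep(1, 6)), 0)  # one community: e - a^2 cancels

  two_tri <- matrix(0, 6, 6)
  two_tri[1, 2] <- two_tri[2, 3] <- two_tri[1, 3] <- 1
  two_tri[4, 5] <- two_tri[5, 6] <- two_tri[4, 6] <- 1
  two_tri <- pmax(two_tri, t(two_tri))
  expect_equal(oracle_max_modularity(two_tri), 0.5)
  res <- modularity(two_tri, seed = 3)
  expect_equal(res$Q, 0.5)
  expect_equal(length(unique(res$membership)), 2)

  set.seed(10)
  for (i in 1:5) {
    w <- rand_graph(7, p_edge = 0.5)
    if (sum(w) == 0) next
    expect_equal(modularity(w, seed = i)$Q, oracle_max_modularity(w),
                 tolerance = 1e-9)
  }

  # seeded determinism and the Q <= 1 bound
  w <- rand_graph(10, p_edge = 0.4)
  r1 <- modularity(w, n_restarts = 25, seed = 42)
  r2 <- modularity(w, n_restarts = 25, seed = 42)
  expect_identical(r1, r2)
  expect_lte(r1$Q, 1)

  expect_error(modularity(matrix(0, 4, 4)), "no edges")
})

test_that("modularity agrees with an independent community-detection library", {
  skip_if_not_installed("igraph")
  set.seed(17)
  for (i in 1:5) {
    w <- rand_graph(20, p_edge = 0.3)
    if (sum(w) == 0) next
    g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                             weighted = TRUE)
    ig <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
    memb_ig <- igraph::membership(ig)
    # partition-evaluation identity: same Q formula for the same partition
    expect_equal(modularity_value(w, memb_ig),
                 igraph::modularity(g, memb_ig,
                                    weights = igraph::E(g)$weight),
                 tolerance = 1e-10)
    # our restarted maximizer is at least as good as the library's run
    expect_gte(modularity(w, n_restarts = 50, seed = i)$Q,
               modularity_value(w, memb_ig) - 1e-9)
  }
})

test_that("metric AUC is a span-normalized trapezoid", {
  set.seed(13)
  conn <- connectivity_matrix(rand_graph(12, p_edge = 1))

  # constant curve returns the constant
  expect_equal(as.numeric(metric_auc(conn, function(w) 0.7)), 0.7)

  # linear curve over the grid integrates to the midpoint
  grid <- density_grid()
  lin <- local({
    i <- 0
    function(w) { i <<- i + 1; grid[i] }  # value = density, linear in d
  })
  expect_equal(as.numeric(metric_auc(conn, lin)),
               (grid[1] + grid[9]) / 2)

  # the default grid has nine thresholds and drives nine evaluations
  calls <- 0
  counter <- function(w) { calls <<- calls + 1; 1 }
  metric_auc(conn, counter)
  expect_equal(length(density_grid()), 9L)
  expect_equal(calls, 9)
})

test_that("metric AUC is invariant to node relabeling", {
  set.seed(14)
  conn <- connectivity_matrix(rand_graph(10, p_edge = 1))
  p <- sample(10)
  for (m in c("clustering", "global_efficiency")) {
    expect_equal(as.numeric(metric_auc(connectivity_matrix(conn[p, p]), m)),
                 as.numeric(metric_auc(conn, m)), tolerance = 1e-10)
  }
})

test_that("global efficiency is non-decreasing along the density grid", {
  set.seed(15)
  for (i in 1:3) {
    conn <- connectivity_matrix(rand_graph(15, p_edge = 1))
    ge <- attr(metric_auc(conn, "global_efficiency"), "curve")$value
    expect_true(all(diff(ge) >= -1e-12))
  }
})

test_that("graph_metric_set returns all finite measures in range", {
  set.seed(16)
  ts <- matrix(rnorm(12 * 60), 12, 60)
  conn <- subject_connectivity(ts, discard_first_k = 0)
  gm <- graph_metric_set(conn, n_restarts = 20)
  expect_true(gm$clustering_auc >= 0 && gm$clustering_auc <= 1)
  expect_true(gm$global_efficiency_auc >= 0 && gm$global_efficiency_auc <= 1)
  expect_true(gm$modularity_auc >= -0.5 && gm$modularity_auc <= 1)
  expect_length(gm$nodewise, 12)
  expect_true(all(is.finite(unlist(gm[1:4]))))
})
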