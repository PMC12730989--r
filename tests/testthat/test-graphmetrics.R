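test_that("threshold grid arithmetic", {
  expect_length(threshold_grid(), 46)
  expect_equal(threshold_grid(0.1, 0.4, 0.1), c(0.1, 0.2, 0.3, 0.4),
               ignore_attr = TRUE)
  expect_error(threshold_grid(0, 0.5), "s_min")
})

test_that("proportional binarization keeps exactly the K strongest edges", {
  set.seed(1)
  m <- random_symmetric_matrix(5, 0.1, 1); diag(m) <- 0
  g <- binarize_proportional(m, 0.3)
  expect_equal(g$n_edges, 3L)         # round(0.3 * 10)
  expect_equal(sum(g$adjacency) / 2, 3)
  # the kept edges are the 3 largest weights
  kept_w <- sort(m[g$adjacency == 1], decreasing = TRUE)
  expect_equal(unique(kept_w), sort(m[upper.tri(m)], decreasing = TRUE)[1:3])

  full <- binarize_proportional(m, 1)
  expect_equal(full$n_edges, 10L)
  expect_true(all(full$adjacency[upper.tri(full$adjacency)] == 1))

  expect_error(binarize_proportional(m, 0), "sparsity")
  expect_error(binarize_proportional(m, 1.2), "sparsity")
  expect_error(binarize_proportional(m, 0.01), "zero edges")
})

test_that("equal-weight ties break by ascending (row, column) index", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 0.5
  m[3, 4] <- m[4, 3] <- 0.5
  m[1, 4] <- m[4, 1] <- 0.9
  g <- binarize_proportional(m, 2 / 6)  # K = 2: (1,4) then tie for last slot
  expect_equal(g$adjacency[1, 4], 1L)
  expect_equal(g$adjacency[1, 2], 1L)   # (1,2) beats (3,4)
  expect_equal(g$adjacency[3, 4], 0L)
  expect_identical(g$adjacency, binarize_proportional(m, 2 / 6)$adjacency)
})

test_that("negative weights are excluded from ranking by default", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- -5
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.1
  g <- binarize_proportional(m, 2 / 3)
  expect_equal(g$adjacency[1, 2], 0L)
  expect_error(binarize_proportional(m, 1), "nonnegative edge candidates")
  g_abs <- binarize_proportional(m, 1 / 3, rank_abs = TRUE)
  expect_equal(g_abs$adjacency[1, 2], 1L)
})

test_that("path metrics match enumeration on the canonical small cases", {
  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  sp <- shortest_path_metrics(binary_graph_from_adjacency(k4))
  expect_equal(sp$lp, 1)
  expect_equal(sp$eg, 1)

  path3 <- matrix(0, 3, 3)
  path3[1, 2] <- path3[2, 1] <- path3[2, 3] <- path3[3, 2] <- 1
  sp <- shortest_path_metrics(binary_graph_from_adjacency(path3))
  expect_equal(sp$lp, 4 / 3)
  expect_equal(sp$eg, 5 / 6)
  expect_equal(sp$lp, bf_lp(path3))
  expect_equal(sp$eg, bf_eg(path3))

  two_edges <- matrix(0, 4, 4)
  two_edges[1, 2] <- two_edges[2, 1] <- two_edges[3, 4] <- two_edges[4, 3] <- 1
  sp <- shortest_path_metrics(binary_graph_from_adjacency(two_edges))
  expect_equal(sp$lp, 1)       # connected ordered pairs only
  expect_equal(sp$eg, 2 / 6)   # 1/Inf = 0 for disconnected pairs

  empty <- binary_graph_from_adjacency(matrix(0L, 3, 3))
  sp <- shortest_path_metrics(empty)
  expect_true(sp$degenerate)
  expect_equal(sp$eg, 0)
  expect_true(is.na(sp$lp))
})

test_that("clustering metrics match the degree<2 convention", {
  k3 <- matrix(1, 3, 3); diag(k3) <- 0
  cl <- clustering_metrics(binary_graph_from_adjacency(k3))
  expect_equal(cl$cp, 1)
  expect_equal(cl$eloc, 1)

  star <- matrix(0, 4, 4); star[1, 2:4] <- 1; star <- star + t(star)
  cl <- clustering_metrics(binary_graph_from_adjacency(star))
  expect_equal(cl$cp, 0)
  expect_equal(cl$eloc, 0)

  k4 <- matrix(1, 4, 4); diag(k4) <- 0
  cl <- clustering_metrics(binary_graph_from_adjacency(k4))
  expect_equal(cl$cp, 1)
  expect_equal(cl$eloc, 1)
})

test_that("metrics agree with brute-force oracles on random small graphs", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n)
    if (sum(adj) == 0) next
    g <- binary_graph_from_adjacency(adj)
    sp <- shortest_path_metrics(g)
    cl <- clustering_metrics(g)
    expect_equal(sp$eg, bf_eg(adj), tolerance = 1e-12)
    expect_equal(sp$lp, bf_lp(adj), tolerance = 1e-12)
    expect_equal(cl$cp, bf_cp(adj), tolerance = 1e-12)
    expect_equal(cl$eloc, bf_eloc(adj), tolerance = 1e-12)
  }
})

test_that("degree-preserving rewiring keeps degrees and is seeded", {
  set.seed(3)
  adj <- random_adjacency(20, 0.3)
  g <- binary_graph_from_adjacency(adj)
  nul <- degree_preserving_null(g, seed = 7)
  expect_equal(colSums(nul$adjacency), colSums(adj), ignore_attr = TRUE)
  expect_identical(nul$adjacency,
                   degree_preserving_null(g, seed = 7)$adjacency)
  expect_false(identical(degree_preserving_null(g, seed = 8)$adjacency,
                         nul$adjacency))

  star <- matrix(0L, 5, 5); star[1, 2:5] <- 1L; star <- star + t(star)
  s <- degree_preserving_null(binary_graph_from_adjacency(star), seed = 1)
  expect_true(attr(s, "rewire_unchanged"))

  one_edge <- matrix(0L, 3, 3); one_edge[1, 2] <- one_edge[2, 1] <- 1L
  expect_error(degree_preserving_null(binary_graph_from_adjacency(one_edge)),
               "at least 2 edges")
})

test_that("an already-random graph has gamma and lambda near 1", {
  set.seed(9)
  adj <- random_adjacency(50, 0.2)
  g <- binary_graph_from_adjacency(adj)
  sw <- small_world(g, n_null = 100, seed = 4)
  expect_gt(sw$gamma, 0.8); expect_lt(sw$gamma, 1.25)
  expect_gt(sw$lambda, 0.8); expect_lt(sw$lambda, 1.25)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
})

test_that("a Watts-Strogatz ring is detected as small-world", {
  ring <- withr::with_seed(11, igraph::sample_smallworld(1, 100, 3, 0.1))
  adj <- as.matrix(igraph::as_adjacency_matrix(ring, sparse = FALSE))
  adj[adj > 1] <- 1L
  storage.mode(adj) <- "integer"
  sw <- small_world(binary_graph_from_adjacency(adj), n_null = 100, seed = 5)
  expect_gt(sw$gamma, 1)
  expect_gt(sw$sigma, 1)
})

test_that("threshold sweep assembles curves and records failures", {
  set.seed(14)
  m <- abs(random_symmetric_matrix(20)); diag(m) <- 0
  sw <- sweep_thresholds(m, threshold_grid(), n_null = 0, seed = 2)
  expect_equal(nrow(sw), 46)
  expect_true(all(diff(sw$eg) >= -1e-12))   # nested edge sets
  expect_equal(nrow(attr(sw, "failures")), 0)

  # signed matrix with many negatives: dense thresholds fail and are recorded
  neg <- random_symmetric_matrix(10, -1, 0.1); diag(neg) <- 0
  swn <- sweep_thresholds(neg, threshold_grid(0.05, 0.9, 0.05), n_null = 0)
  fails <- attr(swn, "failures")
  expect_gt(nrow(fails), 0)
  expect_true(all(is.na(swn$eg[swn$sparsity %in% fails$sparsity])))

  # all-equal weights: deterministic tie-rule prefix, reproducible curves
  ones <- matrix(1, 8, 8); diag(ones) <- 0
  s1 <- sweep_thresholds(ones, threshold_grid(0.1, 0.5, 0.1), n_null = 0)
  s2 <- sweep_thresholds(ones, threshold_grid(0.1, 0.5, 0.1), n_null = 0)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
})

test_that("binarization is invariant under strictly increasing transforms", {
  set.seed(15)
  for (rep in 1:10) {
    r <- abs(random_symmetric_matrix(15, 0, 0.95)); diag(r) <- 0
    z <- atanh(r)
    for (s in c(0.1, 0.3, 0.5)) {
      expect_identical(binarize_proportional(r, s)$adjacency,
                       binarize_proportional(z, s)$adjacency)
    }
  }
})

test_that("metrics are invariant under node permutation", {
  set.seed(16)
  m <- abs(random_symmetric_matrix(12)); diag(m) <- 0
  perm <- sample(12)
  mp <- m[perm, perm]
  for (s in c(0.2, 0.5)) {
    a <- global_metrics(binarize_proportional(m, s), n_null = 0)
    b <- global_metrics(binarize_proportional(mp, s), n_null = 0)
    for (k in c("eg", "eloc", "lp", "cp")) {
      expect_equal(a[[k]], b[[k]], tolerance = 1e-12)
    }
  }
})

test_that("trapezoidal AUC matches analytic areas", {
  grid <- threshold_grid()
  expect_equal(auc_of_curve(rep(2, length(grid)), grid), 0.9)

  s <- seq(0, 1, by = 0.05)
  expect_equal(auc_of_curve(s, s), 0.5)

  set.seed(17)
  v <- rnorm(length(grid))
  expect_equal(auc_of_curve(v, grid) + auc_of_curve(-v, grid), 0)

  expect_error(auc_of_curve(1, 0.05), "at least 2")
  expect_error(auc_of_curve(c(1, NA, 1), c(.1, .2, .3)), "missing")
})
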