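# Independent brute-force graph-metric oracles: Floyd-Warshall distances,
# exhaustive triangle counts, neighbor-subgraph efficiency. Deliberately
# naive and igraph-free, for cross-checking the package implementation.

bf_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  d
}

bf_eg <- function(adj) {
  n <- nrow(adj)
  if (n < 2) return(0)
  d <- bf_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

bf_lp <- function(adj) {
  d <- bf_distances(adj)
  off <- d[row(d) != col(d)]
  off <- off[is.finite(off)]
  if (!length(off)) return(NA_real_)
  mean(off)
}

bf_cp <- function(adj) {
  n <- nrow(adj)
  ci <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) return(0)
    sum(adj[nb, nb]) / (k * (k - 1))
  }, numeric(1))
  mean(ci)
}

bf_eloc <- function(adj) {
  n <- nrow(adj)
  ei <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    bf_eg(adj[nb, nb, drop = FALSE])
  }, numeric(1))
  mean(ei)
}

random_adjacency <- function(n, p = NULL) {
  if (is.null(p)) p <- runif(1, 0.15, 0.8)
  a <- matrix(0L, n, n)
  ut <- upper.tri(a)
  a[ut] <- as.integer(runif(sum(ut)) < p)
  a + t(a)
}

random_symmetric_matrix <- function(n, min = -1, max = 1) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2, min, max)
  m + t(m)
}

binary_graph_from_adjacency <- function(adj) {
  n <- nrow(adj)
  structure(list(adjacency = adj, sparsity = sum(adj) / (n * (n - 1)),
                 n_edges = sum(adj) / 2, target_sparsity = NA_real_),
            class = "binary_graph")
}

tiny_cohort_config <- function(seed = 11, ...) {
  cohort_config(n_roi = 18, n_modules = 3, n_timepoints_ts = 40,
                seed = seed, ...)
}

# moderation-recovery cohort: n subjects per group, metric varying within
# subject, outcomes from the planted linear mixed model
simulate_moderation_cohort <- function(seed, n_per_group = 20,
                                       interaction = 9.087, noise = 2,
                                       subject_sd = 1) {
  cfg <- cohort_config(
    n_per_group = n_per_group,
    interaction_effects = c(path_length = interaction, step_height = 0,
                            stride_length = 0),
    noise_sd = list(outcome = noise, subject = subject_sd, eg_latent = 0.05,
                    fa = 0.03),
    seed = seed)
  subs <- sprintf("S%02d", seq_len(2 * n_per_group))
  grid <- expand.grid(subject = subs, timepoint = cfg$timepoints,
                      stringsAsFactors = FALSE)
  grid$group <- ifelse(match(grid$subject, subs) <= n_per_group,
                       "sci", "treatment")
  metric <- withr::with_seed(seed + 7L,
                             rnorm(nrow(grid), mean = 0.5, sd = 0.1))
  mt <- data.frame(subject = grid$subject, group = grid$group,
                   timepoint = grid$timepoint, metric = metric)
  simulate_outcomes(cfg, mt)
}
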