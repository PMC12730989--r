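#' Proportional sparsity grid
#'
#' @param s_min,s_max,step sparsity range and increment; defaults 0.05 to
#'   0.50 in increments of 0.01 (46 thresholds), the conventional range that
#'   keeps brain networks sparse enough to be biologically plausible while
#'   preserving small-world topology at the dense end.
#' @return Numeric vector of sparsity values with class `threshold_grid`.
#' @export
threshold_grid <- function(s_min = 0.05, s_max = 0.50, step = 0.01) {
  stopifnot_scalar_number(s_min, "s_min", lower = 1e-12, upper = 1)
  stopifnot_scalar_number(s_max, "s_max", lower = s_min, upper = 1)
  stopifnot_scalar_number(step, "step", lower = 1e-12)
  n <- floor((s_max - s_min) / step + 1e-9) + 1L
  grid <- s_min + step * (seq_len(n) - 1L)
  structure(round(grid, 10), class = "threshold_grid")
}

round_half_up <- function(x) floor(x + 0.5)

#' Binarize a connectivity matrix at a proportional threshold
#'
#' Keeps the K = round(s * N(N-1)/2) strongest edges (half-up rounding) of
#' the upper triangle and discards the rest, so every subject's graph has the
#' same edge count at a given sparsity s. Edges are ranked by signed weight,
#' most positive first; ties are broken by ascending (row, column) index so
#' the result is deterministic. Negative weights (possible in individual
#' structural covariance networks) are excluded from the candidate set by
#' default; set `rank_abs = TRUE` to rank by absolute value instead.
#'
#' @param m a [connectivity_matrix()] or plain symmetric matrix.
#' @param s sparsity in (0, 1].
#' @param rank_abs rank edges by |weight| instead of signed weight.
#' @return Object of class `binary_graph`: `adjacency` (0/1 matrix),
#'   `sparsity` (realized edge fraction), `n_edges`, `target_sparsity`.
#' @export
binarize_proportional <- function(m, s, rank_abs = FALSE) {
  vals <- if (inherits(m, "connectivity_matrix")) cm_values(m) else m
  check_square_symmetric(vals, "m")
  stopifnot_scalar_number(s, "s")
  if (s <= 0 || s > 1) stop("sparsity must be in (0, 1]", call. = FALSE)
  n <- nrow(vals)
  n_pairs <- n * (n - 1) / 2
  K <- round_half_up(s * n_pairs)
  if (K < 1) stop(sprintf("sparsity %.3f yields zero edges on %d nodes", s, n),
                  call. = FALSE)
  ut <- which(upper.tri(vals), arr.ind = TRUE)
  w <- vals[upper.tri(vals)]
  rank_w <- if (rank_abs) abs(w) else w
  keep <- if (rank_abs) rep(TRUE, length(w)) else w >= 0
  cand <- which(keep)
  if (length(cand) < K) {
    stop(sprintf(paste0("only %d nonnegative edge candidates for %d requested",
                        " edges at sparsity %.3f"), length(cand), K, s),
         call. = FALSE)
  }
  ord <- cand[order(-rank_w[cand], ut[cand, 1L], ut[cand, 2L])]
  top <- ord[seq_len(K)]
  adj <- matrix(0L, n, n, dimnames = dimnames(vals))
  adj[ut[top, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  structure(list(adjacency = adj, sparsity = K / n_pairs, n_edges = K,
                 target_sparsity = s),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph: %d nodes, %d edges, sparsity %.3f>\n",
              nrow(x$adjacency), x$n_edges, x$sparsity))
  invisible(x)
}

as_igraph <- function(g) {
  adj <- if (inherits(g, "binary_graph")) g$adjacency else g
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected", diag = FALSE)
}

#' Path-based global metrics
#'
#' Characteristic path length Lp is the mean shortest-path length over
#' connected ordered pairs only (disconnected pairs are excluded rather than
#' assigned an arbitrary finite distance); global efficiency Eg is the mean
#' of 1/d over all ordered pairs with 1/Inf = 0, so disconnection lowers Eg.
#' An empty graph returns Eg = 0 and Lp = NA with a `degenerate` flag.
#'
#' @param g a [binarize_proportional()] result (or 0/1 adjacency matrix).
#' @return Named list `lp`, `eg`, `degenerate`.
#' @export
shortest_path_metrics <- function(g) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0L) {
    return(list(lp = NA_real_, eg = 0, degenerate = TRUE))
  }
  list(lp = igraph::mean_distance(ig, unconnected = TRUE),
       eg = igraph::global_efficiency(ig),
       degenerate = FALSE)
}

#' Clustering-based global metrics
#'
#' Cp is the mean local clustering coefficient, with nodes of degree < 2
#' contributing 0; Eloc is the mean, over nodes, of the global efficiency of
#' the subgraph induced by each node's neighbors (0 for degree < 2). The
#' induced-subgraph convention matters: paths between two neighbors may only
#' pass through other neighbors of the ego node, the convention of the
#' standard connectome toolboxes.
#'
#' @inheritParams shortest_path_metrics
#' @return Named list `cp`, `eloc`.
#' @export
clustering_metrics <- function(g) {
  ig <- as_igraph(g)
  if (igraph::ecount(ig) == 0L) return(list(cp = 0, eloc = 0))
  eloc_v <- vapply(seq_len(igraph::vcount(ig)), function(v) {
    nb <- igraph::neighbors(ig, v)
    if (length(nb) < 2L) return(0)
    igraph::global_efficiency(igraph::induced_subgraph(ig, nb))
  }, numeric(1))
  list(cp = igraph::transitivity(ig, type = "localaverage",
                                 isolates = "zero"),
       eloc = mean(eloc_v))
}

#' Degree-preserving random rewiring (Maslov-Sneppen)
#'
#' Double-edge swaps that preserve every node's degree exactly while
#' randomizing the topology; self-loops and multi-edges are never created.
#' Graphs too constrained to swap (a star, for example) come back unchanged
#' with attribute `rewire_unchanged = TRUE`.
#'
#' @param g a [binarize_proportional()] result.
#' @param n_rewires number of attempted swaps; default 10 x edge count.
#' @param seed integer seed for reproducible nulls.
#' @return A `binary_graph` with the same degree sequence.
#' @export
degree_preserving_null <- function(g, n_rewires = NULL, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  if (g$n_edges < 2L) stop("need at least 2 edges to rewire", call. = FALSE)
  if (is.null(n_rewires)) n_rewires <- 10L * g$n_edges
  ig <- as_igraph(g)
  null_ig <- withr::with_seed(as.integer(seed), {
    igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                              niter = n_rewires))
  })
  adj <- as.matrix(igraph::as_adjacency_matrix(null_ig, sparse = FALSE))
  storage.mode(adj) <- "integer"
  dimnames(adj) <- dimnames(g$adjacency)
  out <- structure(list(adjacency = adj, sparsity = g$sparsity,
                        n_edges = g$n_edges,
                        target_sparsity = g$target_sparsity),
                   class = "binary_graph")
  attr(out, "rewire_unchanged") <- identical(adj, g$adjacency)
  out
}

largest_component_fraction <- function(ig) {
  max(igraph::components(ig)$csize) / igraph::vcount(ig)
}

#' Small-world normalization against degree-preserving nulls
#'
#' gamma = Cp / mean(Cp of nulls), lambda = Lp / mean(Lp of nulls),
#' sigma = gamma / lambda. A small-world network shows gamma >> 1 with
#' lambda close to 1, hence sigma > 1. Nulls are seeded so the whole sweep is
#' reproducible. Warns when the largest connected component covers less than
#' 90% of the nodes, where Lp over connected pairs becomes hard to interpret.
#'
#' @param g a [binarize_proportional()] result.
#' @param n_null number of null networks (default 100).
#' @param seed integer seed.
#' @param n_rewires swap attempts per null; default 10 x edge count.
#' @return Named list `gamma`, `lambda`, `sigma`, `cp`, `lp`, `cp_null`,
#'   `lp_null` (null means).
#' @export
small_world <- function(g, n_null = 100L, seed = 1L, n_rewires = NULL) {
  stopifnot(inherits(g, "binary_graph"))
  ig <- as_igraph(g)
  if (largest_component_fraction(ig) < 0.9) {
    warning("largest connected component covers < 90% of nodes; ",
            "path-based normalization may be unstable", call. = FALSE)
  }
  cp <- clustering_metrics(g)$cp
  lp <- shortest_path_metrics(g)$lp
  if (is.null(n_rewires)) n_rewires <- 10L * g$n_edges
  cps <- numeric(n_null)
  lps <- numeric(n_null)
  # one seeded stream for all nulls of this graph; rewiring and metrics stay
  # on the igraph object to avoid per-null adjacency round-trips
  withr::with_seed(as.integer(seed), {
    for (i in seq_len(n_null)) {
      nul <- igraph::rewire(ig, igraph::keeping_degseq(loops = FALSE,
                                                       niter = n_rewires))
      cps[i] <- igraph::transitivity(nul, type = "localaverage",
                                     isolates = "zero")
      lps[i] <- igraph::mean_distance(nul, unconnected = TRUE)
    }
  })
  cp_null <- mean(cps)
  lp_null <- mean(lps, na.rm = TRUE)
  if (!is.finite(cp_null) || cp_null == 0) {
    stop("mean null clustering is zero: gamma undefined", call. = FALSE)
  }
  gam <- cp / cp_null
  lam <- lp / lp_null
  list(gamma = gam, lambda = lam, sigma = gam / lam,
       cp = cp, lp = lp, cp_null = cp_null, lp_null = lp_null)
}

#' All seven global metrics of one binary graph
#'
#' @inheritParams small_world
#' @return Named list: `eg`, `eloc`, `lp`, `cp`, `gamma`, `lambda`, `sigma`,
#'   `sparsity`. When `n_null = 0` the normalized metrics are `NA`.
#' @export
global_metrics <- function(g, n_null = 100L, seed = 1L, n_rewires = NULL) {
  sp <- shortest_path_metrics(g)
  cl <- clustering_metrics(g)
  out <- list(eg = sp$eg, eloc = cl$eloc, lp = sp$lp, cp = cl$cp,
              gamma = NA_real_, lambda = NA_real_, sigma = NA_real_,
              sparsity = g$sparsity)
  if (n_null > 0L) {
    sw <- small_world(g, n_null = n_null, seed = seed, n_rewires = n_rewires)
    out$gamma <- sw$gamma
    out$lambda <- sw$lambda
    out$sigma <- sw$sigma
  }
  out
}

#' Sweep a connectivity matrix across the sparsity grid
#'
#' Binarizes the matrix at every threshold of the grid and computes the seven
#' global metrics. Per-threshold failures (for example too few nonnegative
#' edge candidates at a dense threshold of a signed network) are recorded in
#' the `failures` attribute and yield NA rows; they are never silently
#' dropped.
#'
#' @param m a [connectivity_matrix()] or plain symmetric matrix.
#' @param grid a [threshold_grid()] (default 0.05-0.50 step 0.01).
#' @param n_null null networks per threshold for gamma/lambda/sigma; 0 skips
#'   the normalized metrics.
#' @param seed integer seed; each threshold draws its nulls from an offset of
#'   it, so curves are reproducible.
#' @param rank_abs passed to [binarize_proportional()].
#' @return Data frame of class `metric_sweep` with columns `sparsity`, `eg`,
#'   `eloc`, `lp`, `cp`, `gamma`, `lambda`, `sigma`; attribute `failures`
#'   is a data frame of per-threshold error messages (possibly empty).
#' @export
sweep_thresholds <- function(m, grid = threshold_grid(), n_null = 100L,
                             seed = 1L, rank_abs = FALSE) {
  grid <- as.numeric(grid)
  cols <- c("eg", "eloc", "lp", "cp", "gamma", "lambda", "sigma")
  out <- data.frame(sparsity = grid)
  for (cc in cols) out[[cc]] <- NA_real_
  failures <- data.frame(sparsity = numeric(0), message = character(0))
  for (i in seq_along(grid)) {
    g <- tryCatch(binarize_proportional(m, grid[i], rank_abs = rank_abs),
                  error = function(e) e)
    if (inherits(g, "error")) {
      failures <- rbind(failures,
                        data.frame(sparsity = grid[i],
                                   message = conditionMessage(g)))
      next
    }
    base <- tryCatch(global_metrics(g, n_null = 0L), error = function(e) e)
    if (inherits(base, "error")) {
      failures <- rbind(failures,
                        data.frame(sparsity = grid[i],
                                   message = conditionMessage(base)))
      next
    }
    for (cc in c("eg", "eloc", "lp", "cp")) out[[cc]][i] <- base[[cc]]
    if (n_null > 0L) {
      # normalization can fail on its own (e.g. triangle-free nulls);
      # keep the base metrics and record the failure
      sw <- tryCatch(small_world(g, n_null = n_null,
                                 seed = as.integer(seed) + 1000L * (i - 1L)),
                     error = function(e) e)
      if (inherits(sw, "error")) {
        failures <- rbind(failures,
                          data.frame(sparsity = grid[i],
                                     message = conditionMessage(sw)))
      } else {
        out$gamma[i] <- sw$gamma
        out$lambda[i] <- sw$lambda
        out$sigma[i] <- sw$sigma
      }
    }
  }
  attr(out, "failures") <- failures
  class(out) <- c("metric_sweep", "data.frame")
  out
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integration of the metric values against sparsity; a
#' threshold-free scalar summary of the whole curve.
#'
#' @param values metric values along the grid (or a `metric_sweep` column).
#' @param sparsity the sparsity grid.
#' @return The AUC (a single number).
#' @export
auc_of_curve <- function(values, sparsity) {
  if (length(values) != length(sparsity)) {
    stop("values and sparsity lengths differ", call. = FALSE)
  }
  if (length(values) < 2L) {
    stop("AUC needs at least 2 grid points", call. = FALSE)
  }
  if (anyNA(values)) {
    stop("AUC undefined: metric values missing at some thresholds",
         call. = FALSE)
  }
  n <- length(values)
  sum(diff(sparsity) * (values[-1L] + values[-n]) / 2)
}

#' AUC of every metric in a sweep
#'
#' @param sweep a [sweep_thresholds()] result.
#' @return Named numeric vector of AUCs (NA where a curve is incomplete).
#' @export
sweep_auc <- function(sweep) {
  stopifnot(inherits(sweep, "metric_sweep"))
  cols <- setdiff(names(sweep), "sparsity")
  vapply(cols, function(cc) {
    v <- sweep[[cc]]
    if (anyNA(v)) NA_real_ else auc_of_curve(v, sweep$sparsity)
  }, numeric(1))
}
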