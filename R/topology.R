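#' Weight-to-distance mapping for path-based graph metrics
#'
#' Connection weights are rescaled to (0, 1\] by dividing by the largest
#' weight, and distances are their reciprocals: `d_ij = 1 / (w_ij / max(w))`
#' for positive weights and `Inf` for absent edges (which therefore never
#' enter shortest paths). An alternative `-log(w/max(w))` mapping is
#' available for users who prefer multiplicative path costs. When comparing
#' a lesioned (spared) graph against its normative reference, pass the
#' reference's maximum as `wmax` so both graphs share one scale — this keeps
#' efficiency monotone under edge-weight decreases.
#'
#' @param W Symmetric non-negative weight matrix.
#' @param method `"inverse"` (default) or `"neglog"`.
#' @param wmax Normalising weight; defaults to `max(W)`.
#' @return A distance matrix with zero diagonal and `Inf` on absent edges.
#' @export
to_distance <- function(W, method = c("inverse", "neglog"), wmax = max(W)) {
  method <- match.arg(method)
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (any(W < 0)) abort("weights must be non-negative")
  if (wmax <= 0) abort("all-zero graph: no distances defined")
  wt <- W / wmax
  d <- matrix(Inf, nrow(W), ncol(W))
  pos <- wt > 0
  d[pos] <- if (method == "inverse") 1 / wt[pos] else -log(wt[pos])
  # -log of the max-weight edge is 0; floor at a tiny positive cost
  if (method == "neglog") d[pos] <- pmax(d[pos], 1e-12)
  diag(d) <- 0
  d
}

# all-pairs shortest path distances through igraph (Dijkstra)
shortest_dists <- function(W, method = "inverse", wmax = max(W)) {
  d <- to_distance(W, method, wmax)
  adj <- d
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, weighted = TRUE,
                                           mode = "undirected", diag = FALSE)
  igraph::distances(g, weights = igraph::E(g)$weight)
}

#' Global efficiency of a weighted graph
#'
#' Mean inverse shortest-path distance over ordered node pairs, with
#' disconnected pairs contributing 0; lies in \[0, 1\] after the weight
#' rescaling of [to_distance()]. Equals 1 for a complete equal-weight graph.
#'
#' @inheritParams to_distance
#' @return Scalar efficiency in \[0, 1\] (for `wmax >= max(W)`).
#' @export
global_efficiency <- function(W, method = "inverse", wmax = max(W)) {
  n <- nrow(W)
  if (n < 2 || max(W) == 0) return(0)
  sp <- shortest_dists(W, method, wmax)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

max_betweenness <- function(W, method = "inverse") {
  n <- nrow(W)
  if (n < 3 || max(W) == 0) return(0)
  d <- to_distance(W, method)
  adj <- d
  adj[!is.finite(adj)] <- 0
  diag(adj) <- 0
  g <- igraph::graph_from_adjacency_matrix(adj, weighted = TRUE,
                                           mode = "undirected", diag = FALSE)
  bc <- igraph::betweenness(g, weights = igraph::E(g)$weight)
  max(bc) / ((n - 1) * (n - 2) / 2)
}

# BCT-style weighted assortativity: correlation of endpoint strengths over
# edges; returns 0 on degenerate (constant-strength) graphs
strength_assortativity <- function(W) {
  s <- rowSums(W)
  e <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  if (nrow(e) < 2) return(0)
  x <- s[e[, 1]]; y <- s[e[, 2]]
  num <- mean(x * y) - mean((x + y) / 2)^2
  den <- mean((x^2 + y^2) / 2) - mean((x + y) / 2)^2
  if (den < 1e-12) 0 else num / den
}

# Onnela weighted clustering: per-node geometric-mean triangle intensity
onnela_clustering <- function(W, wmax = max(W)) {
  if (wmax == 0) return(list(mean = 0, transitivity = 0))
  A <- (W / wmax)^(1 / 3)
  tri <- diag(A %*% A %*% A)          # 2 x weighted triangles around i
  k <- rowSums(W > 0)
  denom <- k * (k - 1)
  ci <- ifelse(denom > 0, tri / denom, 0)
  list(mean = mean(ci),
       transitivity = if (sum(denom) > 0) sum(tri) / sum(denom) else 0)
}

#' Graph-topology feature vector of a spared network
#'
#' Computes the 15-metric topology profile of a subject's spared weighted
#' undirected graph: global efficiency, characteristic path length (mean
#' finite shortest-path distance), mean weighted clustering coefficient
#' (Onnela), weighted transitivity, modularity Q *evaluated* at the fixed
#' functional-module partition (not re-estimated), strength assortativity,
#' edge density, mean strength, maximal betweenness centrality (normalised
#' by `(n-1)(n-2)/2`), the drop of maximal betweenness centrality relative
#' to the normative graph (a hub-disruption index), and the local efficiency
#' of each functional module — the global efficiency of the subgraph induced
#' by the module's nodes. Disconnected pairs contribute 0 to efficiencies
#' and are excluded from the characteristic path length.
#'
#' @param W_spared Spared weight matrix (see [spared_graph()]).
#' @param modules Character or factor vector of module labels per node.
#' @param W_norm Normative weight matrix (same nodes), used for the
#'   betweenness-drop reference. Defaults to `W_spared` (zero drop).
#' @param method Weight-to-distance mapping, see [to_distance()].
#' @return A one-row tibble of named metrics (10 global + one
#'   `local_eff_*` column per module).
#' @export
compute_topology <- function(W_spared, modules, W_norm = W_spared,
                             method = "inverse") {
  stopifnot(is.matrix(W_spared), nrow(W_spared) == ncol(W_spared),
            length(modules) == nrow(W_spared))
  n <- nrow(W_spared)
  if (n < 2) abort("graphs with < 2 nodes have no topology")
  if (max(abs(W_spared - t(W_spared))) > 1e-9) abort("graph must be symmetric")
  if (any(W_spared < 0)) abort("graph must be non-negative")

  # one weight scale for spared and normative graphs, so efficiencies are
  # comparable across subjects and monotone under disconnection
  wmax <- max(W_norm, W_spared)
  if (wmax == 0) abort("all-zero graph: no topology defined")
  sp <- shortest_dists(W_spared, method, wmax)
  inv <- 1 / sp
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  geff <- sum(inv) / (n * (n - 1))
  off <- sp[upper.tri(sp)]
  finite_off <- off[is.finite(off)]
  cpl <- if (length(finite_off)) mean(finite_off) else Inf

  cl <- onnela_clustering(W_spared, wmax)

  adj <- W_spared
  g <- igraph::graph_from_adjacency_matrix(adj, weighted = TRUE,
                                           mode = "undirected", diag = FALSE)
  memb <- as.integer(factor(modules))
  qmod <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)

  bc_spared <- max_betweenness(W_spared, method)
  bc_norm <- max_betweenness(W_norm, method)

  out <- tibble(
    global_efficiency = geff,
    char_path_length = cpl,
    mean_clustering = cl$mean,
    transitivity = cl$transitivity,
    modularity = qmod,
    assortativity = strength_assortativity(W_spared),
    density = sum(W_spared[upper.tri(W_spared)] > 0) / (n * (n - 1) / 2),
    mean_strength = mean(rowSums(W_spared)),
    max_betweenness = bc_spared,
    max_bc_drop = bc_norm - bc_spared
  )
  for (m in unique(modules)) {
    nodes <- which(modules == m)
    eff <- if (length(nodes) >= 2 && max(W_spared[nodes, nodes]) > 0) {
      global_efficiency(W_spared[nodes, nodes, drop = FALSE], method,
                        wmax = max(W_norm[nodes, nodes],
                                   W_spared[nodes, nodes]))
    } else 0
    out[[paste0("local_eff_", gsub("[^A-Za-z0-9]+", "_", m))]] <- eff
  }
  out
}
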