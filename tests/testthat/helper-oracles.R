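# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by a different route than the implementation: geometric
# slab tests instead of voxel traversal, Floyd-Warshall + shortest-path
# counting instead of igraph's Dijkstra/Brandes.

# does the closed segment a->b (mm) intersect the closed voxel box?
oracle_segment_hits_box <- function(a, b, lo, hi) {
  d <- b - a
  t0 <- 0
  t1 <- 1
  for (k in 1:3) {
    if (abs(d[k]) < 1e-300) {
      if (a[k] < lo[k] || a[k] > hi[k]) return(FALSE)
    } else {
      ta <- (lo[k] - a[k]) / d[k]
      tb <- (hi[k] - a[k]) / d[k]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
      if (t0 > t1) return(FALSE)
    }
  }
  TRUE
}

# polyline-lesion intersection by slab tests against every lesioned voxel
oracle_polyline_hits_lesion <- function(polyline, lesion) {
  idx <- which(lesion$data == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) return(FALSE)
  vs <- lesion$voxel_size
  lo <- sweep(idx - 1, 2, vs, "*") + rep(lesion$origin, each = nrow(idx))
  hi <- lo + rep(vs, each = nrow(idx))
  for (s in seq_len(nrow(polyline) - 1)) {
    a <- polyline[s, ]
    b <- polyline[s + 1, ]
    for (v in seq_len(nrow(idx))) {
      if (oracle_segment_hits_box(a, b, lo[v, ], hi[v, ])) return(TRUE)
    }
  }
  FALSE
}

# per-streamline counting oracle for the parcel-wise disconnectome
oracle_disconnectome <- function(lesion, con) {
  p <- nrow(con$W)
  lost <- matrix(0, p, p)
  for (s in seq_along(con$streamlines$points)) {
    if (oracle_polyline_hits_lesion(con$streamlines$points[[s]], lesion)) {
      e <- con$streamlines$edges[s, ]
      lost[e[1], e[2]] <- lost[e[1], e[2]] + 1
      lost[e[2], e[1]] <- lost[e[2], e[1]] + 1
    }
  }
  D <- matrix(0, p, p)
  nz <- con$W > 0
  D[nz] <- lost[nz] / con$W[nz]
  D
}

# Floyd-Warshall all-pairs shortest paths on the 1/(w/max) distance graph
oracle_fw_dist <- function(W) {
  n <- nrow(W)
  d <- matrix(Inf, n, n)
  mx <- max(W)
  pos <- W > 0
  d[pos] <- mx / W[pos]
  diag(d) <- 0
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_global_eff <- function(W) {
  n <- nrow(W)
  if (n < 2 || max(W) == 0) return(0)
  d <- oracle_fw_dist(W)
  inv <- 1 / d
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  sum(inv) / (n * (n - 1))
}

oracle_cpl <- function(W) {
  d <- oracle_fw_dist(W)
  off <- d[upper.tri(d)]
  off <- off[is.finite(off)]
  if (length(off)) mean(off) else Inf
}

# shortest-path counts by dynamic programming over the FW distance matrix,
# then betweenness as the usual pair-dependency sum
oracle_max_betweenness <- function(W, tol = 1e-9) {
  n <- nrow(W)
  if (n < 3 || max(W) == 0) return(0)
  d <- oracle_fw_dist(W)
  mx <- max(W)
  edge_d <- matrix(Inf, n, n)
  edge_d[W > 0] <- mx / W[W > 0]
  sigma <- matrix(0, n, n)
  for (s in 1:n) {
    sigma[s, s] <- 1
    for (t in order(d[s, ])) {
      if (t == s || !is.finite(d[s, t])) next
      tot <- 0
      for (v in 1:n) {
        if (v != t && is.finite(edge_d[v, t]) &&
            abs(d[s, v] + edge_d[v, t] - d[s, t]) < tol) {
          tot <- tot + sigma[s, v]
        }
      }
      sigma[s, t] <- tot
    }
  }
  bc <- numeric(n)
  for (v in 1:n) {
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
      if (s == v || t == v || !is.finite(d[s, t]) || sigma[s, t] == 0) next
      if (abs(d[s, v] + d[v, t] - d[s, t]) < tol) {
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
      }
    }
  }
  max(bc) / ((n - 1) * (n - 2) / 2)
}

# small random weighted graph; weights continuous so shortest paths are
# almost surely unique
random_graph <- function(n, p_edge = 0.6) {
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- runif(length(ut)) < p_edge
  W[ut[on]] <- runif(sum(on), 0.2, 2)
  W + t(W)
}
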