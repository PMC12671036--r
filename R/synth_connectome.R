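#' Generate a synthetic normative connectome
#'
#' Places parcels at distinct voxel centers (with an interior margin),
#' assigns them round-robin to functional modules, and draws Poisson fiber
#' counts whose mean decays exponentially with centroid distance and is
#' enriched within modules. For every edge with a positive fiber count,
#' that many streamline polylines are generated between the two parcel
#' centroids through jittered intermediate waypoints, so that
#' `W[i, j]` equals the streamline count by construction. The graph is made
#' connected by bridging components through their nearest centroid pairs.
#'
#' @param cfg A [synth_config()]. Requires `n_parcels >= 2 * n_modules`.
#' @param fiber_base Poisson mean at zero distance.
#' @param decay_mm Exponential length scale of the distance decay.
#' @param module_boost Multiplier on the mean for within-module pairs.
#' @param jitter_sd Waypoint jitter SD in mm.
#' @return A [connectome()] with streamlines.
#' @export
generate_connectome <- function(cfg, fiber_base = 12, decay_mm = 25,
                                module_boost = 4, jitter_sd = 4) {
  stopifnot(inherits(cfg, "synth_config"))
  if (any(cfg$grid_shape < 4)) abort("degenerate grid: every axis needs >= 4 voxels")
  if (cfg$n_parcels < 2 * cfg$n_modules) {
    abort("need n_parcels >= 2 * n_modules")
  }
  set.seed(derive_seed(cfg$seed, 1))
  p <- cfg$n_parcels
  vs <- cfg$voxel_size_mm
  margin <- 2L
  lo <- rep(margin, 3L)
  hi <- cfg$grid_shape - 1L - margin

  # distinct voxel positions, rejection-sampled
  pos <- matrix(0L, 0, 3)
  while (nrow(pos) < p) {
    cand <- cbind(sample(lo[1]:hi[1], p, replace = TRUE),
                  sample(lo[2]:hi[2], p, replace = TRUE),
                  sample(lo[3]:hi[3], p, replace = TRUE))
    pos <- unique(rbind(pos, cand))
  }
  pos <- pos[seq_len(p), , drop = FALSE]
  cent <- (pos + 0.5) * vs

  mods <- module_labels(cfg)[(seq_len(p) - 1L) %% cfg$n_modules + 1L]
  parcels <- tibble(label = sprintf("parcel-%02d", seq_len(p)),
                    x = cent[, 1], y = cent[, 2], z = cent[, 3],
                    module = mods)

  dmat <- as.matrix(stats::dist(cent))
  same_mod <- outer(mods, mods, "==")
  lambda <- fiber_base * exp(-dmat / decay_mm) *
    ifelse(same_mod, module_boost, 1)
  W <- matrix(0, p, p)
  ut <- which(upper.tri(W))
  W[ut] <- rpois(length(ut), lambda[ut])
  W <- W + t(W)

  # bridge disconnected components through their closest centroid pairs
  repeat {
    g <- igraph::graph_from_adjacency_matrix(W > 0, mode = "undirected")
    comp <- igraph::components(g)
    if (comp$no == 1L) break
    main <- which(comp$membership == which.max(comp$csize))
    other <- which(comp$membership != comp$membership[main[1]])
    dd <- dmat[other, main, drop = FALSE]
    k <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    i <- other[k[1]]; j <- main[k[2]]
    W[i, j] <- W[j, i] <- sample(1:3, 1)
  }

  # one polyline per fiber
  ew <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  n_stream <- sum(W[ew])
  pts <- vector("list", n_stream)
  edges <- matrix(0L, n_stream, 2)
  s <- 0L
  for (r in seq_len(nrow(ew))) {
    i <- ew[r, 1]; j <- ew[r, 2]
    for (k in seq_len(W[i, j])) {
      s <- s + 1L
      frac <- c(0.25, 0.5, 0.75)
      mid <- cent[i, ] %o% (1 - frac) + cent[j, ] %o% frac  # 3 x 3, cols = waypoints
      mid <- t(mid) + matrix(rnorm(9, 0, jitter_sd), 3, 3)
      pl <- rbind(cent[i, ], mid, cent[j, ])
      # clamp waypoints inside the grid
      mx <- cfg$grid_shape * vs
      pl <- pmin(pmax(pl, 0.1), rep(mx, each = nrow(pl)) - 0.1)
      pts[[s]] <- unname(pl)
      edges[s, ] <- c(i, j)
    }
  }
  connectome(parcels, W, list(points = pts, edges = edges))
}
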