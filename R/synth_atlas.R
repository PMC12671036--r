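#' Generate synthetic probabilistic atlases
#'
#' Synthetic stand-ins for the four probabilistic atlas tiers, built from
#' the synthetic connectome's geometry:
#' * `gray-matter`: one Gaussian probability blob per parcel centroid;
#' * `functional-network`: per functional module, the voxelwise maximum of
#'   its parcels' (broader) blobs;
#' * `white-matter`: tube-shaped blobs around the centroid-to-centroid
#'   segments of the strongest edges;
#' * `functional-disconnection`: blobs at random locations unrelated to the
#'   planted effects — a deliberately uninformative tier.
#'
#' @param cfg A [synth_config()].
#' @param con A [connectome()] from [generate_connectome()].
#' @param kind Atlas tier to build.
#' @param n_tracts Number of top-weight edges for the white-matter tier.
#' @param n_random Number of blobs for the functional-disconnection tier.
#' @return An [atlas()].
#' @export
generate_atlas <- function(cfg, con,
                           kind = c("gray-matter", "white-matter",
                                    "functional-network",
                                    "functional-disconnection"),
                           n_tracts = 30, n_random = 20) {
  kind <- match.arg(kind)
  stopifnot(inherits(cfg, "synth_config"), inherits(con, "connectome"))
  set.seed(derive_seed(cfg$seed, match(kind, c("gray-matter", "white-matter",
                                               "functional-network",
                                               "functional-disconnection")) + 10))
  g <- cfg$grid_shape
  vs <- cfg$voxel_size_mm
  vx <- (rep(seq_len(g[1]) - 1L, times = g[2] * g[3]) + 0.5) * vs
  vy <- (rep(rep(seq_len(g[2]) - 1L, each = g[1]), times = g[3]) + 0.5) * vs
  vz <- (rep(seq_len(g[3]) - 1L, each = g[1] * g[2]) + 0.5) * vs

  blob <- function(center, sigma) {
    d2 <- (vx - center[1])^2 + (vy - center[2])^2 + (vz - center[3])^2
    p <- exp(-d2 / (2 * sigma^2))
    p[p < 1e-3] <- 0
    volume3d(array(p, dim = g), voxel_size = vs)
  }
  cent <- as.matrix(con$parcels[, c("x", "y", "z")])

  maps <- switch(kind,
    "gray-matter" = {
      m <- lapply(seq_len(nrow(cent)), function(i) blob(cent[i, ], sigma = 6))
      names(m) <- con$parcels$label
      m
    },
    "functional-network" = {
      m <- lapply(unique(con$parcels$module), function(mod) {
        rows <- which(con$parcels$module == mod)
        vol <- blob(cent[rows[1], ], sigma = 8)
        for (r in rows[-1]) vol$data <- pmax(vol$data, blob(cent[r, ], 8)$data)
        vol
      })
      names(m) <- unique(con$parcels$module)
      m
    },
    "white-matter" = {
      ut <- which(upper.tri(con$W), arr.ind = TRUE)
      ord <- order(con$W[ut], decreasing = TRUE)
      keep <- ut[ord[seq_len(min(n_tracts, sum(con$W[ut] > 0)))], ,
                 drop = FALSE]
      m <- lapply(seq_len(nrow(keep)), function(r) {
        a <- cent[keep[r, 1], ]; b <- cent[keep[r, 2], ]
        ab <- b - a
        len2 <- sum(ab^2)
        t <- pmin(1, pmax(0, ((vx - a[1]) * ab[1] + (vy - a[2]) * ab[2] +
                                (vz - a[3]) * ab[3]) / len2))
        d2 <- (vx - (a[1] + t * ab[1]))^2 + (vy - (a[2] + t * ab[2]))^2 +
          (vz - (a[3] + t * ab[3]))^2
        p <- exp(-d2 / (2 * 4^2))
        p[p < 1e-3] <- 0
        volume3d(array(p, dim = g), voxel_size = vs)
      })
      names(m) <- sprintf("tract-%02d-%02d", keep[, 1], keep[, 2])
      m
    },
    "functional-disconnection" = {
      m <- lapply(seq_len(n_random), function(i) {
        blob(runif(3, 0.15, 0.85) * g * vs, sigma = 7)
      })
      names(m) <- sprintf("fdisc-%02d", seq_len(n_random))
      m
    })
  atlas(maps, kind = kind)
}
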