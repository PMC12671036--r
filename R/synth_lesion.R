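#' Macro-region partition of the synthetic grid
#'
#' The grid is partitioned into 8 labeled boxes standing in for the frontal,
#' parietal, insular, temporal and occipital lobes, the basal ganglia, the
#' cerebellum and the brainstem. This is deliberately crude geometry: only
#' region membership matters downstream (radiological flags, lesion
#' placement), not anatomical realism.
#'
#' @param cfg A [synth_config()].
#' @return A tibble with one row per region: `region` and 0-based half-open
#'   voxel bounds `x0, x1, y0, y1, z0, z1` (`x0 <= i < x1`).
#' @export
macro_regions <- function(cfg) {
  g <- cfg$grid_shape
  hx <- g[1] %/% 2L; hy <- g[2] %/% 2L; hz <- g[3] %/% 2L
  tibble(
    region = c("frontal", "parietal", "temporal", "occipital",
               "insular", "basal_ganglia", "cerebellum", "brainstem"),
    x0 = c(0L, hx, 0L, hx, 0L, hx, 0L, hx),
    x1 = c(hx, g[1], hx, g[1], hx, g[1], hx, g[1]),
    y0 = c(0L, 0L, hy, hy, 0L, 0L, hy, hy),
    y1 = c(hy, hy, g[2], g[2], hy, hy, g[2], g[2]),
    z0 = c(hz, hz, hz, hz, 0L, 0L, 0L, 0L),
    z1 = c(g[3], g[3], g[3], g[3], hz, hz, hz, hz)
  )
}

#' Synthetic macro-radiological atlas
#'
#' One binary probability map per macro-region box of [macro_regions()].
#'
#' @param cfg A [synth_config()].
#' @return An [atlas()] with `kind = "macro-radiological"`.
#' @export
generate_macro_atlas <- function(cfg) {
  regs <- macro_regions(cfg)
  maps <- lapply(seq_len(nrow(regs)), function(r) {
    v <- empty_grid(cfg)
    b <- regs[r, ]
    v$data[(b$x0 + 1):b$x1, (b$y0 + 1):b$y1, (b$z0 + 1):b$z1] <- 1L
    v
  })
  names(maps) <- regs$region
  atlas(maps, kind = "macro-radiological")
}

# lesioned voxel indices (1-based linear) for an ellipsoidal lesion of
# exactly `target_n` voxels inside the region box
lesion_voxel_idx <- function(region_label, volume_ml, cfg, seed = NULL,
                             regs = macro_regions(cfg)) {
  if (!region_label %in% macro_region_names) {
    abort(sprintf("unknown macro-region '%s'", region_label))
  }
  if (volume_ml <= 0) abort("volume_ml must be positive")
  if (!is.null(seed)) set.seed(seed)
  voxvol <- grid_voxvol_ml(cfg)
  target_n <- max(1L, as.integer(round(volume_ml / voxvol)))
  r0 <- match(region_label, regs$region)
  b <- list(x0 = regs$x0[r0], x1 = regs$x1[r0], y0 = regs$y0[r0],
            y1 = regs$y1[r0], z0 = regs$z0[r0], z1 = regs$z1[r0])
  nx <- b$x1 - b$x0; ny <- b$y1 - b$y0; nz <- b$z1 - b$z0
  if (target_n > nx * ny * nz) {
    abort(sprintf("requested volume %.2f mL exceeds capacity of region '%s'",
                  volume_ml, region_label))
  }
  # random center inside the region; the lesion is the target_n nearest
  # voxels under an anisotropic metric — a discrete solid ellipsoid of exact
  # count. The ellipsoid may straddle into neighbouring regions (as real
  # strokes straddle lobes) but stays inside the grid.
  ctr <- c(runif(1, b$x0, b$x1), runif(1, b$y0, b$y1), runif(1, b$z0, b$z1))
  axes <- exp(rnorm(3, 0, 0.3))
  g <- cfg$grid_shape
  r <- ceiling((3 * target_n / (4 * pi))^(1 / 3) * 2.5) + 2L
  repeat {
    xr <- max(0L, floor(ctr[1]) - r):min(g[1] - 1L, floor(ctr[1]) + r)
    yr <- max(0L, floor(ctr[2]) - r):min(g[2] - 1L, floor(ctr[2]) + r)
    zr <- max(0L, floor(ctr[3]) - r):min(g[3] - 1L, floor(ctr[3]) + r)
    if (length(xr) * length(yr) * length(zr) >= target_n ||
        r > max(g)) break
    r <- r * 2L
  }
  nx <- length(xr); ny <- length(yr); nz <- length(zr)
  ii <- rep(xr, times = ny * nz)
  jj <- rep(rep(yr, each = nx), times = nz)
  kk <- rep(zr, each = nx * ny)
  d2 <- ((ii + 0.5 - ctr[1]) / axes[1])^2 +
        ((jj + 0.5 - ctr[2]) / axes[2])^2 +
        ((kk + 0.5 - ctr[3]) / axes[3])^2
  pick <- order(d2)[seq_len(target_n)]
  g <- cfg$grid_shape
  sort(1L + ii[pick] + g[1] * (jj[pick] + g[2] * kk[pick]))
}

voxels_to_mask <- function(idx, cfg) {
  v <- empty_grid(cfg)
  v$data[idx] <- 1L
  v
}

#' Generate a synthetic ellipsoidal lesion
#'
#' Draws a compact, randomly anisotropic ellipsoidal binary lesion centered
#' inside the named macro-region. The realized voxel count is exactly
#' `round(volume_ml / voxel_volume)` (floored at one voxel), so the realized
#' volume is within half a voxel-volume of the request. The mask may
#' straddle into neighbouring regions — as real strokes straddle lobes —
#' but always lies entirely inside the grid.
#'
#' @param region_label One of the 8 macro-region names of [macro_regions()].
#' @param volume_ml Requested lesion volume in mL.
#' @param cfg A [synth_config()].
#' @param seed Optional integer seed for the lesion's placement.
#' @return A binary [volume3d()] lesion mask.
#' @examples
#' cfg <- synth_config(n_subjects = 2)
#' lesion_volume(generate_lesion("frontal", 1.08, cfg, seed = 7))
#' @export
generate_lesion <- function(region_label, volume_ml, cfg, seed = NULL) {
  voxels_to_mask(lesion_voxel_idx(region_label, volume_ml, cfg, seed), cfg)
}
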