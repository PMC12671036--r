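#' Configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic cohort: geometry (voxel grid, parcel
#' count, functional modules), cohort size, the lesion-volume distribution,
#' the macro-region sampling frequencies, and the planted linear effects on
#' the CES-D outcome. Defaults emulate a minor-stroke cohort: n = 233
#' subjects, small mostly monofocal lesions (median volume 1.08 mL,
#' interquartile range 0.56-2.72 mL), cerebellar strokes 16.31% and
#' brainstem strokes 7.73% (the remaining six macro-regions share the rest
#' uniformly), and planted effects of female sex (+1.38 CES-D points),
#' EPICES deprivation (+0.05/unit), MOCA (-0.20/unit), baseline depression
#' self-evaluation (+2.00/unit), frontal (+2.84) and cerebellar (+2.18)
#' location, plus a hub-disruption effect (+30 per unit of normalised
#' maximal betweenness-centrality drop of the spared graph, scaled so the
#' strongest disruptions the generator produces shift CES-D by a few
#' points).
#'
#' @param n_subjects Number of subjects.
#' @param n_parcels Number of connectome parcels (must be at least
#'   `2 * n_modules`).
#' @param n_modules Number of functional modules; the default five are
#'   visual, somato-motor, salience, cognitive-control and default-mode.
#' @param grid_shape Voxel counts per axis (each at least 4).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param effect_table Named numeric vector of linear effects on CES-D.
#'   Names must resolve to generated predictors: a clinical covariate, a
#'   macro-region name, or `"max_bc_drop"` for the topology effect.
#' @param intercept CES-D intercept.
#' @param noise_sd Gaussian noise SD on CES-D, in scale points.
#' @param lesion_volume_lognormal `c(meanlog, sdlog)` of the lesion-volume
#'   distribution in mL.
#' @param region_freq Named sampling probabilities over the 8 macro-regions.
#' @param multifocal If `TRUE`, subjects may receive a second (smaller)
#'   lesion with probability 0.25; the default is one lesion per subject.
#' @param seed Integer seed; the same config is guaranteed to regenerate a
#'   bit-identical connectome, lesions and cohort.
#' @return A `synth_config` object (a validated list).
#' @export
synth_config <- function(n_subjects = 233,
                         n_parcels = 36,
                         n_modules = 5,
                         grid_shape = c(48, 56, 48),
                         voxel_size_mm = 2,
                         effect_table = c(sex = 1.38, epices = 0.05,
                                          moca = -0.20, dep_self = 2.00,
                                          frontal = 2.84, cerebellar = 2.18,
                                          max_bc_drop = 30),
                         intercept = 14.5,
                         noise_sd = 6,
                         lesion_volume_lognormal =
                           c(meanlog = log(1.08),
                             sdlog = (log(2.72) - log(0.56)) / (2 * qnorm(0.75))),
                         region_freq = NULL,
                         multifocal = FALSE,
                         seed = 1L) {
  stopifnot(n_subjects >= 1, n_parcels >= 2, n_modules >= 1,
            length(grid_shape) == 3, voxel_size_mm > 0,
            noise_sd > 0, all(is.finite(effect_table)),
            length(lesion_volume_lognormal) == 2)
  if (n_modules > n_parcels) abort("n_modules must not exceed n_parcels")
  if (any(grid_shape < 4)) abort("degenerate grid: every axis needs >= 4 voxels")
  if (is.null(names(effect_table)) && length(effect_table) > 0) {
    abort("effect_table must be a named numeric vector")
  }
  if (is.null(region_freq)) {
    other <- (1 - 0.1631 - 0.0773) / 6
    region_freq <- c(frontal = other, parietal = other, insular = other,
                     temporal = other, occipital = other,
                     basal_ganglia = other,
                     cerebellum = 0.1631, brainstem = 0.0773)
  }
  if (!setequal(names(region_freq), macro_region_names)) {
    abort("region_freq must name exactly the 8 macro-regions")
  }
  region_freq <- region_freq[macro_region_names] / sum(region_freq)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_parcels = as.integer(n_parcels),
                 n_modules = as.integer(n_modules),
                 grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 effect_table = effect_table,
                 intercept = intercept,
                 noise_sd = noise_sd,
                 lesion_volume_lognormal = lesion_volume_lognormal,
                 region_freq = region_freq,
                 multifocal = isTRUE(multifocal),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' @export
#' @method print synth_config
print.synth_config <- function(x, ...) {
  cat(sprintf(paste0("<synth_config> n=%d, %d parcels / %d modules, grid %s @ %g mm, ",
                     "seed %d\n  planted effects: %s\n"),
              x$n_subjects, x$n_parcels, x$n_modules,
              paste(x$grid_shape, collapse = "x"), x$voxel_size_mm, x$seed,
              paste(sprintf("%s=%+g", names(x$effect_table), x$effect_table),
                    collapse = ", ")))
  invisible(x)
}

module_names_default <- c("visual", "somato-motor", "salience",
                          "cognitive-control", "default-mode")

macro_region_names <- c("frontal", "parietal", "insular", "temporal",
                        "occipital", "basal_ganglia", "cerebellum", "brainstem")

module_labels <- function(cfg) {
  if (cfg$n_modules <= length(module_names_default)) {
    module_names_default[seq_len(cfg$n_modules)]
  } else {
    c(module_names_default,
      sprintf("module-%d", seq_len(cfg$n_modules - length(module_names_default)) +
                length(module_names_default)))
  }
}

# mix a base seed with a stage offset, staying inside 32-bit integer range
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + 104729 * offset) %% 2147483629 + 1)
}

grid_voxvol_ml <- function(cfg) cfg$voxel_size_mm^3 / 1000

empty_grid <- function(cfg) {
  volume3d(array(0L, cfg$grid_shape), voxel_size = cfg$voxel_size_mm)
}
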