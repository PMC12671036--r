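#' Generate a synthetic stroke cohort with planted effects
#'
#' Draws per-subject clinical covariates from distributions matched to a
#' minor-stroke population (30% female, MOCA median 26, NIHSS median 1,
#' EPICES median ~13.6, ...), samples one lesion per subject — macro-region
#' from the configured frequency table, volume from the configured lognormal
#' — and builds the CES-D outcome as
#' `intercept + sum(effect * predictor) + N(0, noise_sd)`, clipped to
#' \[0, 60\] and rounded to an integer. Effect-table names resolve to
#' clinical covariates, macro-region indicator flags, or `"max_bc_drop"`:
#' the hub-disruption effect is planted by scoring each subject's lesion
#' through the package's own disconnectome and topology machinery (the
#' maximal betweenness-centrality drop of the spared graph) — a documented
#' circularity that makes the effect exactly recoverable by the topology
#' tier.
#'
#' All planted quantities (linear predictor, pre-noise effects, lesion voxel
#' sets) are recorded alongside the observables so recovery can be tested.
#'
#' @param cfg A [synth_config()].
#' @param con A [connectome()] with streamlines; required only when the
#'   effect table carries a non-zero `max_bc_drop` entry.
#' @param index Optional precomputed [index_streamlines()].
#' @return A `cohort` tibble, one row per subject, with clinical covariates,
#'   `region`, `volume_ml`, a `lesion_voxels` list-column (1-based linear
#'   voxel indices), the planted `max_bc_drop` (0 when not planted),
#'   `y_linpred`, and the outcome `cesd`. Attributes: `truth` (effect table,
#'   intercept, noise SD) and `cfg`.
#' @export
generate_cohort <- function(cfg, con = NULL, index = NULL) {
  stopifnot(inherits(cfg, "synth_config"))
  eff <- cfg$effect_table
  topo_eff <- if ("max_bc_drop" %in% names(eff)) eff[["max_bc_drop"]] else 0
  if (topo_eff != 0 && is.null(con)) {
    abort("a connectome is required to plant the max_bc_drop topology effect")
  }
  set.seed(derive_seed(cfg$seed, 2))
  n <- cfg$n_subjects

  clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  covars <- tibble(
    subject_id = sprintf("sub-%03d", seq_len(n)),
    sex = rbinom(n, 1, 0.2961),                       # 1 = female
    age = clip(round(rnorm(n, 58.6, 16.3)), 18, 95),
    living_alone = rbinom(n, 1, 0.2017),
    education = clip(round(rnorm(n, 4.7, 1.9)), 1, 8),
    nihss = rpois(n, 1.5),
    mrs = sample(0:4, n, replace = TRUE, prob = c(.55, .30, .10, .04, .01)),
    moca = clip(round(rnorm(n, 26.3, 2.3)), 16, 30),
    dep_self = clip(round(rnorm(n, 2, 1.8)), 0, 10),
    anx_self = clip(round(rnorm(n, 3, 2.4)), 0, 10),
    epices = round(clip(rlnorm(n, log(13.6), 0.858), 0, 100), 1)
  )

  region <- sample(names(cfg$region_freq), n, replace = TRUE,
                   prob = cfg$region_freq)
  volume_ml <- rlnorm(n, cfg$lesion_volume_lognormal[1],
                      cfg$lesion_volume_lognormal[2])
  # keep lesions small relative to their region box
  cap <- min(macro_region_capacity_ml(cfg)) * 0.4
  volume_ml <- pmin(volume_ml, cap)
  extra <- if (cfg$multifocal) rbinom(n, 1, 0.25) else rep(0L, n)
  lesion_seed <- sample.int(2147483600L, n)

  regs <- macro_regions(cfg)
  lesion_voxels <- vector("list", n)
  for (i in seq_len(n)) {
    idx <- lesion_voxel_idx(region[i], volume_ml[i], cfg,
                            seed = lesion_seed[i], regs = regs)
    if (extra[i] == 1L) {
      reg2 <- sample(names(cfg$region_freq), 1, prob = cfg$region_freq)
      idx <- sort(union(idx, lesion_voxel_idx(reg2, volume_ml[i] / 2, cfg,
                                              seed = lesion_seed[i] + 1L,
                                              regs = regs)))
    }
    lesion_voxels[[i]] <- idx
  }

  # radiological flags of the realised masks: lesions may straddle into a
  # neighbouring region, and planted location effects act on the flags the
  # radiological tier sees, not just the sampled center region
  flags <- t(vapply(lesion_voxels, region_flags_from_voxels, numeric(8),
                    cfg = cfg, regs = regs))
  colnames(flags) <- regs$region
  flags <- flags[, macro_region_names, drop = FALSE]

  drop <- rep(0, n)
  if (topo_eff != 0) {
    if (is.null(index)) index <- index_streamlines(con, cfg)
    bc_norm <- max_betweenness(con$W)
    for (i in seq_len(n)) {
      hits <- streamline_hits_idx(index, lesion_voxels[[i]])
      disc <- disconnectome_from_hits(hits, index$edges, con$W)
      drop[i] <- bc_norm - max_betweenness(con$W * (1 - disc$D))
    }
  }

  linpred <- rep(cfg$intercept, n)
  for (nm in names(eff)) {
    # clinical adjectives for regions resolve to their region flag
    region_alias <- c(cerebellar = "cerebellum")
    nm_region <- if (nm %in% names(region_alias)) region_alias[[nm]] else nm
    xi <- if (nm %in% names(covars)) {
      covars[[nm]]
    } else if (nm_region %in% macro_region_names) {
      flags[, nm_region]
    } else if (nm == "max_bc_drop") {
      drop
    } else {
      abort(sprintf("effect '%s' does not resolve to a generated predictor", nm))
    }
    linpred <- linpred + eff[[nm]] * xi
  }
  cesd <- as.integer(round(clip(linpred + rnorm(n, 0, cfg$noise_sd), 0, 60)))

  out <- dplyr::mutate(covars, region = region, volume_ml = volume_ml,
                       lesion_voxels = lesion_voxels,
                       max_bc_drop = drop, y_linpred = linpred, cesd = cesd)
  attr(out, "truth") <- list(effect_table = eff, intercept = cfg$intercept,
                             noise_sd = cfg$noise_sd)
  attr(out, "region_flags") <- flags
  attr(out, "cfg") <- cfg
  class(out) <- c("cohort", class(out))
  out
}

# which macro-region boxes does a set of linear voxel indices touch?
region_flags_from_voxels <- function(idx, cfg, regs = macro_regions(cfg)) {
  g <- cfg$grid_shape
  v <- idx - 1L
  x <- v %% g[1]
  y <- (v %/% g[1]) %% g[2]
  z <- v %/% (g[1] * g[2])
  b <- regs
  vapply(seq_len(nrow(b)), function(r) {
    as.numeric(any(x >= b$x0[r] & x < b$x1[r] &
                   y >= b$y0[r] & y < b$y1[r] &
                   z >= b$z0[r] & z < b$z1[r]))
  }, numeric(1))
}

macro_region_capacity_ml <- function(cfg) {
  b <- macro_regions(cfg)
  (b$x1 - b$x0) * (b$y1 - b$y0) * (b$z1 - b$z0) * grid_voxvol_ml(cfg)
}

#' Materialise a subject's lesion mask
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param i Subject row index.
#' @return A binary [volume3d()].
#' @export
cohort_lesion <- function(cohort, i) {
  voxels_to_mask(cohort$lesion_voxels[[i]], attr(cohort, "cfg"))
}

#' Write a cohort to disk
#'
#' Writes the per-subject covariate/outcome table as CSV (dropping the
#' lesion list-column) and one uint8 NIfTI lesion mask per subject.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory; lesions go to `dir/lesions/`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(file.path(dir, "lesions"), recursive = TRUE, showWarnings = FALSE)
  tab <- dplyr::select(as_tibble(cohort), -"lesion_voxels")
  readr::write_csv(tab, file.path(dir, "cohort.csv"))
  for (i in seq_len(nrow(cohort))) {
    write_volume(cohort_lesion(cohort, i),
                 file.path(dir, "lesions",
                           sprintf("%s.nii.gz", cohort$subject_id[i])))
  }
  invisible(dir)
}
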