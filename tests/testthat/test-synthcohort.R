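test_that("connectome generation is deterministic and well-formed", {
  cfg <- small_cfg(seed = 5)
  con1 <- generate_connectome(cfg)
  con2 <- generate_connectome(cfg)
  expect_identical(con1$W, con2$W)
  expect_identical(con1$streamlines$points, con2$streamlines$points)

  expect_equal(con1$W, t(con1$W))
  expect_true(all(diag(con1$W) == 0))
  g <- igraph::graph_from_adjacency_matrix(con1$W > 0, mode = "undirected")
  expect_equal(igraph::components(g)$no, 1L)
  # W equals streamline endpoint counts (enforced by the constructor)
  expect_s3_class(connectome(con1$parcels, con1$W, con1$streamlines),
                  "connectome")
})

test_that("a 2-parcel connectome has one edge with at least one streamline", {
  cfg <- synth_config(n_subjects = 2, n_parcels = 2, n_modules = 1,
                      grid_shape = c(12, 12, 12), seed = 2)
  con <- generate_connectome(cfg)
  expect_gte(con$W[1, 2], 1)
  expect_equal(con$W[1, 2], con$W[2, 1])
  expect_gte(length(con$streamlines$points), 1)
})

test_that("within-module fiber counts exceed between-module counts", {
  cfg <- synth_config(n_subjects = 2, n_parcels = 20, n_modules = 4,
                      grid_shape = c(24, 28, 24), seed = 8)
  con <- generate_connectome(cfg)
  same <- outer(con$parcels$module, con$parcels$module, "==")
  ut <- upper.tri(con$W)
  expect_gt(mean(con$W[ut & same]), mean(con$W[ut & !same]))
})

test_that("degenerate grids and invalid module counts are rejected", {
  expect_error(synth_config(grid_shape = c(3, 20, 20)), "degenerate")
  expect_error(synth_config(n_parcels = 4, n_modules = 5), "n_modules")
  expect_error(generate_connectome(synth_config(n_parcels = 8, n_modules = 5)),
               "2 \\* n_modules")
})

test_that("lesion volumes are realised to the exact voxel count", {
  cfg <- small_cfg()
  les <- generate_lesion("frontal", 1.08, cfg, seed = 3)
  expect_equal(sum(les$data), 135)           # 1.08 mL / 0.008 mL per voxel
  expect_equal(lesion_volume(les), 1.08)

  tiny <- generate_lesion("parietal", 0.001, cfg, seed = 3)
  expect_equal(sum(tiny$data), 1)            # floored at one voxel

  expect_error(generate_lesion("brainstem", 1e5, cfg), "capacity")
  expect_error(generate_lesion("cortex", 1, cfg), "unknown")
  expect_error(generate_lesion("frontal", -1, cfg), "positive")
})

test_that("lognormal lesion volumes have the configured median", {
  cfg <- synth_config(seed = 21)    # full-size grid: ample region capacity
  set.seed(77)
  vols <- rlnorm(100, cfg$lesion_volume_lognormal[1],
                 cfg$lesion_volume_lognormal[2])
  realized <- vapply(seq_along(vols), function(i) {
    lesion_volume(generate_lesion("occipital", vols[i], cfg, seed = i))
  }, numeric(1))
  expect_lt(abs(median(realized) - 1.08) / 1.08, 0.25)
})

test_that("cohort generation is deterministic and obeys the outcome contract", {
  cfg <- small_cfg(seed = 9)
  con <- small_connectome(9)
  coh1 <- generate_cohort(cfg, con)
  coh2 <- generate_cohort(cfg, con)
  expect_identical(coh1$cesd, coh2$cesd)
  expect_identical(coh1$lesion_voxels, coh2$lesion_voxels)

  expect_true(all(coh1$cesd == round(coh1$cesd)))
  expect_true(all(coh1$cesd >= 0 & coh1$cesd <= 60))
  expect_true(all(coh1$region %in% macro_regions(cfg)$region))
})

test_that("zero effects and vanishing noise give a constant outcome", {
  cfg <- small_cfg(seed = 4, effect_table = c(sex = 0),
                   intercept = 17, noise_sd = 1e-9)
  coh <- generate_cohort(cfg)
  expect_true(all(coh$cesd == 17))
  expect_true(all(coh$y_linpred == 17))
})

test_that("default cohort CES-D distribution sits in the target range", {
  cfg <- synth_config(seed = 14)
  con <- generate_connectome(cfg)
  coh <- generate_cohort(cfg, con)
  expect_gte(median(coh$cesd), 13)
  expect_lte(median(coh$cesd), 20.25)
  # roughly 30% female, MOCA around 26, one lesion per subject
  expect_gt(mean(coh$sex), 0.2)
  expect_lt(mean(coh$sex), 0.4)
  expect_equal(median(coh$moca), 26)
})

test_that("unresolvable effect names are rejected", {
  cfg <- small_cfg(effect_table = c(not_a_predictor = 1))
  expect_error(generate_cohort(cfg), "does not resolve")
})

test_that("connectome and cohort survive a plain-text round trip", {
  cfg <- small_cfg(seed = 6)
  con <- small_connectome(6)
  dir <- withr::local_tempdir()
  write_connectome(con, file.path(dir, "con"))
  back <- read_connectome(file.path(dir, "con"))
  expect_equal(back$W, con$W)
  expect_equal(back$parcels$module, con$parcels$module)
  expect_equal(back$streamlines$edges, con$streamlines$edges)
  expect_equal(back$streamlines$points[[3]], con$streamlines$points[[3]],
               tolerance = 1e-8)

  cfg_small <- synth_config(n_subjects = 3, n_parcels = 15, n_modules = 5,
                            grid_shape = c(24, 28, 24), seed = 6,
                            effect_table = c(sex = 1))
  coh <- generate_cohort(cfg_small)
  write_cohort(coh, file.path(dir, "cohort"))
  tab <- readr::read_csv(file.path(dir, "cohort", "cohort.csv"),
                         show_col_types = FALSE)
  expect_equal(nrow(tab), 3)
  les <- read_volume(file.path(dir, "cohort", "lesions", "sub-001.nii.gz"))
  expect_equal(which(les$data == 1), coh$lesion_voxels[[1]])
})
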