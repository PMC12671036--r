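test_that("streamline-lesion intersection handles the obvious geometries", {
  cfg <- small_cfg()
  les <- volume3d(array(0L, cfg$grid_shape), voxel_size = 2)
  les$data[6:8, 6:8, 6:8] <- 1L

  # far outside the lesion bounding box
  far <- rbind(c(40, 40, 40), c(44, 46, 44))
  expect_false(streamline_hits_lesion(far, les))

  # vertex exactly at the center of a lesioned voxel (0-based voxel 6 ->
  # center at (6 + .5) * 2 = 13 mm)
  thru <- rbind(c(1, 1, 1), c(13, 13, 13), c(40, 40, 40))
  expect_true(streamline_hits_lesion(thru, les))

  expect_error(streamline_hits_lesion(rbind(c(1, 1, 1)), les), "2 points")
})

test_that("voxel traversal agrees with the segment-box oracle on random polylines", {
  cfg <- small_cfg()
  set.seed(31)
  les <- random_lesion_mask(cfg, 120)
  ext <- cfg$grid_shape * cfg$voxel_size_mm
  for (k in 1:200) {
    npts <- sample(2:5, 1)
    pl <- cbind(runif(npts, 0, ext[1]), runif(npts, 0, ext[2]),
                runif(npts, 0, ext[3]))
    expect_equal(streamline_hits_lesion(pl, les),
                 oracle_polyline_hits_lesion(pl, les))
  }
})

test_that("disconnectome fractions match the per-streamline counting oracle", {
  cfg <- small_cfg(seed = 12)
  con <- small_connectome(12)
  idx <- index_streamlines(con, cfg)
  set.seed(13)
  for (k in 1:5) {
    les <- generate_lesion(sample(macro_regions(cfg)$region, 1),
                           rlnorm(1, log(1.08), 1), cfg, seed = 100 + k)
    disc <- compute_disconnectome(les, con, idx)
    expect_identical(disc$D, oracle_disconnectome(les, con))
  }
})

test_that("empty and total lesions give the extreme disconnectomes", {
  cfg <- small_cfg(seed = 12)
  con <- small_connectome(12)
  idx <- index_streamlines(con, cfg)
  empty <- volume3d(array(0L, cfg$grid_shape), voxel_size = 2)
  expect_true(all(compute_disconnectome(empty, con, idx)$D == 0))

  full <- volume3d(array(1L, cfg$grid_shape), voxel_size = 2)
  D <- compute_disconnectome(full, con, idx)$D
  expect_true(all(D[con$W > 0] == 1))
  expect_true(all(D[con$W == 0] == 0))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("growing a lesion never decreases any disconnection fraction", {
  cfg <- small_cfg(seed = 12)
  con <- small_connectome(12)
  idx <- index_streamlines(con, cfg)
  set.seed(5)
  a <- random_lesion_mask(cfg, 200)
  b <- a
  b$data[sample.int(prod(cfg$grid_shape), 400)] <- 1L
  Da <- compute_disconnectome(a, con, idx)$D
  Db <- compute_disconnectome(b, con, idx)$D
  expect_true(all(Db >= Da))

  # a union of two lesions disconnects at least the elementwise max
  u <- a
  c2 <- random_lesion_mask(cfg, 200)
  u$data <- array(as.integer(a$data | c2$data), dim(a$data))
  Du <- compute_disconnectome(u, con, idx)$D
  Dc <- compute_disconnectome(c2, con, idx)$D
  expect_true(all(Du >= pmax(Da, Dc) - 1e-12))
})

test_that("disconnection maps match a voxel-by-voxel oracle and threshold at 0.5", {
  cfg <- small_cfg(seed = 12)
  con <- small_connectome(12)
  idx <- index_streamlines(con, cfg)
  set.seed(6)
  les <- random_lesion_mask(cfg, 300)
  dm <- disconnection_map(les, con, idx)
  expect_true(all(dm$probability$data >= 0 & dm$probability$data <= 1))
  expect_identical(dm$binary$data,
                   array(as.integer(dm$probability$data >= 0.5),
                         dim(dm$probability$data)))

  # oracle: recount per-voxel traversals and hits from the streamline index
  hits <- vapply(seq_along(con$streamlines$points), function(s) {
    oracle_polyline_hits_lesion(con$streamlines$points[[s]], les)
  }, logical(1))
  nvox <- prod(cfg$grid_shape)
  total <- hit <- numeric(nvox)
  for (s in seq_along(idx$voxels)) {
    total[idx$voxels[[s]]] <- total[idx$voxels[[s]]] + 1
    if (hits[s]) hit[idx$voxels[[s]]] <- hit[idx$voxels[[s]]] + 1
  }
  frac <- ifelse(total > 0, hit / pmax(total, 1), 0)
  expect_equal(as.vector(dm$probability$data), frac)

  empty <- volume3d(array(0L, cfg$grid_shape), voxel_size = 2)
  expect_true(all(disconnection_map(empty, con, idx)$probability$data == 0))
})

test_that("the spared graph is the fiber count attenuated by disconnection", {
  cfg <- small_cfg(seed = 12)
  con <- small_connectome(12)
  idx <- index_streamlines(con, cfg)
  set.seed(8)
  les <- random_lesion_mask(cfg, 250)
  disc <- compute_disconnectome(les, con, idx)
  sp <- spared_graph(con, disc)
  expect_equal(sp, con$W * (1 - disc$D))
  expect_true(all(sp >= 0))
  expect_equal(sp, t(sp))

  none <- compute_disconnectome(volume3d(array(0L, cfg$grid_shape),
                                         voxel_size = 2), con, idx)
  expect_equal(spared_graph(con, none), con$W)
})

test_that("group disconnection overlay covers more voxels than the lesion overlay", {
  cfg <- synth_config(n_subjects = 30, seed = 19, effect_table = c(sex = 1))
  con <- generate_connectome(cfg)
  idx <- index_streamlines(con, cfg)
  coh <- generate_cohort(cfg, con)
  les_cov <- disc_cov <- logical(prod(cfg$grid_shape))
  for (i in seq_len(nrow(coh))) {
    les_cov[coh$lesion_voxels[[i]]] <- TRUE
    dm <- disconnection_map(cohort_lesion(coh, i), con, idx)
    disc_cov[dm$binary$data == 1] <- TRUE
  }
  expect_gt(mean(disc_cov), mean(les_cov))
})
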