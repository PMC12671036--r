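test_that("NIfTI round trip preserves data and grid geometry", {
  set.seed(1)
  arr <- array(sample(0:1, 10 * 12 * 8, replace = TRUE), c(10, 12, 8))
  vol <- volume3d(arr, voxel_size = 2, origin = c(-10, -12, -8))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(as.integer(back$data), as.integer(arr))
  expect_equal(back$voxel_size, vol$voxel_size)
  expect_equal(back$origin, vol$origin)
})

test_that("anisotropic voxel sizes come back from the header", {
  vol <- volume3d(array(runif(4 * 5 * 6), c(4, 5, 6)),
                  voxel_size = c(1, 2, 4))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  expect_equal(read_volume(path)$voxel_size, c(1, 2, 4))
})

test_that("non-3D volumes are rejected", {
  expect_error(volume3d(matrix(0, 3, 3)), "3D")
  path <- withr::local_tempfile(fileext = ".nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(4, 4, 4, 2))), path)
  expect_error(read_volume(path), "3D")
  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
})

test_that("lesion volume is voxel count times voxel volume", {
  m <- array(0L, c(20, 20, 20))
  m[seq_len(135)] <- 1L
  expect_equal(lesion_volume(volume3d(m, voxel_size = 2)), 1.08)
  m2 <- array(0L, c(20, 20, 20))
  expect_equal(lesion_volume(volume3d(m2, voxel_size = 2)), 0)
  m3 <- array(0L, c(20, 20, 20))
  m3[seq_len(1000)] <- 1L
  expect_equal(lesion_volume(volume3d(m3, voxel_size = 2)), 8)
  m3[1] <- 0.5
  expect_error(lesion_volume(volume3d(m3, voxel_size = 2)), "binary")
})

random_prob_atlas <- function(g, n_roi, kind = "gray-matter") {
  maps <- lapply(seq_len(n_roi), function(i) {
    volume3d(array(runif(prod(g)), g), voxel_size = 2)
  })
  names(maps) <- sprintf("roi%02d", seq_len(n_roi))
  atlas(maps, kind = kind)
}

test_that("lesion load is the max ROI probability over lesioned voxels", {
  g <- c(12, 12, 12)
  set.seed(42)
  atl <- random_prob_atlas(g, 10)

  les0 <- volume3d(array(0L, g), voxel_size = 2)
  expect_true(all(lesion_load(les0, atl)$load == 0))

  # single lesioned voxel: the score is exactly that voxel's probability
  les1 <- les0
  les1$data[5, 5, 5] <- 1L
  ll <- lesion_load(les1, atl)
  expect_equal(ll$load,
               vapply(atl$roi_maps, function(m) m$data[5, 5, 5], numeric(1)),
               ignore_attr = TRUE)

  # brute-force per-voxel oracle on a random 50-voxel lesion
  les <- les0
  les$data[sample.int(prod(g), 50)] <- 1L
  idx <- which(les$data == 1)
  oracle <- vapply(atl$roi_maps, function(m) max(m$data[idx]), numeric(1))
  expect_equal(lesion_load(les, atl)$load, unname(oracle))
})

test_that("lesion load is monotone and max-decomposable over unions", {
  g <- c(12, 12, 12)
  set.seed(7)
  atl <- random_prob_atlas(g, 6)
  a <- volume3d(array(0L, g), voxel_size = 2)
  a$data[sample.int(prod(g), 30)] <- 1L
  b <- a
  b$data[sample.int(prod(g), 30)] <- 1L   # superset plus extras
  expect_true(all(lesion_load(b, atl)$load >= lesion_load(a, atl)$load))

  u <- volume3d(array(as.integer(a$data | b$data), g), voxel_size = 2)
  expect_equal(lesion_load(u, atl)$load,
               pmax(lesion_load(a, atl)$load, lesion_load(b, atl)$load))
})

test_that("percent-scaled atlas maps are rescaled with a warning", {
  g <- c(6, 6, 6)
  m <- volume3d(array(runif(prod(g)) * 100, g), voxel_size = 2)
  expect_warning(atl <- atlas(list(a = m), kind = "gray-matter"),
                 "percent")
  expect_lte(max(atl$roi_maps$a$data), 1)
})

test_that("radiological flags mark exactly the overlapped macro-regions", {
  cfg <- small_cfg()
  macro <- generate_macro_atlas(cfg)
  regs <- macro_regions(cfg)

  cb <- regs[regs$region == "cerebellum", ]
  les <- volume3d(array(0L, cfg$grid_shape), voxel_size = 2)
  les$data[cb$x0 + 3, cb$y0 + 3, cb$z0 + 3] <- 1L
  fl <- radiological_flags(les, macro)
  expect_equal(fl$flag[fl$region == "cerebellum"], 1L)
  expect_equal(sum(fl$flag), 1L)

  # straddling the frontal/insular boundary sets both flags
  fr <- regs[regs$region == "frontal", ]
  les2 <- volume3d(array(0L, cfg$grid_shape), voxel_size = 2)
  les2$data[fr$x0 + 2, fr$y0 + 2, fr$z0 + 1] <- 1L       # frontal (z >= hz)
  les2$data[fr$x0 + 2, fr$y0 + 2, fr$z0] <- 1L           # insular (z < hz)
  fl2 <- radiological_flags(les2, macro)
  expect_equal(sort(fl2$region[fl2$flag == 1]), c("frontal", "insular"))

  # 20 random lesions against a direct box-overlap oracle
  set.seed(11)
  for (k in 1:20) {
    les3 <- random_lesion_mask(cfg, 40)
    ids <- which(les3$data == 1, arr.ind = TRUE) - 1L
    oracle <- vapply(seq_len(nrow(regs)), function(r) {
      b <- regs[r, ]
      any(ids[, 1] >= b$x0 & ids[, 1] < b$x1 &
          ids[, 2] >= b$y0 & ids[, 2] < b$y1 &
          ids[, 3] >= b$z0 & ids[, 3] < b$z1)
    }, logical(1))
    expect_equal(radiological_flags(les3, macro)$flag, as.integer(oracle))
  }
})
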