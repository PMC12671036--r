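# shared small fixtures, built in code

small_cfg <- function(seed = 1, ...) {
  synth_config(n_subjects = 30, n_parcels = 15, n_modules = 5,
               grid_shape = c(24, 28, 24), seed = seed, ...)
}

# a 15-parcel connectome on the small grid, cached per seed within a run
small_connectome <- local({
  cache <- list()
  function(seed = 1) {
    key <- as.character(seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <<- generate_connectome(small_cfg(seed))
    }
    cache[[key]]
  }
})

random_lesion_mask <- function(cfg, n_vox = 50) {
  g <- cfg$grid_shape
  v <- volume3d(array(0L, g), voxel_size = cfg$voxel_size_mm)
  v$data[sample.int(prod(g), n_vox)] <- 1L
  v
}
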