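#' Probabilistic atlases
#'
#' An atlas is an ordered set of named regions of interest (ROIs), each given
#' as a probability map on a common voxel grid, plus a `kind` tag saying which
#' model tier it feeds. Probabilities live in \[0, 1\]; maps supplied on a
#' percent scale (maximum > 1) are rescaled by 1/100 with a warning.
#'
#' @param roi_maps Named list of [volume3d()] probability maps, one per ROI,
#'   all on the same grid.
#' @param kind One of `"gray-matter"`, `"white-matter"`,
#'   `"functional-network"`, `"functional-disconnection"`,
#'   `"macro-radiological"`.
#' @return An `atlas` object.
#' @export
atlas <- function(roi_maps, kind = c("gray-matter", "white-matter",
                                     "functional-network",
                                     "functional-disconnection",
                                     "macro-radiological")) {
  kind <- match.arg(kind)
  stopifnot(is.list(roi_maps), length(roi_maps) >= 1)
  if (is.null(names(roi_maps)) || any(names(roi_maps) == "")) {
    abort("every ROI map must be named")
  }
  for (nm in names(roi_maps)) {
    m <- roi_maps[[nm]]
    stopifnot(inherits(m, "volume3d"))
    if (!same_grid(m, roi_maps[[1]])) {
      abort(sprintf("ROI map '%s' is not on the same grid as the first map", nm))
    }
    mx <- max(m$data)
    if (mx > 1) {
      warn(sprintf("ROI map '%s' looks percent-scaled (max %.3g); rescaling by 1/100",
                   nm, mx))
      m$data <- m$data / 100
      roi_maps[[nm]] <- m
    }
    if (min(m$data) < 0 || max(m$data) > 1) {
      abort(sprintf("ROI map '%s' has probabilities outside [0, 1]", nm))
    }
  }
  structure(list(roi_labels = names(roi_maps), roi_maps = roi_maps, kind = kind),
            class = "atlas")
}

#' @export
#' @method print atlas
print.atlas <- function(x, ...) {
  cat(sprintf("<atlas> kind '%s', %d ROIs: %s\n", x$kind, length(x$roi_labels),
              paste(head(x$roi_labels, 5), collapse = ", ")))
  invisible(x)
}

#' Atlas lesion load: maximal ROI probability over lesioned voxels
#'
#' The lesion-load score of a ROI is the maximum of its probability map over
#' the lesioned voxels, i.e. how squarely the lesion sits on the region's
#' core. A lesion with no overlap scores 0. All four atlas tiers (gray
#' matter, white matter, functional networks, functional disconnections)
#' share this operation.
#'
#' @param lesion A binary [volume3d()] lesion mask on the atlas grid.
#' @param atlas An [atlas()].
#' @return A tibble with one row per ROI: `roi`, `load` in \[0, 1\].
#' @export
lesion_load <- function(lesion, atlas) {
  stopifnot(inherits(lesion, "volume3d"), inherits(atlas, "atlas"))
  if (!is_binary_volume(lesion)) abort("lesion mask must be binary (0/1)")
  if (!same_grid(lesion, atlas$roi_maps[[1]])) {
    abort("lesion and atlas are on different grids")
  }
  idx <- which(lesion$data == 1)
  load <- vapply(atlas$roi_maps, function(m) {
    if (length(idx) == 0) 0 else max(m$data[idx])
  }, numeric(1))
  tibble(roi = atlas$roi_labels, load = unname(load))
}

#' Macroscopic radiological location flags
#'
#' Binary presence indicators for the eight macroscopic regions (frontal,
#' parietal, insular, temporal, occipital lobes, basal ganglia, cerebellum,
#' brainstem), mirroring a radiologist's categorical stroke-location reading.
#' Left/right are merged (laterality is not encoded). A region is flagged
#' when the lesion load exceeds `threshold`; the default flags any overlap.
#'
#' @param lesion A binary [volume3d()] lesion mask.
#' @param macro_atlas An [atlas()] with `kind = "macro-radiological"`.
#' @param threshold Presence threshold on the lesion-load score; a region is
#'   flagged when `load > threshold`. Default 0 (any overlap).
#' @return A tibble with one row per region: `region`, `flag` (0/1).
#' @export
radiological_flags <- function(lesion, macro_atlas, threshold = 0) {
  stopifnot(inherits(macro_atlas, "atlas"))
  if (macro_atlas$kind != "macro-radiological") {
    abort("`macro_atlas` must have kind 'macro-radiological'")
  }
  ll <- lesion_load(lesion, macro_atlas)
  tibble(region = ll$roi, flag = as.integer(ll$load > threshold))
}

#' Read / write an atlas as NIfTI maps plus a CSV manifest
#'
#' `write_atlas()` writes one NIfTI file per ROI and a `manifest.csv` with
#' columns `roi`, `file`, `kind`; `read_atlas()` reads the manifest back.
#'
#' @param atlas An [atlas()].
#' @param dir Directory for the maps and manifest.
#' @param manifest Path to a manifest CSV.
#' @return `read_atlas()` returns an `atlas`; `write_atlas()` the manifest
#'   path, invisibly.
#' @export
write_atlas <- function(atlas, dir) {
  stopifnot(inherits(atlas, "atlas"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s.nii.gz", gsub("[^A-Za-z0-9]+", "_", atlas$roi_labels))
  for (i in seq_along(files)) {
    write_volume(atlas$roi_maps[[i]], file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "manifest.csv")
  readr::write_csv(tibble(roi = atlas$roi_labels, file = files,
                          kind = atlas$kind), manifest)
  invisible(manifest)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(manifest) {
  mf <- readr::read_csv(manifest, show_col_types = FALSE)
  maps <- lapply(file.path(dirname(manifest), mf$file), read_volume)
  names(maps) <- mf$roi
  atlas(maps, kind = mf$kind[1])
}
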