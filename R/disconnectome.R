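#' Does a streamline intersect a lesion?
#'
#' The polyline is walked through the voxel grid with an exact
#' (Amanatides-Woo) traversal, so every voxel the segment chain passes
#' through is visited — there is no sampling step and no way to skip a
#' grazed voxel. Returns `TRUE` iff any traversed voxel is lesioned.
#'
#' @param polyline An n-by-3 matrix of points in mm (n >= 2).
#' @param lesion A binary [volume3d()] lesion mask.
#' @return Logical scalar.
#' @export
streamline_hits_lesion <- function(polyline, lesion) {
  stopifnot(inherits(lesion, "volume3d"))
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2) abort("polyline must have at least 2 points")
  idx <- voxels_traversed_cpp(polyline, lesion$origin, lesion$voxel_size,
                              dim(lesion$data))
  any(lesion$data[idx] == 1)
}

#' Precompute streamline voxel traversal for a connectome
#'
#' Streamlines are fixed per connectome, so the set of voxels each one
#' passes through is computed once and reused for every subject's lesion.
#'
#' @param con A [connectome()] with streamlines.
#' @param cfg A [synth_config()] (or any object with the grid geometry) or a
#'   [volume3d()] defining the reference grid.
#' @return A `streamline_index` object.
#' @export
index_streamlines <- function(con, cfg) {
  stopifnot(inherits(con, "connectome"))
  if (is.null(con$streamlines)) abort("connectome has no streamlines")
  if (inherits(cfg, "volume3d")) {
    dims <- dim(cfg$data); vs <- cfg$voxel_size; org <- cfg$origin
  } else {
    dims <- cfg$grid_shape; vs <- rep(cfg$voxel_size_mm, 3); org <- c(0, 0, 0)
  }
  vox <- traverse_streamlines_cpp(con$streamlines$points, org, vs,
                                  as.integer(dims))
  lens <- lengths(vox)
  structure(list(edges = con$streamlines$edges,
                 voxels = vox,
                 flat = unlist(vox, use.names = FALSE),
                 stream_id = rep.int(seq_along(vox), lens),
                 dims = as.integer(dims), voxel_size = vs, origin = org),
            class = "streamline_index")
}

# logical hit vector over streamlines, given lesioned linear voxel indices
streamline_hits_idx <- function(index, lesion_idx) {
  les <- logical(prod(index$dims))
  les[lesion_idx] <- TRUE
  hit_flat <- les[index$flat]
  hits <- logical(length(index$voxels))
  if (any(hit_flat)) {
    rs <- rowsum(as.integer(hit_flat), index$stream_id, reorder = TRUE)
    hits[as.integer(rownames(rs))] <- rs[, 1] > 0
  }
  hits
}

lesion_indices <- function(lesion) {
  stopifnot(inherits(lesion, "volume3d"))
  if (!is_binary_volume(lesion)) abort("lesion mask must be binary (0/1)")
  which(lesion$data == 1)
}

check_lesion_frame <- function(lesion, index) {
  if (!identical(dim(lesion$data), index$dims) ||
      max(abs(lesion$voxel_size - index$voxel_size)) > 1e-6 ||
      max(abs(lesion$origin - index$origin)) > 1e-6) {
    abort("lesion and connectome streamline index are on different grids")
  }
}

#' Parcel-wise structural disconnectome
#'
#' For every connectome edge, the fraction of its streamlines that pass
#' through the lesion: `D[i, j] = (# streamlines of {i, j} hitting the
#' lesion) / W[i, j]` where `W[i, j] > 0`, else 0. Entries are disconnection
#' fractions in \[0, 1\]; `D` is symmetric and hollow.
#'
#' @param lesion A binary [volume3d()] lesion mask in the connectome's frame.
#' @param con A [connectome()] with streamlines.
#' @param index Optional precomputed [index_streamlines()] (built on the fly
#'   otherwise).
#' @param subject_id Optional subject identifier carried on the result.
#' @return A `disconnectome` object with matrix `D`.
#' @export
compute_disconnectome <- function(lesion, con, index = NULL,
                                  subject_id = NA_character_) {
  if (is.null(index)) index <- index_streamlines(con, lesion)
  check_lesion_frame(lesion, index)
  disconnectome_from_hits(streamline_hits_idx(index, lesion_indices(lesion)),
                          index$edges, con$W, subject_id)
}

disconnectome_from_hits <- function(hits, edges, W, subject_id = NA_character_) {
  p <- nrow(W)
  lost <- matrix(0, p, p)
  if (any(hits)) {
    he <- edges[hits, , drop = FALSE]
    for (s in seq_len(nrow(he))) {
      i <- he[s, 1]; j <- he[s, 2]
      lost[i, j] <- lost[i, j] + 1
      lost[j, i] <- lost[j, i] + 1
    }
  }
  D <- matrix(0, p, p)
  nz <- W > 0
  D[nz] <- lost[nz] / W[nz]
  structure(list(D = D, subject_id = subject_id), class = "disconnectome")
}

#' @export
#' @method print disconnectome
print.disconnectome <- function(x, ...) {
  cat(sprintf("<disconnectome> %d parcels, %d disconnected edges (max fraction %.2f)\n",
              nrow(x$D), sum(x$D[upper.tri(x$D)] > 0), max(x$D)))
  invisible(x)
}

#' Long-format edge table of a disconnectome
#'
#' @param disc A `disconnectome`.
#' @return A tibble `subject, i, j, fraction` over the upper triangle.
#' @export
disconnectome_edges <- function(disc) {
  stopifnot(inherits(disc, "disconnectome"))
  ut <- which(upper.tri(disc$D), arr.ind = TRUE)
  tibble(subject = disc$subject_id, i = ut[, 1], j = ut[, 2],
         fraction = disc$D[ut])
}

#' Voxelwise disconnection probability map
#'
#' Per voxel, the fraction of streamlines traversing that voxel that hit
#' the lesion; voxels traversed by no streamline get 0. The binarized
#' companion thresholds at probability >= 0.5 (inclusive).
#'
#' @inheritParams compute_disconnectome
#' @return A `disconnection_map`: list with `probability` and `binary`
#'   [volume3d()] companions.
#' @export
disconnection_map <- function(lesion, con, index = NULL) {
  if (is.null(index)) index <- index_streamlines(con, lesion)
  check_lesion_frame(lesion, index)
  hits <- streamline_hits_idx(index, lesion_indices(lesion))
  nvox <- prod(index$dims)
  n_total <- tabulate(index$flat, nbins = nvox)
  n_hit <- tabulate(index$flat[hits[index$stream_id]], nbins = nvox)
  frac <- ifelse(n_total > 0, n_hit / pmax(n_total, 1L), 0)
  prob <- volume3d(array(frac, dim = index$dims),
                   voxel_size = index$voxel_size, origin = index$origin)
  bin <- prob
  bin$data <- array(as.integer(prob$data >= 0.5), dim = index$dims)
  structure(list(probability = prob, binary = bin), class = "disconnection_map")
}

#' Spared weighted graph after disconnection
#'
#' Elementwise `W * (1 - D)`: each edge keeps the fiber-count scale,
#' attenuated by its disconnection fraction.
#'
#' @param con A [connectome()].
#' @param disc A `disconnectome` on the same parcels.
#' @return A symmetric non-negative weight matrix.
#' @export
spared_graph <- function(con, disc) {
  stopifnot(inherits(con, "connectome"), inherits(disc, "disconnectome"))
  if (!identical(dim(con$W), dim(disc$D))) {
    abort("connectome and disconnectome have mismatched parcel counts")
  }
  con$W * (1 - disc$D)
}
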