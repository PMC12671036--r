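#' 3D volumes on a regular voxel grid
#'
#' A `volume3d` is a 3D scalar array on an axis-aligned voxel grid together
#' with the grid geometry: per-axis voxel sizes in mm and the world position
#' (mm) of the corner of voxel `(0, 0, 0)`. Voxel indices are 0-based and the
#' world coordinate of the *center* of voxel `(i, j, k)` is
#' `origin + (c(i, j, k) + 0.5) * voxel_size`; each voxel is the half-open box
#' `[origin + idx * voxel_size, origin + (idx + 1) * voxel_size)`.
#'
#' @param data A 3D numeric, integer or logical array.
#' @param voxel_size Voxel edge lengths in mm, length 1 (isotropic) or 3.
#' @param origin World coordinates (mm) of the corner of voxel (0,0,0).
#' @return A `volume3d` object.
#' @examples
#' v <- volume3d(array(0L, c(4, 4, 4)), voxel_size = 2)
#' lesion_volume(v)
#' @export
volume3d <- function(data, voxel_size = 2, origin = c(0, 0, 0)) {
  if (length(dim(data)) != 3L) {
    abort(sprintf("`data` must be a 3D array, got %d dimension(s)",
                  length(dim(data))))
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0),
            length(origin) == 3L, all(is.finite(origin)))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' @export
#' @method print volume3d
print.volume3d <- function(x, ...) {
  cat(sprintf("<volume3d> %s voxels @ %s mm, origin (%s)\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x"),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.volume3d <- function(x) dim(x$data)

voxel_volume_ml <- function(vol) prod(vol$voxel_size) / 1000

is_binary_volume <- function(vol) all(vol$data %in% c(0, 1))

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$voxel_size - b$voxel_size)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' Read / write volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with a diagonal sform encoding the voxel
#' sizes and origin. NIfTI places voxel *centers* at integer indices, so the
#' translation written to the header is `origin + 0.5 * voxel_size`; the
#' round trip `write_volume()` then `read_volume()` reproduces data and grid
#' geometry exactly (bit-exact data for integer volumes). Only axis-aligned
#' orientations (diagonal affines) are supported.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param vol A [volume3d()].
#' @return `read_volume()` returns a `volume3d`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1, drop = TRUE]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    abort(sprintf("expected a 3D volume, got %dD grid", length(d)))
  }
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4) {
    abort("only axis-aligned (diagonal-affine) volumes are supported")
  }
  vs <- abs(diag(rot))
  if (any(vs <= 0)) abort("voxel sizes in header must be strictly positive")
  origin <- aff[1:3, 4] - 0.5 * diag(rot)
  # fold negative axis scales into the origin so voxel_size stays positive
  neg <- diag(rot) < 0
  if (any(neg)) origin[neg] <- origin[neg] + diag(rot)[neg] * (d[neg] - 1)
  volume3d(array(as.vector(img), dim = d), voxel_size = vs, origin = origin)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  aff <- diag(4)
  diag(aff)[1:3] <- vol$voxel_size
  aff[1:3, 4] <- vol$origin + 0.5 * vol$voxel_size
  data <- vol$data
  datatype <- "auto"
  if (is_binary_volume(vol)) {
    data <- array(as.integer(data), dim = dim(data))
    datatype <- "uint8"
  }
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- vol$voxel_size
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Lesion volume in mL
#'
#' The number of lesioned voxels times the voxel volume; at the 2 mm
#' isotropic grid used throughout, one voxel is 0.008 mL.
#'
#' @param lesion A binary [volume3d()] lesion mask.
#' @return Volume in mL (scalar).
#' @examples
#' m <- array(0L, c(10, 10, 10)); m[1:5, 1:3, 1:9] <- 1L
#' lesion_volume(volume3d(m, voxel_size = 2))
#' @export
lesion_volume <- function(lesion) {
  stopifnot(inherits(lesion, "volume3d"))
  if (!is_binary_volume(lesion)) abort("lesion mask must be binary (0/1)")
  sum(lesion$data) * voxel_volume_ml(lesion)
}
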