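#' Normative streamline connectomes
#'
#' A connectome bundles (i) a parcel table — label, centroid in mm, and
#' functional-module membership —, (ii) a symmetric, hollow, non-negative
#' parcel-by-parcel fiber-count matrix `W`, and (iii) the streamline
#' polylines themselves (points in mm) with their endpoint parcel pair.
#' When streamlines are supplied, `W[i, j]` must equal the number of
#' streamlines with endpoint pair `{i, j}`.
#'
#' @param parcels A data frame with columns `label`, `x`, `y`, `z`, `module`.
#' @param W Symmetric numeric matrix of fiber counts, zero diagonal.
#' @param streamlines Optional list with `points` (list of n-by-3 matrices)
#'   and `edges` (integer matrix, one `(i, j)` row per streamline).
#' @return A `connectome` object.
#' @export
connectome <- function(parcels, W, streamlines = NULL) {
  parcels <- as_tibble(parcels)
  stopifnot(all(c("label", "x", "y", "z", "module") %in% names(parcels)))
  p <- nrow(parcels)
  stopifnot(is.matrix(W), nrow(W) == p, ncol(W) == p)
  if (max(abs(W - t(W))) > 1e-9) abort("W must be symmetric")
  if (any(diag(W) != 0)) abort("W must have a zero diagonal")
  if (any(W < 0)) abort("W must be non-negative")
  if (!is.null(streamlines)) {
    stopifnot(is.list(streamlines$points),
              is.matrix(streamlines$edges),
              length(streamlines$points) == nrow(streamlines$edges))
    counts <- matrix(0, p, p)
    e <- streamlines$edges
    for (s in seq_len(nrow(e))) {
      i <- e[s, 1]; j <- e[s, 2]
      counts[i, j] <- counts[i, j] + 1
      counts[j, i] <- counts[j, i] + 1
    }
    if (max(abs(counts - W)) > 1e-9) {
      abort("W does not match streamline endpoint counts")
    }
  }
  structure(list(parcels = parcels, W = W, streamlines = streamlines),
            class = "connectome")
}

#' @export
#' @method print connectome
print.connectome <- function(x, ...) {
  ns <- if (is.null(x$streamlines)) 0L else length(x$streamlines$points)
  cat(sprintf("<connectome> %d parcels, %d modules, %d edges, %d streamlines\n",
              nrow(x$parcels), length(unique(x$parcels$module)),
              sum(x$W[upper.tri(x$W)] > 0), ns))
  invisible(x)
}

n_parcels <- function(con) nrow(con$parcels)

#' Write / read a connectome as plain-text files
#'
#' Writes `parcels.csv` (`label, x, y, z, module`), `edges.csv`
#' (`i, j, fiber_count`, upper triangle only, 1-based) and
#' `streamlines.txt`. The streamline format is one streamline per line:
#' two integer endpoint parcel indices followed by the flattened
#' `x y z` coordinates of the polyline points, whitespace-delimited.
#'
#' @param con A [connectome()].
#' @param dir Output / input directory.
#' @return `read_connectome()` returns a `connectome`; `write_connectome()`
#'   returns `dir` invisibly.
#' @export
write_connectome <- function(con, dir) {
  stopifnot(inherits(con, "connectome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(con$parcels, file.path(dir, "parcels.csv"))
  ut <- which(upper.tri(con$W) & con$W > 0, arr.ind = TRUE)
  readr::write_csv(tibble(i = ut[, 1], j = ut[, 2],
                          fiber_count = con$W[ut]),
                   file.path(dir, "edges.csv"))
  if (!is.null(con$streamlines)) {
    lines <- vapply(seq_along(con$streamlines$points), function(s) {
      pts <- con$streamlines$points[[s]]
      paste(c(con$streamlines$edges[s, ], format(t(pts), trim = TRUE,
                                                 digits = 10)),
            collapse = " ")
    }, character(1))
    writeLines(lines, file.path(dir, "streamlines.txt"))
  }
  invisible(dir)
}

#' @rdname write_connectome
#' @export
read_connectome <- function(dir) {
  parcels <- readr::read_csv(file.path(dir, "parcels.csv"),
                             show_col_types = FALSE)
  edges <- readr::read_csv(file.path(dir, "edges.csv"),
                           show_col_types = FALSE)
  p <- nrow(parcels)
  W <- matrix(0, p, p)
  W[cbind(edges$i, edges$j)] <- edges$fiber_count
  W[cbind(edges$j, edges$i)] <- edges$fiber_count
  sl <- NULL
  sl_path <- file.path(dir, "streamlines.txt")
  if (file.exists(sl_path)) {
    lines <- readLines(sl_path)
    fields <- lapply(strsplit(trimws(lines), "\\s+"), as.numeric)
    pts <- lapply(fields, function(f) {
      matrix(f[-(1:2)], ncol = 3, byrow = TRUE)
    })
    e <- t(vapply(fields, function(f) as.integer(f[1:2]), integer(2)))
    sl <- list(points = pts, edges = e)
  }
  connectome(parcels, W, sl)
}
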