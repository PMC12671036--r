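#' Network-based statistics permutation test
#'
#' Mass-univariate edge screening with family-wise error control by
#' permutation. Each edge's disconnection fraction is regressed on the
#' outcome (univariate F statistic, df = 1 and n - 2; zero-variance edges
#' are excluded); edges with `F >= threshold` form a suprathreshold graph
#' whose connected components are the candidate subnetworks. The null
#' distribution of the maximal component statistic is built by permuting the
#' outcome, and each observed component gets
#' `p = (1 + #permutations with null max >= observed) / (n_perm + 1)`.
#' The component statistic is either its `"extent"` (number of
#' suprathreshold edges, the classic choice) or its `"intensity"` (sum of
#' `F - threshold` over its edges), which has a continuous null upper tail
#' and therefore finer-grained p-values on small graphs.
#'
#' @param edge_x Subjects-by-edges matrix of disconnection fractions.
#' @param y Numeric outcome.
#' @param edge_index Two-column integer matrix mapping edge columns to
#'   parcel pairs.
#' @param threshold Primary F threshold (> 0). The default 10 is deliberately
#'   strict; `f_threshold_p()` converts a per-edge p-value to a threshold.
#' @param n_perm Number of permutations (values < 100 draw a warning).
#' @param seed Integer seed for the permutations.
#' @param statistic Component statistic, `"extent"` or `"intensity"`.
#' @return A `psd_nbs` object: per-edge F statistics, component table with
#'   FWER p-values, `fmax` (largest edge statistic), `max_component_size`,
#'   `p_min` (1 when no component exists), and the permutation null maxima.
#' @export
nbs_test <- function(edge_x, y, edge_index, threshold = 10, n_perm = 1000,
                     seed = 1L, statistic = c("extent", "intensity")) {
  statistic <- match.arg(statistic)
  if (threshold <= 0) abort("primary threshold must be positive")
  if (n_perm < 100) warn("n_perm < 100 gives a very coarse FWER estimate")
  y <- as.numeric(y)
  n <- length(y)
  edge_x <- as.matrix(edge_x)
  stopifnot(nrow(edge_x) == n, nrow(edge_index) == ncol(edge_x))

  keep <- apply(edge_x, 2, var) > 0
  X <- scale(edge_x[, keep, drop = FALSE])
  idx <- edge_index[keep, , drop = FALSE]
  m <- ncol(X)

  f_from_y <- function(yv) {
    r <- as.numeric(crossprod(X, scale(yv))) / (n - 1)
    r2 <- pmin(r^2, 1 - 1e-12)
    (n - 2) * r2 / (1 - r2)
  }
  comp_stats <- function(fv) {
    supra <- which(fv >= threshold)
    if (length(supra) == 0) return(NULL)
    e <- idx[supra, , drop = FALSE]
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    memb <- igraph::components(g)$membership
    ce <- memb[e[, 1]]                     # component of each supra edge
    val <- if (statistic == "extent") rep(1, length(supra)) else
      fv[supra] - threshold
    st <- as.numeric(rowsum(val, ce))
    tibble(component = seq_along(st),
           n_edges = as.numeric(rowsum(rep(1, length(supra)), ce)),
           stat = st)
  }

  f_obs <- f_from_y(y)
  obs <- comp_stats(f_obs)

  set.seed(seed)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    fp <- f_from_y(y[sample.int(n)])
    cs <- comp_stats(fp)
    null_max[b] <- if (is.null(cs)) 0 else max(cs$stat)
  }

  if (is.null(obs)) {
    comps <- tibble(component = integer(), n_edges = numeric(),
                    stat = numeric(), p_fwer = numeric())
    p_min <- 1
    max_size <- 0
  } else {
    obs$p_fwer <- vapply(obs$stat, function(s) {
      (1 + sum(null_max >= s)) / (n_perm + 1)
    }, numeric(1))
    comps <- obs
    p_min <- min(obs$p_fwer)
    max_size <- max(obs$n_edges)
  }
  structure(list(edge_stats = tibble(i = idx[, 1], j = idx[, 2], f = f_obs),
                 threshold = threshold, statistic = statistic,
                 components = comps, max_component_size = max_size,
                 fmax = if (m > 0) max(f_obs) else 0,
                 p_min = p_min, n_perm = n_perm, seed = seed,
                 null_max = null_max),
            class = "psd_nbs")
}

#' @rdname nbs_test
#' @param p Per-edge p-value to convert.
#' @param n Sample size.
#' @export
f_threshold_p <- function(p, n) stats::qf(p, 1, n - 2, lower.tail = FALSE)

#' @export
#' @method print psd_nbs
print.psd_nbs <- function(x, ...) {
  cat(sprintf("<psd_nbs> %d edges, threshold F >= %.2f (%s), Fmax = %.2f\n",
              nrow(x$edge_stats), x$threshold, x$statistic, x$fmax))
  if (nrow(x$components) == 0) {
    cat("  no suprathreshold component\n")
  } else {
    cat(sprintf("  %d component(s); min FWER p = %.4f (%d permutations)\n",
                nrow(x$components), x$p_min, x$n_perm))
  }
  invisible(x)
}
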