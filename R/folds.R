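#' Repeated stratified k-fold cross-validation scheme
#'
#' Partitions are stratified on outcome tertiles: subjects are binned by the
#' empirical tertiles of `y` (boundary values go to the lower bin), each bin
#' is split into near-equal folds, and folds are assembled across bins, so
#' every fold's outcome distribution mirrors the cohort's.
#'
#' @param n_repetitions Number of independent repetitions (default 10).
#' @param n_folds Folds per repetition (default 10).
#' @param seed Integer seed for the partitions.
#' @return A `cv_scheme` object.
#' @export
cv_scheme <- function(n_repetitions = 10, n_folds = 10, seed = 1L) {
  stopifnot(n_repetitions >= 1, n_folds >= 2)
  structure(list(n_repetitions = as.integer(n_repetitions),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "cv_scheme")
}

outcome_tertile <- function(y) {
  q <- quantile(y, c(1 / 3, 2 / 3), names = FALSE)
  1L + (y > q[1]) + (y > q[2])
}

#' Build stratified fold assignments
#'
#' @param y Outcome vector (length n >= `n_folds`).
#' @param cv A [cv_scheme()].
#' @return A list of length `n_repetitions`; each element an integer vector
#'   of fold ids in `1:n_folds`, one per subject. Within each repetition the
#'   folds are disjoint and exhaustive, fold sizes within each tertile
#'   stratum differ by at most one, and each fold's stratum counts are
#'   within one subject of the proportional share.
#' @export
make_folds <- function(y, cv = cv_scheme()) {
  n <- length(y)
  if (n < cv$n_folds) abort(sprintf("n = %d < n_folds = %d", n, cv$n_folds))
  set.seed(cv$seed)
  strata <- outcome_tertile(y)
  k <- cv$n_folds
  lapply(seq_len(cv$n_repetitions), function(rep) {
    fold <- integer(n)
    load <- integer(k)
    # largest stratum first; within a stratum, deal members round-robin over
    # the folds ordered by current load, so per-stratum counts differ by at
    # most one and the extras always land on the lightest folds
    for (s in order(-tabulate(strata, 3))) {
      ids <- which(strata == s)
      if (length(ids) == 0) next
      ids <- ids[sample.int(length(ids))]
      ord <- order(load + runif(k) / 2)   # random tie-break
      fold[ids] <- ord[(seq_along(ids) - 1L) %% k + 1L]
      load <- load + tabulate(fold[ids], k)
    }
    fold
  })
}
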