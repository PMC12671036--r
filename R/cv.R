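#' Out-of-sample R-squared by repeated stratified cross-validation
#'
#' The model is refit inside every training fold (for LASSO tiers the
#' penalty is reselected inside the training fold only, by an internal
#' single-repetition stratified CV) and used to predict the held-out fold.
#' Per repetition, held-out predictions are pooled and
#' `R^2 = 1 - SS_res / SS_tot` computed over them; the reported value is
#' the mean over repetitions and may be negative for uninformative models.
#'
#' @param x Predictor matrix or data frame (or `NULL` for intercept-only).
#' @param y Numeric outcome.
#' @param cv A [cv_scheme()].
#' @param method `"glm"` or `"lasso"`.
#' @param nonnegative For `method = "lasso"`, constrain coefficients >= 0.
#' @param inner_folds Folds of the internal penalty-selection CV.
#' @return `out_of_sample_r2()` returns the scalar mean R-squared;
#'   `cv_fit()` returns a list with the held-out prediction matrix
#'   (subjects by repetitions), per-repetition R-squared, its mean `r2_out`,
#'   and the per-subject mean held-out prediction `prediction`.
#' @export
out_of_sample_r2 <- function(x, y, cv = cv_scheme(), method = c("glm", "lasso"),
                             nonnegative = FALSE, inner_folds = 5) {
  cv_fit(x, y, cv, method, nonnegative, inner_folds)$r2_out
}

#' @rdname out_of_sample_r2
#' @export
cv_fit <- function(x, y, cv = cv_scheme(), method = c("glm", "lasso"),
                   nonnegative = FALSE, inner_folds = 5) {
  method <- match.arg(method)
  y <- as.numeric(y)
  n <- length(y)
  xm <- if (is.null(x)) NULL else {
    m <- as.matrix(as.data.frame(x)); storage.mode(m) <- "double"; m
  }
  folds <- make_folds(y, cv)
  preds <- matrix(NA_real_, n, cv$n_repetitions)
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    seen <- logical(n)
    for (f in sort(unique(fold))) {
      test <- fold == f
      if (any(seen & test)) abort("leakage guard: subject assigned twice")
      seen <- seen | test
      preds[test, r] <- fold_predict(xm, y, !test, test, method, nonnegative,
                                     inner_folds,
                                     seed = derive_seed(cv$seed, r * 100 + f))
    }
    if (!all(seen)) abort("leakage guard: folds are not exhaustive")
  }
  r2_rep <- apply(preds, 2, function(p) {
    1 - sum((y - p)^2) / sum((y - mean(y))^2)
  })
  list(prediction = rowMeans(preds), predictions = preds,
       r2_per_rep = r2_rep, r2_out = mean(r2_rep))
}

fold_predict <- function(xm, y, train, test, method, nonnegative, inner_folds,
                         seed) {
  if (is.null(xm) || ncol(xm) == 0) return(rep(mean(y[train]), sum(test)))
  xtr <- xm[train, , drop = FALSE]
  if (method == "glm") {
    fit <- lm.fit(cbind(1, xtr), y[train])
    as.numeric(cbind(1, xm[test, , drop = FALSE]) %*% fit$coefficients)
  } else {
    lower <- if (nonnegative) 0 else -Inf
    path <- glmnet::glmnet(xtr, y[train], family = "gaussian",
                           lower.limits = lower, lambda.min.ratio = 0.01)
    sel <- select_lambda(xtr, y[train], path$lambda, lower,
                         cv_scheme(1, inner_folds, seed = seed))
    as.numeric(predict(path, xm[test, , drop = FALSE], s = sel$lambda))
  }
}
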