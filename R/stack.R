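#' Similarity of model predictions
#'
#' Pairwise Pearson correlations between the (cross-validated) prediction
#' vectors of subordinate models. Pairs with `|rho| >= 0.7` are flagged as
#' collinearity risks for the stacking regression.
#'
#' @param preds Subjects-by-models matrix or data frame of predictions.
#' @return The correlation matrix, with attribute `high_pairs`: a tibble of
#'   flagged pairs (`model_a`, `model_b`, `rho`).
#' @export
prediction_correlations <- function(preds) {
  pm <- as.matrix(as.data.frame(preds))
  if (ncol(pm) < 2) abort("need at least two models")
  sds <- apply(pm, 2, sd)
  if (any(sds == 0)) {
    abort(sprintf("zero-variance prediction vector(s): %s",
                  paste(colnames(pm)[sds == 0], collapse = ", ")))
  }
  rho <- cor(pm)
  hi <- which(upper.tri(rho) & abs(rho) >= 0.7, arr.ind = TRUE)
  attr(rho, "high_pairs") <- tibble(model_a = colnames(pm)[hi[, 1]],
                                    model_b = colnames(pm)[hi[, 2]],
                                    rho = rho[hi])
  rho
}

#' Hierarchical stacking of subordinate model predictions
#'
#' Forward stepwise regression whose regressors are the subordinate models'
#' prediction vectors. Starting from the intercept-only null model, each
#' step evaluates every unused prediction vector as an added regressor,
#' takes the one with the largest deviance drop (ties broken by lower model
#' index), and accepts it only if the chi-square test on the scaled Gaussian
#' deviance difference `n * log(RSS_old / RSS_new)` (df = 1) is significant
#' at `alpha`; the algorithm stops at the first rejection or when all models
#' are included. The final meta-model is refit by least squares on the
#' accepted predictions. Predictions should be cross-validated (out-of-fold)
#' so the stack does not inherit subordinate in-sample optimism.
#'
#' @param preds Subjects-by-models matrix or data frame of (out-of-fold)
#'   subordinate predictions, with model names as column names.
#' @param y Numeric outcome.
#' @param alpha Acceptance level of the deviance chi-square test.
#' @param cv Optional [cv_scheme()]; when supplied, the stack's own
#'   out-of-sample R-squared is estimated by refitting the stacking weights
#'   inside every training fold, with the selected model set held fixed —
#'   the same convention used for the GLM tiers, whose model class is also
#'   fixed across folds.
#' @param reselect If `TRUE`, the forward selection itself is re-run inside
#'   every training fold (a stricter evaluation that also charges for
#'   selection instability).
#' @return A `psd_stack` object: `included` models in entry order, the final
#'   `fit` (a `psd_fit` with coefficient inference), the deviance `trace`
#'   (one row per evaluated step), `r2_in`, `r2_out` (NA without `cv`),
#'   `aic`, and each model's marginal `subordinate_r2` (R-squared of the
#'   outcome on that prediction vector alone).
#' @export
hierarchical_stack <- function(preds, y, alpha = 0.05, cv = NULL,
                               reselect = FALSE) {
  pm <- as.matrix(as.data.frame(preds))
  if (ncol(pm) == 0) abort("no subordinate models supplied")
  if (is.null(colnames(pm))) colnames(pm) <- sprintf("m%d", seq_len(ncol(pm)))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(pm) == n)

  sel <- forward_deviance(pm, y, alpha)
  fit <- fit_glm(pm[, sel$included, drop = FALSE], y, name = "hierarchical")
  sub_r2 <- apply(pm, 2, function(p) {
    if (sd(p) == 0) 0 else cor(p, y)^2
  })
  r2_out <- NA_real_
  if (!is.null(cv)) {
    pred <- cv_fit_stack(pm, y, alpha, cv, reselect = reselect,
                         included = sel$included)
    r2_out <- pred$r2_out
  }
  structure(list(included = sel$included, fit = fit, trace = sel$trace,
                 r2_in = fit$r2_in, r2_out = r2_out, aic = fit$aic,
                 subordinate_r2 = sub_r2, alpha = alpha, y = y),
            class = "psd_stack")
}

# forward selection core; returns included set (entry order) + trace
forward_deviance <- function(pm, y, alpha) {
  n <- length(y)
  rss_of <- function(cols) {
    X <- cbind(1, pm[, cols, drop = FALSE])
    sum(lm.fit(X, y)$residuals^2)
  }
  included <- character(0)
  rss_cur <- sum((y - mean(y))^2)
  trace <- list()
  repeat {
    unused <- setdiff(colnames(pm), included)
    if (length(unused) == 0) break
    rss_new <- vapply(unused, function(m) rss_of(c(included, m)), numeric(1))
    best <- which.max(rss_cur - rss_new)  # ties -> lowest index (which.max)
    stat <- n * log(rss_cur / rss_new[best])
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    accepted <- p < alpha
    trace[[length(trace) + 1]] <-
      tibble(step = length(trace) + 1L, model = unused[best],
             rss_before = rss_cur, rss_after = unname(rss_new[best]),
             deviance_drop = unname(stat), p_value = unname(p),
             accepted = accepted)
    if (!accepted) break
    included <- c(included, unused[best])
    rss_cur <- rss_new[best]
  }
  list(included = included, trace = dplyr::bind_rows(trace))
}

# cross-validated stack R2: per training fold, refit the stacking weights
# (and optionally redo the forward selection) and predict the held-out fold
cv_fit_stack <- function(pm, y, alpha, cv, reselect = FALSE,
                         included = colnames(pm)) {
  n <- length(y)
  folds <- make_folds(y, cv)
  preds <- matrix(NA_real_, n, cv$n_repetitions)
  for (r in seq_along(folds)) {
    fold <- folds[[r]]
    for (f in sort(unique(fold))) {
      test <- fold == f
      keep <- if (reselect) {
        forward_deviance(pm[!test, , drop = FALSE], y[!test], alpha)$included
      } else included
      if (length(keep) == 0) {
        preds[test, r] <- mean(y[!test])
      } else {
        X <- cbind(1, pm[!test, keep, drop = FALSE])
        beta <- lm.fit(X, y[!test])$coefficients
        preds[test, r] <- cbind(1, pm[test, keep, drop = FALSE]) %*% beta
      }
    }
  }
  r2_rep <- apply(preds, 2, function(p) 1 - sum((y - p)^2) / sum((y - mean(y))^2))
  list(prediction = rowMeans(preds), r2_out = mean(r2_rep))
}

#' @export
#' @method print psd_stack
print.psd_stack <- function(x, ...) {
  cat(sprintf("<psd_stack> %d of %d models included: %s\n",
              length(x$included), length(x$subordinate_r2),
              if (length(x$included)) paste(x$included, collapse = " -> ")
              else "(none)"))
  cat(sprintf("  R2 in = %.3f%s, AIC = %.2f\n", x$r2_in,
              if (is.na(x$r2_out)) "" else sprintf(", R2 out = %.3f", x$r2_out),
              x$aic))
  invisible(x)
}
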