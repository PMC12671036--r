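#' Fit a (non-negative) LASSO tier model
#'
#' L1-penalised least squares on internally standardised predictors, with
#' the penalty chosen on glmnet's log-spaced grid by repeated stratified
#' cross-validated mean squared error (CV-min rule by default; the 1-SE rule
#' is available). With `nonnegative = TRUE` all coefficients are constrained
#' to be >= 0 — the convention for lesion-load tiers, where damage can only
#' add depressive risk; the topology tier leaves the sign free. Coefficients
#' are reported on the original predictor scale. An empty selection (all
#' coefficients shrunk to zero) is a valid null fit predicting the outcome
#' mean. Overall significance is an F-test of the selected non-zero model
#' against the constant model; AIC is Gaussian with the number of non-zero
#' coefficients as the model dimension.
#'
#' @param x Numeric matrix or data frame of predictors (>= 2 columns).
#' @param y Numeric outcome.
#' @param nonnegative Constrain coefficients to be non-negative.
#' @param cv A [cv_scheme()] used to pick the penalty.
#' @param lambda_rule `"min"` (default) or `"1se"`.
#' @param lambda Optional fixed penalty; skips cross-validated selection.
#' @param name Model label.
#' @return A `psd_fit` object.
#' @export
fit_lasso <- function(x, y, nonnegative = FALSE, cv = cv_scheme(),
                      lambda_rule = c("min", "1se"), lambda = NULL,
                      name = "lasso") {
  lambda_rule <- match.arg(lambda_rule)
  y <- as.numeric(y)
  xm <- as.matrix(as.data.frame(x))
  storage.mode(xm) <- "double"
  if (is.null(colnames(xm))) colnames(xm) <- sprintf("x%d", seq_len(ncol(xm)))
  lower <- if (nonnegative) 0 else -Inf

  if (is.null(lambda)) {
    full <- glmnet::glmnet(xm, y, family = "gaussian", lower.limits = lower,
                           lambda.min.ratio = 0.01)
    grid <- full$lambda
    sel <- select_lambda(xm, y, grid, lower, cv, lambda_rule)
    fit_lasso_at(xm, y, sel$lambda, lower, name = name,
                 extra = list(cv_mse = sel$cvm, lambda_grid = grid,
                              nonnegative = nonnegative))
  } else {
    fit_lasso_at(xm, y, lambda, lower, name = name,
                 extra = list(nonnegative = nonnegative))
  }
}

# cross-validated MSE over a fixed lambda grid; pooled across folds and reps
select_lambda <- function(xm, y, lambda, lower, cv, lambda_rule = "min") {
  folds <- make_folds(y, cv)
  err <- matrix(0, 0, length(lambda))
  for (rep_folds in folds) {
    for (f in sort(unique(rep_folds))) {
      test <- rep_folds == f
      fit <- glmnet::glmnet(xm[!test, , drop = FALSE], y[!test],
                            family = "gaussian", lambda = lambda,
                            lower.limits = lower)
      pred <- predict(fit, xm[test, , drop = FALSE], s = lambda)
      err <- rbind(err, colMeans((pred - y[test])^2))
    }
  }
  cvm <- colMeans(err)
  cvsd <- apply(err, 2, sd) / sqrt(nrow(err))
  i_min <- which.min(cvm)
  i <- if (lambda_rule == "1se") {
    which(cvm <= cvm[i_min] + cvsd[i_min])[1]  # largest such lambda
  } else i_min
  list(lambda = lambda[i], cvm = cvm)
}

fit_lasso_at <- function(xm, y, lambda, lower, name = "lasso", extra = list()) {
  n <- length(y)
  fit <- glmnet::glmnet(xm, y, family = "gaussian", lower.limits = lower)
  # tight-threshold exact refit at the single chosen penalty (KKT to ~1e-7);
  # muffle the benign grid-interpolation warning from duplicate lambdas
  cf <- withCallingHandlers(
    as.numeric(coef(fit, s = lambda, exact = TRUE, x = xm, y = y,
                    lower.limits = lower, thresh = 1e-12, maxit = 1e6)),
    warning = function(w) {
      if (grepl("collapsing to unique", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  names(cf) <- c("(Intercept)", colnames(xm))
  fitted <- as.numeric(cbind(1, xm) %*% cf)
  rss <- sum((y - fitted)^2)
  tss <- sum((y - mean(y))^2)
  nz <- which(cf[-1] != 0)
  k <- length(nz)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  if (k > 0 && rss > 0 && tss > rss && n > k + 1) {
    fstat <- ((tss - rss) / k) / (rss / (n - k - 1))
    fp <- pf(fstat, k, n - k - 1, lower.tail = FALSE)
  } else {
    fstat <- NA_real_
    fp <- 1
  }
  out <- new_psd_fit(name = name, method = "lasso",
                     coefficients = tibble(term = names(cf),
                                           estimate = unname(cf),
                                           std_error = NA_real_,
                                           statistic = NA_real_,
                                           p_value = NA_real_),
                     fitted = fitted, y = y, r2_in = max(r2, 0),
                     aic = gaussian_aic(n, rss, k),
                     n_predictors = k, f_statistic = fstat, p_value = fp,
                     selected = colnames(xm)[nz], lambda = lambda)
  out[names(extra)] <- extra
  out
}
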