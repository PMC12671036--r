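#' Fit an ordinary least-squares tier model
#'
#' A general linear model with an intercept and one coefficient per
#' predictor: least-squares estimates with classical standard errors,
#' two-sided t-test p-values (df = n - p - 1), in-sample
#' `R^2 = 1 - RSS/TSS`, an overall F-test against the constant model, and
#' the Gaussian AIC `n*log(RSS/n) + 2*(p + 2)` (coefficients, intercept and
#' residual variance all count as free parameters).
#'
#' @param x A data frame or numeric matrix of predictors (may have zero
#'   columns or be `NULL` for the intercept-only model).
#' @param y Numeric outcome.
#' @param name Model label carried into comparison tables.
#' @return A `psd_fit` object; see [tidy.psd_fit()] and [glance.psd_fit()].
#' @examples
#' x <- data.frame(a = rnorm(50), b = rnorm(50))
#' f <- fit_glm(x, 1 + 2 * x$a + rnorm(50), name = "demo")
#' glance(f)
#' @export
fit_glm <- function(x, y, name = "glm") {
  y <- as.numeric(y)
  n <- length(y)
  X <- design_matrix(x, n)
  p <- ncol(X) - 1L
  if (n <= p + 1) abort(sprintf("need n > p + 1 (n = %d, p = %d)", n, p))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(sprintf("design is rank-deficient; offending column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  res <- fit$residuals
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df <- n - p - 1L
  sigma2 <- rss / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(diag(xtx_inv) * sigma2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df)
  r2 <- if (tss > 0) 1 - rss / tss else 0
  if (p > 0 && tss > rss) {
    fstat <- ((tss - rss) / p) / sigma2
    fp <- pf(fstat, p, df, lower.tail = FALSE)
  } else {
    fstat <- NA_real_
    fp <- 1
  }
  new_psd_fit(name = name, method = "glm",
              coefficients = tibble(term = colnames(X), estimate = unname(beta),
                                    std_error = unname(se),
                                    statistic = unname(tval),
                                    p_value = unname(pval)),
              fitted = as.numeric(X %*% beta), y = y,
              r2_in = r2, aic = gaussian_aic(n, rss, p),
              n_predictors = p, f_statistic = fstat, p_value = fp,
              selected = colnames(X)[-1])
}

design_matrix <- function(x, n) {
  if (is.null(x)) return(matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")))
  xm <- as.matrix(as.data.frame(x))
  storage.mode(xm) <- "double"
  if (nrow(xm) != n) abort("x and y have different lengths")
  if (is.null(colnames(xm)) && ncol(xm) > 0) {
    colnames(xm) <- sprintf("x%d", seq_len(ncol(xm)))
  }
  cbind("(Intercept)" = 1, xm)
}

gaussian_aic <- function(n, rss, k) n * log(rss / n) + 2 * (k + 2)

new_psd_fit <- function(...) structure(list(...), class = "psd_fit")

#' @export
#' @method print psd_fit
print.psd_fit <- function(x, ...) {
  cat(sprintf("<psd_fit '%s'> %s, n = %d, %d predictor(s), R2 = %.3f, AIC = %.2f\n",
              x$name, x$method, length(x$y), x$n_predictors, x$r2_in, x$aic))
  if (!is.null(x$r2_out) && !is.na(x$r2_out)) {
    cat(sprintf("  out-of-sample R2 = %.3f\n", x$r2_out))
  }
  invisible(x)
}
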