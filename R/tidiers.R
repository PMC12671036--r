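#' Tidy a fitted tier model
#'
#' @param x A `psd_fit`.
#' @param ... Unused.
#' @return A tibble with one row per term: `term`, `estimate`, `std_error`,
#'   `statistic`, `p_value` (inference columns are `NA` for LASSO fits).
#' @export
tidy.psd_fit <- function(x, ...) x$coefficients

#' @rdname tidy.psd_fit
#' @export
glance.psd_fit <- function(x, ...) {
  tibble(model = x$name, method = x$method, n = length(x$y),
         n_predictors = x$n_predictors, r2_in = x$r2_in,
         r2_out = x$r2_out %||% NA_real_,
         f_statistic = x$f_statistic, p_value = x$p_value, aic = x$aic)
}

#' Tidy a hierarchical stack
#'
#' @param x A `psd_stack`.
#' @param ... Unused.
#' @return `tidy()`: the stacking coefficients with inference; `glance()`:
#'   a one-row summary compatible with comparison tables.
#' @export
tidy.psd_stack <- function(x, ...) tidy(x$fit)

#' @rdname tidy.psd_stack
#' @export
glance.psd_stack <- function(x, ...) {
  tibble(model = "hierarchical", r2_in = x$r2_in, r2_out = x$r2_out,
         p_value = x$fit$p_value, aic = x$aic,
         n_included = length(x$included))
}

#' Tidy an NBS result
#'
#' @param x A `psd_nbs`.
#' @param ... Unused.
#' @return `tidy()`: the component table (`component`, `n_edges`, `stat`,
#'   `p_fwer`); `glance()`: a one-row summary with `fmax`,
#'   `max_component_size`, `p_min`, `threshold` and `n_perm`.
#' @export
tidy.psd_nbs <- function(x, ...) x$components

#' @rdname tidy.psd_nbs
#' @export
glance.psd_nbs <- function(x, ...) {
  tibble(fmax = x$fmax, max_component_size = x$max_component_size,
         p_min = x$p_min, threshold = x$threshold, n_perm = x$n_perm,
         statistic = x$statistic)
}
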