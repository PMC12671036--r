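#' Relative model probability from AIC
#'
#' The evidence ratio `exp((aic_ref - aic_i) / 2)` of model i against a
#' reference model: 1 when the AICs are equal, small when model i has much
#' higher (worse) AIC than the reference.
#'
#' @param aic_i AIC of the model being weighed.
#' @param aic_ref AIC of the reference model (best model, or null model).
#' @return A positive scalar (vectorised over `aic_i`).
#' @examples
#' relative_probability(774.91, 722.83)  # ~4.9e-12
#' @export
relative_probability <- function(aic_i, aic_ref) {
  stopifnot(all(is.finite(aic_i)), all(is.finite(aic_ref)))
  exp((aic_ref - aic_i) / 2)
}

#' Compare fitted tier models by AIC
#'
#' Sorts models by AIC and reports, per model: in/out-of-sample R-squared,
#' the overall p-value against the constant model, AIC, the AIC difference
#' to the best model, the relative probability versus the best model and
#' versus the intercept-only null model, and a support label (`strong`
#' evidence against the model when its ΔAIC > 4, `moderate` when > 2,
#' `weak` otherwise). All fits must be on the identical subject set.
#'
#' @param fits A (optionally named) list of `psd_fit` objects.
#' @return A `psd_comparison` tibble.
#' @export
compare_models <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "psd_fit")))
  y0 <- fits[[1]]$y
  for (f in fits) {
    if (length(f$y) != length(y0) || max(abs(f$y - y0)) > 0) {
      abort("all fits must be on the identical subject set")
    }
  }
  null_fit <- fit_glm(NULL, y0, name = ".null")
  tab <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble(model = f$name, r2_in = f$r2_in,
           r2_out = if (is.null(f$r2_out)) NA_real_ else f$r2_out,
           p_value = f$p_value, aic = f$aic)
  }))
  tab <- dplyr::arrange(tab, .data$aic)
  tab <- dplyr::mutate(tab,
    delta_aic = .data$aic - .data$aic[1],
    p_vs_best = relative_probability(.data$aic, .data$aic[1]),
    p_vs_null = relative_probability(.data$aic, null_fit$aic),
    support = dplyr::case_when(.data$delta_aic > 4 ~ "strong",
                               .data$delta_aic > 2 ~ "moderate",
                               TRUE ~ "weak"))
  attr(tab, "null_aic") <- null_fit$aic
  class(tab) <- c("psd_comparison", class(tab))
  tab
}

#' Write a model-comparison table as CSV and Markdown
#'
#' Mirrors the familiar journal layout: model, within/out-of-sample
#' R-squared as percentages (2 decimals), p-value and relative
#' probabilities in 3-significant-digit scientific notation, AIC to 2
#' decimals.
#'
#' @param comparison A `psd_comparison` from [compare_models()].
#' @param path Output path without extension; writes `<path>.csv` and
#'   `<path>.md`.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(comparison, path) {
  readr::write_csv(as_tibble(comparison), paste0(path, ".csv"))
  fmt <- dplyr::transmute(as_tibble(comparison),
    model = .data$model,
    `R2 within` = sprintf("%.2f%%", 100 * .data$r2_in),
    `R2 out` = ifelse(is.na(.data$r2_out), "",
                      sprintf("%.2f%%", 100 * .data$r2_out)),
    p = signif(.data$p_value, 3),
    AIC = sprintf("%.2f", .data$aic),
    `P/P(best)` = signif(.data$p_vs_best, 3),
    `P/P(null)` = signif(.data$p_vs_null, 3))
  lines <- c(paste0("| ", paste(names(fmt), collapse = " | "), " |"),
             paste0("|", paste(rep("---", ncol(fmt)), collapse = "|"), "|"),
             vapply(seq_len(nrow(fmt)), function(i) {
               paste0("| ", paste(unlist(fmt[i, ]), collapse = " | "), " |")
             }, character(1)))
  writeLines(lines, paste0(path, ".md"))
  invisible(path)
}
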