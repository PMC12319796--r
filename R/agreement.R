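#' Pearson correlation with two-sided p-value
#'
#' Product-moment correlation between two series, with the two-sided p-value
#' from the t transform (via [stats::cor.test()]).
#'
#' @param x,y numeric vectors of equal length, n >= 3, all finite.
#' @return List with `r` and `p_value`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 3L)
    stop("need n >= 3 for a correlation test", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance in input", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

#' Bland--Altman bias and limits of agreement
#'
#' Differences are oriented as `x - y` (by convention model minus reference).
#' The bias is the mean difference and the limits of agreement are
#' `bias +/- 1.96 * SD` with the sample (n - 1) standard deviation.
#'
#' @param x,y numeric vectors of equal length, n >= 2.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' must have equal length", call. = FALSE)
  if (length(x) < 2L)
    stop("need n >= 2 for limits of agreement", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       sd = s, n = length(d))
}

#' Agreement report between two OEF series
#'
#' Combines [pearson()] and [bland_altman()] for a model-vs-reference OEF
#' comparison. Differences are oriented model minus reference
#' (`x - y`); the orientation is recorded in the output.
#'
#' @param x model OEF series (e.g. `oef_mri`).
#' @param y reference OEF series (e.g. `oef_pet`).
#' @return An object of class `"oef_agreement"`: list with `r`, `p_value`,
#'   `bias`, `loa_low`, `loa_high`, `sd`, `n`, `orientation`.
#' @export
agreement_report <- function(x, y) {
  pr <- pearson(x, y)
  ba <- bland_altman(x, y)
  structure(c(pr, ba, list(orientation = "model_minus_reference")),
            class = "oef_agreement")
}

#' @export
print.oef_agreement <- function(x, ...) {
  cat(sprintf("OEF agreement (n = %d, differences %s)\n", x$n, x$orientation))
  cat(sprintf("  Pearson r = %.3f, p = %.3g\n", x$r, x$p_value))
  cat(sprintf("  Bias = %.4f, 95%% limits of agreement [%.4f, %.4f]\n",
              x$bias, x$loa_low, x$loa_high))
  invisible(x)
}
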