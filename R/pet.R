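#' Correct CBF for incomplete water extraction
#'
#' Labeled-water PET underestimates cerebral blood flow because water does not
#' equilibrate instantaneously across the blood-brain barrier; the measured
#' flow is `E` times the true flow, with `E = 0.84` the accepted whole-brain
#' average. The correction divides the raw value by `E`.
#'
#' @param cbf_raw uncorrected CBF (any flow unit, >= 0); vectorized.
#' @param E water extraction correction factor, in (0, 1].
#' @return Corrected CBF, `cbf_raw / E`.
#' @export
correct_cbf <- function(cbf_raw, E = 0.84) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0 || E > 1)
    stop("'E' must be a single number in (0, 1]", call. = FALSE)
  if (any(!is.finite(cbf_raw)) || any(cbf_raw < 0))
    stop("'cbf_raw' must be finite and >= 0", call. = FALSE)
  cbf_raw / E
}

#' Oxygen extraction fraction from PET clearances
#'
#' For labeled molecular oxygen the unidirectional clearance is
#' `K1(O2) = CBF * OEF`, so `OEF = K1(O2) / CBF`. Values above 1 are
#' physically impossible and are flagged with a warning, never clipped.
#'
#' @param k1_o2 oxygen clearance (same flow unit as `cbf_corrected`, >= 0).
#' @param cbf_corrected extraction-corrected CBF (> 0); see [correct_cbf()].
#' @return OEF fraction(s).
#' @export
pet_oef <- function(k1_o2, cbf_corrected) {
  if (any(!is.finite(k1_o2)) || any(k1_o2 < 0))
    stop("'k1_o2' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(cbf_corrected)) || any(cbf_corrected <= 0))
    stop("'cbf_corrected' must be finite and > 0", call. = FALSE)
  out <- k1_o2 / cbf_corrected
  if (any(out > 1))
    warning(sum(out > 1), " value(s) of K1(O2)/CBF exceed 1 (OEF > 1); ",
            "left unclipped")
  out
}

#' Cerebral metabolic rate of oxygen
#'
#' `CMRO2 = K1(O2) * [O2]a`: oxygen clearance times arterial oxygen
#' concentration.
#'
#' @param k1_o2 oxygen clearance (flow unit, >= 0).
#' @param o2_a arterial oxygen concentration (mL O2 / mL blood, >= 0).
#' @return CMRO2 in (flow unit) x (mL O2 / mL blood).
#' @export
cmro2 <- function(k1_o2, o2_a) {
  if (any(!is.finite(k1_o2)) || any(k1_o2 < 0))
    stop("'k1_o2' must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(o2_a)) || any(o2_a < 0))
    stop("'o2_a' must be finite and >= 0", call. = FALSE)
  k1_o2 * o2_a
}

#' PET-arm summary table
#'
#' Applies the PET-arm computations to a per-subject table: corrects CBF for
#' incomplete water extraction, forms `oef_pet = K1(O2) / CBF`, and, when an
#' arterial oxygen concentration column `o2_a` is present, adds `cmro2`.
#'
#' @param df data frame with columns `k1_o2` and `cbf_raw` (consistent flow
#'   units), optionally `o2_a`.
#' @param E water extraction correction factor.
#' @return The input with added columns `cbf_corrected`, `oef_pet` and, if
#'   available, `cmro2`.
#' @export
pet_table <- function(df, E = 0.84) {
  .check_table(df, c("k1_o2", "cbf_raw"))
  df$cbf_corrected <- correct_cbf(df$cbf_raw, E)
  df$oef_pet <- pet_oef(df$k1_o2, df$cbf_corrected)
  if ("o2_a" %in% names(df))
    df$cmro2 <- cmro2(df$k1_o2, df$o2_a)
  df
}
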