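#' Physiological constants of the oxygen transport model
#'
#' Bundles the fixed constants of the Hill oxygen-binding model with the two
#' calibratable parameters of the capillary transport model: the tissue oxygen
#' tension `PtO2` and the oxygen transfer rate constant `k`.
#'
#' The defaults are the generally accepted literature values of the original
#' single-capillary model: `P50 = 26` mmHg, Hill coefficient `h = 2.8`,
#' hemoglobin-bound oxygen capacity `B = 0.1943` mL O2/mL blood, oxygen
#' solubility `alpha_H = 3.1e-5` mL O2/mL/mmHg, and arterial saturation
#' `S_a = 0.95`. With these values the infinite-`k` extraction ceiling
#' [limit_extraction()] evaluates to 0.60 at `PtO2 = 21.8` mmHg and to 0.50 at
#' `PtO2 = 25` mmHg, the two published anchor points; this consistency is
#' checked when the package is loaded.
#'
#' @param P50 half-saturation oxygen tension (mmHg).
#' @param h Hill coefficient (dimensionless).
#' @param B maximum hemoglobin-bound oxygen concentration (mL O2 / mL blood).
#' @param alpha_H oxygen solubility, Henry's constant (mL O2 / mL / mmHg).
#' @param S_a arterial oxygen saturation fraction, in (0, 1].
#' @param PtO2 tissue oxygen tension (mmHg, >= 0).
#' @param k oxygen transfer rate constant (1/s, > 0).
#' @return An object of class `"oef_constants"`: a named list of the seven
#'   parameters.
#' @seealso [read_constants()] to load values from a YAML/JSON config file,
#'   [hill_saturation()], [limit_extraction()].
#' @examples
#' cst <- oef_constants()
#' limit_extraction(25, cst)   # ~0.50, the original model's OEF ceiling
#' @export
oef_constants <- function(P50 = 26, h = 2.8, B = 0.1943, alpha_H = 3.1e-5,
                          S_a = 0.95, PtO2 = 21.8, k = 68) {
  cst <- list(P50 = P50, h = h, B = B, alpha_H = alpha_H,
              S_a = S_a, PtO2 = PtO2, k = k)
  for (nm in names(cst)) {
    v <- cst[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (P50 <= 0) stop("'P50' must be > 0", call. = FALSE)
  if (h <= 0) stop("'h' must be > 0", call. = FALSE)
  if (B <= 0) stop("'B' must be > 0", call. = FALSE)
  if (alpha_H <= 0) stop("'alpha_H' must be > 0", call. = FALSE)
  if (S_a <= 0 || S_a > 1) stop("'S_a' must be in (0, 1]", call. = FALSE)
  if (PtO2 < 0) stop("'PtO2' must be >= 0", call. = FALSE)
  if (k <= 0) stop("'k' must be > 0", call. = FALSE)
  structure(cst, class = "oef_constants")
}

#' @export
print.oef_constants <- function(x, ...) {
  cat("Oxygen transport model constants\n")
  cat(sprintf("  Hill binding: P50 = %g mmHg, h = %g, B = %g mL/mL, alpha_H = %g mL/mL/mmHg\n",
              x$P50, x$h, x$B, x$alpha_H))
  cat(sprintf("  Arterial saturation S_a = %g\n", x$S_a))
  cat(sprintf("  Calibratable: PtO2 = %g mmHg, k = %g 1/s  (OEF ceiling %.3f)\n",
              x$PtO2, x$k, limit_extraction(x$PtO2, x, on_no_gradient = "zero")))
  invisible(x)
}

#' Read model constants from a configuration file
#'
#' Reads a YAML (or JSON, which YAML subsumes) file with keys `alpha_H`,
#' `P50_mmHg`, `B`, `hill_h`, `S_a`, `PtO2_mmHg`, `k_per_s`. Missing keys fall
#' back to the package defaults. A default config is shipped at
#' `system.file("extdata", "constants.yaml", package = "capox")`.
#'
#' @param path path to the config file.
#' @return An [oef_constants()] object.
#' @export
read_constants <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("alpha_H", "P50_mmHg", "B", "hill_h", "S_a", "PtO2_mmHg", "k_per_s")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
  def <- oef_constants()
  pick <- function(key, fallback) if (!is.null(cfg[[key]])) cfg[[key]] else fallback
  oef_constants(P50 = pick("P50_mmHg", def$P50),
                h = pick("hill_h", def$h),
                B = pick("B", def$B),
                alpha_H = pick("alpha_H", def$alpha_H),
                S_a = pick("S_a", def$S_a),
                PtO2 = pick("PtO2_mmHg", def$PtO2),
                k = pick("k_per_s", def$k))
}

#' Hill-equation hemoglobin oxygen saturation
#'
#' \deqn{S(P) = \frac{P^h}{P^h + P_{50}^h}}
#'
#' @param P oxygen tension (mmHg, >= 0); vectorized.
#' @param constants an [oef_constants()] object.
#' @return Saturation fraction(s) in `[0, 1)`.
#' @export
hill_saturation <- function(P, constants = oef_constants()) {
  if (any(!is.finite(P)) || any(P < 0))
    stop("oxygen tension 'P' must be finite and >= 0", call. = FALSE)
  # P^h / (P^h + P50^h), written to avoid overflow for large P
  r <- (P / constants$P50)^constants$h
  r / (1 + r)
}

#' Oxygen tension from bound-oxygen concentration (inverse Hill)
#'
#' Inverts the Hill relation: \eqn{P = P_{50} (C / (B - C))^{1/h}}. The plasma
#' oxygen concentration follows as `alpha_H * P`.
#'
#' @param C hemoglobin-bound oxygen concentration (mL O2 / mL blood), in
#'   `[0, B)`; vectorized.
#' @inheritParams hill_saturation
#' @return Oxygen tension(s) in mmHg.
#' @export
plasma_tension <- function(C, constants = oef_constants()) {
  B <- constants$B
  if (any(!is.finite(C)) || any(C < 0))
    stop("bound concentration 'C' must be finite and >= 0", call. = FALSE)
  if (any(C >= B))
    stop("bound concentration 'C' must be < B = ", B,
         " (inverse Hill singularity)", call. = FALSE)
  constants$P50 * (C / (B - C))^(1 / constants$h)
}

#' Maximum oxygen extraction fraction (infinite-k limit)
#'
#' As the transfer rate constant `k` grows without bound, blood equilibrates
#' with tissue instantaneously and the transit-time distribution becomes
#' irrelevant: every capillary extracts down to the tissue equilibrium. The
#' extraction ceiling is then the closed form
#' \deqn{OEF_{max} = 1 - S(P_tO_2) / S_a.}
#'
#' @param PtO2 tissue oxygen tension (mmHg, >= 0); vectorized. Defaults to the
#'   value stored in `constants`.
#' @inheritParams hill_saturation
#' @param on_no_gradient what to do when `S(PtO2) >= S_a` (tissue tension at or
#'   above the arterial-equivalent tension, so no extraction is possible):
#'   `"zero"` returns 0, `"error"` signals an error.
#' @return Maximum OEF fraction(s) in `[0, 1)`.
#' @export
limit_extraction <- function(PtO2 = constants$PtO2, constants = oef_constants(),
                             on_no_gradient = c("zero", "error")) {
  on_no_gradient <- match.arg(on_no_gradient)
  val <- 1 - hill_saturation(PtO2, constants) / constants$S_a
  bad <- val <= 0
  if (any(bad)) {
    if (on_no_gradient == "error")
      stop("no extraction gradient: S(PtO2) >= S_a at PtO2 = ",
           paste(signif(PtO2[bad], 4), collapse = ", "), " mmHg", call. = FALSE)
    val[bad] <- 0
  }
  val
}

# Equilibrium (tissue-matched) and inflow bound-oxygen concentrations; the
# capillary ODE state lives between these two.
.c_eq <- function(constants) constants$B * hill_saturation(constants$PtO2, constants)
.c_in <- function(constants) constants$S_a * constants$B

# Error unless the constants admit extraction (inflow above equilibrium).
.check_gradient <- function(constants) {
  if (.c_eq(constants) >= .c_in(constants))
    stop("no extraction gradient: tissue tension PtO2 = ", constants$PtO2,
         " mmHg is at or above the arterial-equivalent tension ",
         signif(plasma_tension(.c_in(constants) * (1 - 1e-15), constants), 5),
         " mmHg", call. = FALSE)
  invisible(TRUE)
}
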