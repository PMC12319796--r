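#' Tissue oxygen tension from a target maximum OEF
#'
#' Inverts the infinite-`k` extraction ceiling [limit_extraction()] in closed
#' form: a target ceiling `m` requires tissue saturation
#' `S(PtO2) = S_a * (1 - m)`, hence
#' \deqn{P_tO_2 = P_{50}\left(\frac{S}{1-S}\right)^{1/h}, \quad S = S_a(1-m).}
#' This is the first step of the model calibration: in the infinite-`k` limit
#' the transit-time distribution is irrelevant, so `PtO2` alone fixes the OEF
#' ceiling, which is matched to the upper limit of OEF reported for
#' non-ischemic human brain.
#'
#' @param target_max_oef desired OEF ceiling, in (0, 1).
#' @param constants an [oef_constants()] object (its `PtO2` is ignored).
#' @return Tissue oxygen tension in mmHg.
#' @examples
#' calibrate_pto2(0.6)   # ~21.8 mmHg
#' calibrate_pto2(0.5)   # ~25 mmHg, the original model's setting
#' @export
calibrate_pto2 <- function(target_max_oef, constants = oef_constants()) {
  if (!is.numeric(target_max_oef) || length(target_max_oef) != 1L ||
      !is.finite(target_max_oef))
    stop("'target_max_oef' must be a single finite number", call. = FALSE)
  if (target_max_oef <= 0 || target_max_oef >= 1)
    stop("infeasible target ceiling ", target_max_oef,
         ": must lie strictly in (0, 1)", call. = FALSE)
  S <- constants$S_a * (1 - target_max_oef)
  constants$P50 * (S / (1 - S))^(1 / constants$h)
}

#' Transfer rate constant matching an observed OEF
#'
#' Given `PtO2` (in `constants`) and a subject's transit-time statistics,
#' finds the rate constant `k` such that the model OEF equals `target_oef`.
#' OEF is strictly increasing in `k`, so the root is unique; it is located by
#' Brent's method on `log k` over `bracket` (the log scale suits the wide
#' physiological spread of calibrated `k` and the saturation of OEF in `k`).
#'
#' @param target_oef observed OEF to match, in
#'   `(0, limit_extraction(PtO2))`. A target at or above the ceiling is
#'   unreachable at any finite `k` and signals an error reporting the ceiling.
#' @param mtt,cth subject transit-time statistics (s).
#' @param constants an [oef_constants()] object with the calibrated `PtO2`;
#'   its `k` is ignored.
#' @param bracket search interval for `k` (1/s).
#' @param tol relative tolerance on `k`.
#' @return Calibrated `k` in 1/s, with attribute `"converged"` (logical:
#'   `|model OEF - target| <= 1e-6`).
#' @examples
#' cst <- oef_constants(PtO2 = calibrate_pto2(0.6))
#' calibrate_k(0.37, mtt = 4.52, cth = 5.45, constants = cst)
#' @export
calibrate_k <- function(target_oef, mtt, cth, constants = oef_constants(),
                        bracket = c(1e-3, 1e6), tol = 1e-9) {
  if (!is.numeric(target_oef) || length(target_oef) != 1L ||
      !is.finite(target_oef) || target_oef <= 0)
    stop("'target_oef' must be a single number > 0", call. = FALSE)
  .check_gradient(constants)
  ceiling_oef <- limit_extraction(constants$PtO2, constants)
  if (target_oef >= ceiling_oef)
    stop(sprintf(paste0("unreachable target OEF %.4g: at PtO2 = %g mmHg the ",
                        "model ceiling is %.4g (infinite-k limit)"),
                 target_oef, constants$PtO2, ceiling_oef), call. = FALSE)
  oef_at <- function(logk) {
    cst <- constants
    cst$k <- exp(logk)
    .oef_many(mtt, cth, cst) - target_oef
  }
  lo <- log(bracket[1]); hi <- log(bracket[2])
  flo <- oef_at(lo); fhi <- oef_at(hi)
  if (flo > 0 || fhi < 0)
    stop(sprintf(paste0("target OEF %.4g not bracketed by k in [%g, %g] 1/s ",
                        "(model OEF spans [%.4g, %.4g])"),
                 target_oef, bracket[1], bracket[2],
                 flo + target_oef, fhi + target_oef), call. = FALSE)
  root <- stats::uniroot(oef_at, c(lo, hi), f.lower = flo, f.upper = fhi,
                         tol = tol)
  k <- exp(root$root)
  structure(k, converged = abs(root$f.root) <= 1e-6)
}

#' Calibrate the transfer rate constant across a cohort
#'
#' The full two-step calibration: fix `PtO2` so the infinite-`k` OEF ceiling
#' equals `target_max_oef` ([calibrate_pto2()]), then solve [calibrate_k()]
#' per subject so the model OEF in the calibration region matches that
#' subject's PET OEF, and summarize the per-subject rate constants. Subjects
#' whose PET OEF is at or above the model ceiling (unreachable at any `k`),
#' non-positive, or missing are excluded and reported with a reason, never
#' silently dropped.
#'
#' @param subjects data frame with columns `subject_id`, `roi`, `mtt_s`,
#'   `cth_s`, `oef_pet` (one row per subject after restriction to `roi`).
#' @param target_max_oef OEF ceiling used to fix `PtO2`.
#' @param constants an [oef_constants()] object supplying the Hill constants.
#' @param roi region used for calibration; normal-appearing white matter by
#'   convention, as the region least affected by hemodynamic pathology.
#' @return An object of class `"oef_calibration"`: list with elements
#'   `pto2` (mmHg), `k` (data frame `subject_id`, `k`, `converged`),
#'   `k_mean`, `k_median`, `k_range` (1/s, over converged subjects),
#'   `excluded` (data frame `subject_id`, `reason`), `target_max_oef`,
#'   `roi`, and `constants` (with the calibrated `PtO2` and `k = k_mean`).
#' @export
calibrate_cohort <- function(subjects, target_max_oef = 0.6,
                             constants = oef_constants(), roi = "NAWM") {
  .check_table(subjects, c("subject_id", "roi", "mtt_s", "cth_s", "oef_pet"))
  subjects <- subjects[subjects$roi == roi, , drop = FALSE]
  if (nrow(subjects) == 0L)
    stop("no subjects with roi = '", roi, "'", call. = FALSE)
  pto2 <- calibrate_pto2(target_max_oef, constants)
  cst <- constants
  cst$PtO2 <- pto2
  ceiling_oef <- limit_extraction(pto2, cst)

  ok <- rep(TRUE, nrow(subjects))
  reason <- character(nrow(subjects))
  bad <- !is.finite(subjects$oef_pet)
  reason[bad] <- "missing or non-finite PET OEF"
  low <- !bad & subjects$oef_pet <= 0
  reason[low] <- "non-positive PET OEF"
  high <- !bad & !low & subjects$oef_pet >= ceiling_oef
  reason[high] <- sprintf("PET OEF >= model ceiling %.4g", ceiling_oef)
  ok <- !(bad | low | high)

  fits <- lapply(which(ok), function(i) {
    k <- calibrate_k(subjects$oef_pet[i], subjects$mtt_s[i],
                     subjects$cth_s[i], cst)
    data.frame(subject_id = subjects$subject_id[i],
               k = as.numeric(k), converged = attr(k, "converged"))
  })
  ktab <- if (length(fits)) do.call(rbind, fits) else
    data.frame(subject_id = character(), k = numeric(), converged = logical())
  conv <- ktab$k[ktab$converged]
  if (length(conv) == 0L)
    stop("no subject could be calibrated (all excluded or non-converged)",
         call. = FALSE)
  cst$k <- mean(conv)
  structure(list(pto2 = pto2,
                 k = ktab,
                 k_mean = mean(conv),
                 k_median = stats::median(conv),
                 k_range = range(conv),
                 excluded = data.frame(subject_id = subjects$subject_id[!ok],
                                       reason = reason[!ok]),
                 target_max_oef = target_max_oef,
                 roi = roi,
                 constants = cst),
            class = "oef_calibration")
}

#' @export
print.oef_calibration <- function(x, ...) {
  cat("Two-step OEF model calibration\n")
  cat(sprintf("  Step 1: PtO2 = %.3f mmHg (OEF ceiling %.3g, region '%s')\n",
              x$pto2, x$target_max_oef, x$roi))
  cat(sprintf("  Step 2: k calibrated in %d subject(s): mean %.1f, median %.1f, range [%.1f, %.1f] 1/s\n",
              nrow(x$k), x$k_mean, x$k_median, x$k_range[1], x$k_range[2]))
  if (nrow(x$excluded))
    cat(sprintf("  Excluded %d subject(s): %s\n", nrow(x$excluded),
                paste(unique(x$excluded$reason), collapse = "; ")))
  invisible(x)
}

# Shared schema check; names every missing column.
.check_table <- function(df, cols) {
  if (!is.data.frame(df))
    stop("expected a data frame", call. = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}
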