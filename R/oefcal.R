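#' Fit the capillary OEF model to a cohort
#'
#' `oefcal()` is the package's top-level model fit. Given a per-subject,
#' per-region table of transit-time statistics and PET oxygen extraction
#' observations, it
#' \enumerate{
#'   \item fixes the tissue oxygen tension `PtO2` so the infinite-`k` OEF
#'     ceiling equals `target_max_oef` ([calibrate_pto2()]),
#'   \item calibrates the transfer rate constant `k` per subject in the
#'     calibration region and averages it ([calibrate_cohort()]),
#'   \item predicts the model OEF for every row of `data` with the common
#'     cohort `k`, and
#'   \item computes Pearson and Bland--Altman agreement between model and PET
#'     OEF per region ([agreement_report()]).
#' }
#'
#' @param data data frame with columns `subject_id`, `roi`, `mtt_s`, `cth_s`
#'   and (for calibration/agreement) `oef_pet`. If `oef_pet` is absent the fit
#'   runs in estimation-only mode: `constants` must then carry the desired
#'   `PtO2` and `k`, and no calibration or agreement is performed.
#' @param roi_calibrate region used for `k` calibration (default
#'   normal-appearing white matter).
#' @param target_max_oef OEF ceiling fixing `PtO2`.
#' @param constants an [oef_constants()] object supplying the Hill constants
#'   (and, in estimation-only mode, `PtO2` and `k`).
#' @return An object of class `"oefcal"` with components `calibration`
#'   (an `"oef_calibration"`, or `NULL` in estimation-only mode), `constants`
#'   (calibrated), `data` (input plus `oef_mri` column), `agreement` (named
#'   list of `"oef_agreement"` per region), `n_subjects`, and `call`.
#'   Supports `print`, `summary`, `coef`, `predict`, `fitted`, `residuals`,
#'   `simulate`, and `plot`.
#' @examples
#' coh <- generate_cohort(n_subjects = 12, seed = 42)
#' fit <- oefcal(coh)
#' coef(fit)
#' summary(fit)
#' @export
oefcal <- function(data, roi_calibrate = "NAWM", target_max_oef = 0.6,
                   constants = oef_constants()) {
  .check_table(data, c("subject_id", "roi", "mtt_s", "cth_s"))
  has_pet <- "oef_pet" %in% names(data)
  if (has_pet) {
    cal <- calibrate_cohort(data, target_max_oef = target_max_oef,
                            constants = constants, roi = roi_calibrate)
    cst <- cal$constants
  } else {
    cal <- NULL
    cst <- constants
  }
  data$oef_mri <- oef(data$mtt_s, data$cth_s, cst)
  agreement <- list()
  if (has_pet) {
    for (r in unique(data$roi)) {
      d <- data[data$roi == r & is.finite(data$oef_pet), , drop = FALSE]
      if (nrow(d) >= 3L && stats::sd(d$oef_mri) > 0 && stats::sd(d$oef_pet) > 0)
        agreement[[r]] <- agreement_report(d$oef_mri, d$oef_pet)
    }
  }
  structure(list(calibration = cal,
                 constants = cst,
                 data = data,
                 agreement = agreement,
                 n_subjects = length(unique(data$subject_id)),
                 call = match.call()),
            class = "oefcal")
}

#' @export
print.oefcal <- function(x, ...) {
  cat("Capillary transit time OEF model fit\n")
  cat("Call: "); print(x$call)
  cat(sprintf("  %d subject(s), %d row(s), regions: %s\n", x$n_subjects,
              nrow(x$data), paste(unique(x$data$roi), collapse = ", ")))
  if (is.null(x$calibration)) {
    cat(sprintf("  Estimation-only mode: PtO2 = %.3f mmHg, k = %.1f 1/s (supplied)\n",
                x$constants$PtO2, x$constants$k))
  } else {
    cat(sprintf("  Calibrated PtO2 = %.3f mmHg, cohort k = %.1f 1/s (range [%.1f, %.1f])\n",
                x$constants$PtO2, x$constants$k,
                x$calibration$k_range[1], x$calibration$k_range[2]))
  }
  invisible(x)
}

#' @export
#' @rdname oefcal
#' @param object,x an `"oefcal"` fit.
#' @param ... unused.
summary.oefcal <- function(object, ...) {
  structure(list(fit = object), class = "summary.oefcal")
}

#' @export
print.summary.oefcal <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$calibration)) {
    cat("\n"); print(fit$calibration)
  }
  for (r in names(fit$agreement)) {
    a <- fit$agreement[[r]]
    cat(sprintf("\nAgreement (model - PET), %s: n = %d\n", r, a$n))
    cat(sprintf("  Pearson r = %.3f (p = %.3g)\n", a$r, a$p_value))
    cat(sprintf("  Bland-Altman bias = %.4f, limits [%.4f, %.4f]\n",
                a$bias, a$loa_low, a$loa_high))
  }
  by_roi <- split(fit$data, fit$data$roi)
  cat("\nOEF by region (mean [min; max]):\n")
  for (r in names(by_roi)) {
    d <- by_roi[[r]]
    cat(sprintf("  %-6s model %.3f [%.3f; %.3f]", r, mean(d$oef_mri),
                min(d$oef_mri), max(d$oef_mri)))
    if ("oef_pet" %in% names(d) && any(is.finite(d$oef_pet))) {
      p <- d$oef_pet[is.finite(d$oef_pet)]
      cat(sprintf("   PET %.3f [%.3f; %.3f]", mean(p), min(p), max(p)))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.oefcal <- function(object, ...) {
  c(PtO2_mmHg = object$constants$PtO2, k_per_s = object$constants$k)
}

#' @export
#' @rdname oefcal
#' @param newdata optional data frame with `mtt_s` and `cth_s` (and
#'   `subject_id` when `k = "subject"`); defaults to the fitting data.
#' @param k `"cohort"` predicts with the single cohort-mean rate constant;
#'   `"subject"` uses each subject's individually calibrated `k` (rows of
#'   subjects not in the calibration fall back to the cohort value).
predict.oefcal <- function(object, newdata = NULL, k = c("cohort", "subject"),
                           ...) {
  k <- match.arg(k)
  if (is.null(newdata)) newdata <- object$data
  .check_table(newdata, c("mtt_s", "cth_s"))
  if (k == "cohort") {
    return(oef(newdata$mtt_s, newdata$cth_s, object$constants))
  }
  if (is.null(object$calibration))
    stop("per-subject prediction requires a calibrated fit", call. = FALSE)
  .check_table(newdata, "subject_id")
  ktab <- object$calibration$k
  ks <- ktab$k[match(newdata$subject_id, ktab$subject_id)]
  ks[is.na(ks)] <- object$constants$k
  vapply(seq_len(nrow(newdata)), function(i) {
    cst <- object$constants
    cst$k <- ks[i]
    oef(newdata$mtt_s[i], newdata$cth_s[i], cst)
  }, numeric(1))
}

#' @export
fitted.oefcal <- function(object, ...) object$data$oef_mri

#' @export
residuals.oefcal <- function(object, ...) {
  if (!"oef_pet" %in% names(object$data))
    stop("no PET observations: residuals undefined in estimation-only mode",
         call. = FALSE)
  object$data$oef_mri - object$data$oef_pet
}

#' @export
#' @rdname oefcal
#' @param nsim number of simulated PET observation vectors.
#' @param seed optional seed, handled like [stats::simulate()] (the RNG state
#'   is restored afterwards when `seed` is given).
#' @param cv coefficient of variation of the multiplicative PET observation
#'   noise.
simulate.oefcal <- function(object, nsim = 1, seed = NULL, cv = 0.10, ...) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      stats::runif(1)
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  mu <- object$data$oef_mri
  ceiling_oef <- limit_extraction(object$constants$PtO2, object$constants)
  out <- as.data.frame(replicate(nsim, {
    pmin(pmax(mu * (1 + cv * stats::rnorm(length(mu))), 1e-9),
         ceiling_oef * (1 - 1e-9))
  }, simplify = TRUE))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
#' @rdname oefcal
#' @param roi region to plot; defaults to the first region with an agreement
#'   report.
plot.oefcal <- function(x, roi = NULL, ...) {
  if (length(x$agreement) == 0L)
    stop("nothing to plot: fit has no agreement reports", call. = FALSE)
  if (is.null(roi)) roi <- names(x$agreement)[1]
  a <- x$agreement[[roi]]
  if (is.null(a)) stop("no agreement report for roi '", roi, "'", call. = FALSE)
  d <- x$data[x$data$roi == roi & is.finite(x$data$oef_pet), , drop = FALSE]
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  lim <- range(c(d$oef_pet, d$oef_mri))
  plot(d$oef_pet, d$oef_mri, xlim = lim, ylim = lim,
       xlab = "PET OEF", ylab = "Model OEF",
       main = sprintf("%s: r = %.3f", roi, a$r), ...)
  graphics::abline(0, 1, lty = 3)
  m <- (d$oef_mri + d$oef_pet) / 2
  plot(m, d$oef_mri - d$oef_pet, xlab = "Mean OEF",
       ylab = "Model - PET OEF", main = sprintf("%s: Bland-Altman", roi), ...)
  graphics::abline(h = c(a$bias, a$loa_low, a$loa_high), lty = c(2, 3, 3))
  invisible(x)
}
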