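#' Synthetic cohort configuration
#'
#' Describes the statistical structure of a simulated study cohort: per-region
#' location and range of the transit-time statistics, the spread of the true
#' per-subject transfer rate constant, and the PET observation noise. The
#' defaults emulate a healthy elderly cohort: normal-appearing white matter
#' MTT 4.52 s \[3.14; 6.42\] and CTH 5.45 s \[3.82; 8.31\]; gray matter MTT
#' 3.40 s \[2.35; 4.60\] and CTH 4.08 s \[2.85; 6.07\]; per-subject `k`
#' centered at 68 1/s spanning 22--175; 10% multiplicative PET OEF noise.
#'
#' Each `c(mean, lo, hi)` triple is realized as a lognormal with the given
#' mean whose 2.5th/97.5th percentiles match `(lo, hi)`, truncated to
#' `[lo, hi]` by resampling. MTT and CTH are drawn jointly with Spearman rank
#' correlation `mtt_cth_rho` through a Gaussian copula (heterogeneity tracks
#' mean transit time across tissue).
#'
#' @param n_subjects cohort size.
#' @param cv coefficient of variation of the multiplicative PET OEF noise.
#' @param mtt_cth_rho Spearman correlation between MTT and CTH within region.
#' @param target_max_oef OEF ceiling defining the forward model's `PtO2`.
#' @param rois named list; each element a list with `mtt = c(mean, lo, hi)`
#'   and `cth = c(mean, lo, hi)` in seconds.
#' @param k_true `c(median, lo, hi)` of the lognormal per-subject transfer
#'   rate constant (1/s), truncated to `[lo, hi]`.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_subjects = 68L,
                          cv = 0.10,
                          mtt_cth_rho = 0.8,
                          target_max_oef = 0.6,
                          rois = list(
                            NAWM = list(mtt = c(4.52, 3.14, 6.42),
                                        cth = c(5.45, 3.82, 8.31)),
                            GM = list(mtt = c(3.40, 2.35, 4.60),
                                      cth = c(4.08, 2.85, 6.07))),
                          k_true = c(median = 68, lo = 22, hi = 175)) {
  if (!is.numeric(n_subjects) || length(n_subjects) != 1L || n_subjects < 0)
    stop("'n_subjects' must be a single number >= 0", call. = FALSE)
  if (cv < 0) stop("'cv' must be >= 0", call. = FALSE)
  if (abs(mtt_cth_rho) >= 1) stop("'mtt_cth_rho' must be in (-1, 1)", call. = FALSE)
  for (r in names(rois)) for (what in c("mtt", "cth")) {
    v <- rois[[r]][[what]]
    if (is.null(v) || length(v) != 3L || any(v <= 0) ||
        v[2] > v[1] || v[1] > v[3])
      stop("roi '", r, "' ", what,
           " must be c(mean, lo, hi) with 0 < lo <= mean <= hi", call. = FALSE)
  }
  if (length(k_true) != 3L || any(k_true <= 0) ||
      k_true[2] > k_true[1] || k_true[1] > k_true[3])
    stop("'k_true' must be c(median, lo, hi) with 0 < lo <= median <= hi",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), cv = cv,
                 mtt_cth_rho = mtt_cth_rho, target_max_oef = target_max_oef,
                 rois = rois, k_true = k_true),
            class = "cohort_config")
}

#' Generate a synthetic study cohort
#'
#' Draws a reproducible cohort of subjects with per-region transit-time
#' statistics, a hidden true transfer rate constant per subject, and noisy
#' PET OEF observations produced by the forward model
#' (`oef(mtt, cth; k_true, PtO2)` times multiplicative Gaussian noise, clipped
#' to the model's extraction ceiling; see [forward_pet()]).
#'
#' @param n_subjects number of subjects (overrides `config`).
#' @param seed integer RNG seed; the same seed reproduces the table exactly.
#' @param config a [cohort_config()].
#' @param constants an [oef_constants()] object supplying the Hill constants;
#'   the forward model's `PtO2` is set from `config$target_max_oef`.
#' @return Data frame with one row per subject x region: `subject_id`, `roi`,
#'   `mtt_s`, `cth_s`, `k_true` (hidden truth), `oef_model` (noiseless model
#'   OEF), `oef_pet` (noisy observation). `n_subjects = 0` yields an empty
#'   table with the full header.
#' @examples
#' coh <- generate_cohort(n_subjects = 8, seed = 1)
#' head(coh)
#' @export
generate_cohort <- function(n_subjects = NULL, seed = 1L,
                            config = cohort_config(),
                            constants = oef_constants()) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config()", call. = FALSE)
  n <- if (is.null(n_subjects)) config$n_subjects else as.integer(n_subjects)
  cols <- c("subject_id", "roi", "mtt_s", "cth_s", "k_true", "oef_model",
            "oef_pet")
  if (n == 0L) {
    out <- as.data.frame(setNames(
      list(character(), character(), numeric(), numeric(), numeric(),
           numeric(), numeric()), cols))
    return(out)
  }
  set.seed(seed)
  kp <- .lognormal_from_range(config$k_true[1], config$k_true[2],
                              config$k_true[3], location = "median")
  k_true <- .rtrunc_lognormal(n, kp$mu, kp$sigma,
                              config$k_true[2], config$k_true[3])
  ids <- sprintf("S%03d", seq_len(n))
  rows <- list()
  for (r in names(config$rois)) {
    mc <- .draw_mtt_cth(n, config$rois[[r]], config$mtt_cth_rho)
    rows[[r]] <- data.frame(subject_id = ids, roi = r,
                            mtt_s = mc[, 1], cth_s = mc[, 2],
                            k_true = k_true)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$subject_id, out$roi), ]
  rownames(out) <- NULL
  forward_pet(out, constants = constants, cv = config$cv,
              target_max_oef = config$target_max_oef)
}

#' Forward PET observations from the transit-time model
#'
#' Adds the model OEF (`oef_model`) and a noisy PET observation (`oef_pet`)
#' to a cohort table: each row's OEF is evaluated with its subject's true
#' `k_true` at the `PtO2` implied by `target_max_oef`, then multiplied by
#' `(1 + cv * z)` with standard normal `z`. Observations are clipped into
#' `(0, ceiling)` where `ceiling` is the model's infinite-`k` extraction
#' limit; the number of clipped values is reported as a message.
#'
#' Uses the current RNG stream; call `set.seed()` first (or use
#' [generate_cohort()], which seeds the whole draw) for reproducibility.
#'
#' @param cohort data frame with `mtt_s`, `cth_s`, `k_true`.
#' @param constants an [oef_constants()] object (Hill constants).
#' @param cv multiplicative noise coefficient of variation; `cv = 0`
#'   reproduces the model OEF exactly.
#' @param target_max_oef OEF ceiling fixing the forward model's `PtO2`.
#' @return The input with `oef_model` and `oef_pet` columns (re)computed.
#' @export
forward_pet <- function(cohort, constants = oef_constants(), cv = 0.10,
                        target_max_oef = 0.6) {
  .check_table(cohort, c("mtt_s", "cth_s", "k_true"))
  if (any(!is.finite(cohort$k_true)))
    stop("'k_true' must be present and finite for every row", call. = FALSE)
  cst <- constants
  cst$PtO2 <- calibrate_pto2(target_max_oef, constants)
  ceiling_oef <- limit_extraction(cst$PtO2, cst)
  cohort$oef_model <- .oef_many(cohort$mtt_s, cohort$cth_s, cst,
                                k = cohort$k_true)
  obs <- cohort$oef_model * (1 + cv * stats::rnorm(nrow(cohort)))
  clipped <- obs <= 0 | obs >= ceiling_oef
  if (any(clipped))
    message(sum(clipped), " PET OEF observation(s) clipped into (0, ",
            signif(ceiling_oef, 4), ")")
  cohort$oef_pet <- pmin(pmax(obs, 1e-9), ceiling_oef * (1 - 1e-9))
  cohort
}

# Lognormal (mu, sigma) whose 2.5/97.5 percentile band is [lo, hi] and whose
# mean (or median) is 'center'.
.lognormal_from_range <- function(center, lo, hi,
                                  location = c("mean", "median")) {
  location <- match.arg(location)
  sigma <- log(hi / lo) / (2 * stats::qnorm(0.975))
  mu <- if (location == "mean") log(center) - sigma^2 / 2 else log(center)
  list(mu = mu, sigma = sigma)
}

# Truncated lognormal by inverse-CDF sampling (exact truncation, one draw
# per value, keeps the RNG stream length deterministic). A degenerate band
# (lo == hi) collapses to a point mass.
.rtrunc_lognormal <- function(n, mu, sigma, lo, hi) {
  u <- stats::runif(n)
  if (sigma == 0 || hi <= lo) return(rep(exp(mu), n))
  plo <- stats::plnorm(lo, mu, sigma)
  phi <- stats::plnorm(hi, mu, sigma)
  stats::qlnorm(plo + u * (phi - plo), mu, sigma)
}

# Correlated (MTT, CTH) draw: Gaussian copula with normal-scale correlation
# matched to the requested Spearman rho, lognormal margins truncated to the
# configured ranges by inverse-CDF.
.draw_mtt_cth <- function(n, roi_spec, rho_s) {
  rho <- 2 * sin(pi * rho_s / 6)
  z <- MASS::mvrnorm(n, mu = c(0, 0),
                     Sigma = matrix(c(1, rho, rho, 1), 2))
  if (n == 1L) z <- matrix(z, nrow = 1L)
  pm <- .lognormal_from_range(roi_spec$mtt[1], roi_spec$mtt[2], roi_spec$mtt[3])
  pc <- .lognormal_from_range(roi_spec$cth[1], roi_spec$cth[2], roi_spec$cth[3])
  tq <- function(u, p, lo, hi) {
    plo <- stats::plnorm(lo, p$mu, p$sigma)
    phi <- stats::plnorm(hi, p$mu, p$sigma)
    stats::qlnorm(plo + u * (phi - plo), p$mu, p$sigma)
  }
  cbind(mtt = tq(stats::pnorm(z[, 1]), pm, roi_spec$mtt[2], roi_spec$mtt[3]),
        cth = tq(stats::pnorm(z[, 2]), pc, roi_spec$cth[2], roi_spec$cth[3]))
}
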