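#' PET frame schedule
#'
#' Frame binning of a dynamic PET acquisition as an ordered vector of frame
#' durations. The default is the 3-minute bolus protocol of 21 frames:
#' 12 x 5 s, 6 x 10 s, 3 x 20 s (total 180 s).
#'
#' @param durations positive frame durations in seconds, in acquisition order.
#' @return An object of class `"tac_schedule"`: data frame with columns
#'   `start`, `end`, `mid`, `dur` (s).
#' @export
tac_schedule <- function(durations = c(rep(5, 12), rep(10, 6), rep(20, 3))) {
  if (any(!is.finite(durations)) || any(durations <= 0))
    stop("frame durations must be finite and > 0", call. = FALSE)
  end <- cumsum(durations)
  start <- c(0, end[-length(end)])
  structure(data.frame(start = start, end = end, mid = (start + end) / 2,
                       dur = durations),
            class = c("tac_schedule", "data.frame"))
}

#' Gamma-variate arterial input function
#'
#' A bolus-shaped arterial input sampled on a fine uniform time grid:
#' zero before arrival `t0`, then `A ((t - t0)/tp)^a exp(a (1 - (t-t0)/tp))`,
#' which peaks with value `A` at `t0 + tp`.
#'
#' @param t_max end of the sampled window (s).
#' @param dt grid spacing (s).
#' @param t0 bolus arrival time (s).
#' @param tp time to peak after arrival (s).
#' @param shape gamma-variate shape exponent `a`.
#' @param amplitude peak value `A` (arbitrary activity units).
#' @return Data frame with columns `time` (s) and `activity`.
#' @export
gamma_aif <- function(t_max = 180, dt = 0.1, t0 = 10, tp = 12, shape = 3,
                      amplitude = 1) {
  t <- seq(0, t_max, by = dt)
  s <- pmax(t - t0, 0) / tp
  a <- amplitude * s^shape * exp(shape * (1 - s))
  data.frame(time = t, activity = a)
}

#' Simulate a one-tissue-compartment time--activity curve
#'
#' Tissue activity of the single-tissue-compartment model,
#' \deqn{C_T(t) = K_1 \int_0^t C_a(s)\, e^{-k_2 (t - s)}\, ds,}
#' computed on the input's uniform fine grid by an exact-exponential
#' trapezoidal recursion, then averaged over each acquisition frame.
#'
#' @param K1 unidirectional clearance (>= 0; units of the AIF activity are
#'   carried through).
#' @param k2 efflux rate constant (1/s, >= 0).
#' @param aif arterial input: data frame with columns `time` (uniform grid, s)
#'   and `activity` (>= 0), e.g. from [gamma_aif()]. The grid must cover the
#'   schedule.
#' @param schedule a [tac_schedule()].
#' @return Numeric vector of frame-averaged tissue activities, one per frame.
#' @export
simulate_tac <- function(K1, k2, aif, schedule = tac_schedule()) {
  .check_table(aif, c("time", "activity"))
  if (!is.numeric(K1) || length(K1) != 1L || !is.finite(K1) || K1 < 0)
    stop("'K1' must be a single number >= 0", call. = FALSE)
  if (!is.numeric(k2) || length(k2) != 1L || !is.finite(k2) || k2 < 0)
    stop("'k2' must be a single number >= 0", call. = FALSE)
  t <- aif$time
  a <- aif$activity
  if (any(a < 0)) stop("AIF activity must be >= 0", call. = FALSE)
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9))
    stop("AIF must be sampled on a uniform time grid", call. = FALSE)
  if (max(schedule$end) > max(t) + 1e-9)
    stop("frame schedule extends beyond the sampled AIF support", call. = FALSE)
  dt <- dt[1]
  # trapezoidal convolution with exp(-k2 t): y_i = e*y_{i-1} + dt/2*(a_i + e*a_{i-1})
  e <- exp(-k2 * dt)
  n <- length(a)
  y <- numeric(n)
  for (i in 2:n) y[i] <- e * y[i - 1] + dt / 2 * (a[i] + e * a[i - 1])
  tissue <- K1 * y
  vapply(seq_len(nrow(schedule)), function(j) {
    .frame_mean(t, tissue, schedule$start[j], schedule$end[j])
  }, numeric(1))
}

# Trapezoidal average of a sampled curve over [s, e], interpolating the ends.
.frame_mean <- function(t, v, s, e) {
  inner <- t[t > s & t < e]
  xs <- c(s, inner, e)
  ys <- stats::approx(t, v, xout = xs)$y
  sum(diff(xs) * (ys[-1] + ys[-length(ys)]) / 2) / (e - s)
}

#' Fit the one-tissue-compartment model to a time--activity curve
#'
#' Least-squares estimation of `(K1, k2)` from a frame-averaged tissue curve
#' and a sampled arterial input, minimizing the residual sum of squares over
#' frames with the Levenberg--Marquardt algorithm
#' ([minpack.lm::nls.lm()]) under nonnegativity bounds.
#'
#' @param tac frame-averaged tissue activity, one value per frame.
#' @param aif arterial input as in [simulate_tac()].
#' @param schedule a [tac_schedule()] congruent with `tac`.
#' @param start optional named starting values `c(K1 = , k2 = )`; a data-driven
#'   default is used otherwise.
#' @return An object of class `"tcm_fit"`: list with `K1`, `k2`, `converged`,
#'   `rss`, `niter`, `message`.
#' @export
fit_1tcm <- function(tac, aif, schedule = tac_schedule(), start = NULL) {
  if (length(tac) != nrow(schedule))
    stop("'tac' length must equal the number of frames", call. = FALSE)
  if (any(!is.finite(tac)))
    stop("'tac' must be finite", call. = FALSE)
  if (all(tac == 0))
    return(structure(list(K1 = 0, k2 = 0, converged = TRUE, rss = 0,
                          niter = 0L, message = "all-zero input"),
                     class = "tcm_fit"))
  if (is.null(start)) {
    # scale K1 from the late-frame ratio of tissue to integrated input
    cum <- simulate_tac(1, 0, aif, schedule)
    start <- c(K1 = max(tac[length(tac)] / cum[length(cum)], 1e-6), k2 = 0.005)
  }
  resid_fn <- function(p) simulate_tac(p[1], p[2], aif, schedule) - tac
  fit <- minpack.lm::nls.lm(par = unname(start), lower = c(0, 0),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(
                              ftol = 1e-12, ptol = 1e-12, maxiter = 200))
  converged <- fit$info %in% 1:4
  if (!converged)
    warning("1TCM fit did not converge: ", fit$message)
  structure(list(K1 = fit$par[1], k2 = fit$par[2], converged = converged,
                 rss = fit$deviance, niter = fit$niter,
                 message = fit$message),
            class = "tcm_fit")
}

#' @export
print.tcm_fit <- function(x, ...) {
  cat(sprintf("1TCM fit: K1 = %.5g, k2 = %.5g 1/s (%s, rss = %.3g, %d iter)\n",
              x$K1, x$k2,
              if (x$converged) "converged" else "NOT converged",
              x$rss, x$niter))
  invisible(x)
}
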