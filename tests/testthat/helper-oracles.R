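# Independent numerical oracles used across the suite. These deliberately
# avoid the package's solver path (deSolve / Gauss-Legendre): the capillary
# oracle is a hand-rolled fixed-step classical Runge-Kutta integration of the
# transport equation in the normalized distance x, and the OEF oracle is a
# midpoint Riemann sum over the transit-time density.

# Hill saturation written out directly (not via the package).
oracle_hill <- function(P, cst) {
  r <- (P / cst$P50)^cst$h
  r / (1 + r)
}

# Fixed-step 4th-order Runge-Kutta solution of
#   dC/dx = -k*tau * alpha_H * (P50 (C/(B-C))^(1/h) - PtO2),  C(0) = S_a B,
# returning Q = 1 - C(1)/C(0). Step count defaults to a stability-safe,
# accuracy-generous choice for the stiffness at hand (the equilibrium decay
# scale is ~190 in s = k*tau*x units).
oracle_rk4_Q <- function(tau, k, cst, n = NULL) {
  u <- k * tau
  if (u == 0) return(0)
  if (is.null(n)) n <- max(10000L, ceiling(2 * u))
  B <- cst$B; aH <- cst$alpha_H; P50 <- cst$P50
  invh <- 1 / cst$h; Pt <- cst$PtO2
  Ceq <- B * oracle_hill(Pt, cst)
  Cmax <- B * (1 - 1e-12)
  C0 <- cst$S_a * B
  h <- 1 / n
  C <- C0
  for (i in seq_len(n)) {
    x <- C; if (x < Ceq) x <- Ceq else if (x > Cmax) x <- Cmax
    k1 <- -u * aH * (P50 * (x / (B - x))^invh - Pt)
    x <- C + h / 2 * k1; if (x < Ceq) x <- Ceq else if (x > Cmax) x <- Cmax
    k2 <- -u * aH * (P50 * (x / (B - x))^invh - Pt)
    x <- C + h / 2 * k2; if (x < Ceq) x <- Ceq else if (x > Cmax) x <- Cmax
    k3 <- -u * aH * (P50 * (x / (B - x))^invh - Pt)
    x <- C + h * k3; if (x < Ceq) x <- Ceq else if (x > Cmax) x <- Cmax
    k4 <- -u * aH * (P50 * (x / (B - x))^invh - Pt)
    C <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    if (C < Ceq) C <- Ceq
  }
  1 - C / C0
}

# Brute-force midpoint Riemann sum for the OEF integral, truncated at the
# p-quantile of the gamma transit-time distribution. Single-capillary
# extraction is taken from the package (it is validated independently against
# oracle_rk4_Q); this oracle targets the quadrature scheme.
oracle_riemann_oef <- function(mtt, cth, cst, n = 1e5, p = 1 - 1e-7) {
  alpha <- (mtt / cth)^2
  beta <- cth^2 / mtt
  q <- qgamma(p, shape = alpha, scale = beta)
  tau <- (seq_len(n) - 0.5) * q / n
  Q <- single_capillary_extraction(tau, cst)
  sum(dgamma(tau, shape = alpha, scale = beta) * Q) * q / n
}

# Default constants with the calibrated operating point used throughout the
# suite (ceiling 0.6 -> PtO2 ~21.8 mmHg; cohort rate constant 68 1/s).
cst_calibrated <- function(k = 68) {
  oef_constants(PtO2 = calibrate_pto2(0.6), k = k)
}
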