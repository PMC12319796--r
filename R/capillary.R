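#' Oxygen extraction of a single capillary
#'
#' Solves the transport equation for the bound-oxygen concentration along a
#' capillary of transit time `tau`,
#' \deqn{\frac{dC}{dx} = -k\tau\,\alpha_H\!\left(P_{50}\Big(\frac{C}{B-C}\Big)^{1/h} - P_tO_2\right),
#'   \quad x \in [0,1],\ C(0) = S_a B,}
#' and returns the extraction fraction \eqn{Q = 1 - C(1)/C(0)}.
#'
#' `Q` depends on `k` and `tau` only through the product `u = k tau`
#' (substituting `s = k tau x` makes the equation autonomous), so all requested
#' transit times are obtained from a single integration of the autonomous
#' equation, evaluated at every `u`. The equation becomes stiff as `u` grows;
#' `deSolve::lsoda` switches to a stiff integrator automatically, and for
#' `u > 1e5` the solution is within 1e-8 of the tissue equilibrium and is
#' clamped there analytically.
#'
#' @param tau capillary transit time(s) in seconds (>= 0); vectorized.
#' @param constants an [oef_constants()] object; `k` and `PtO2` are taken from
#'   it.
#' @return Extraction fraction(s) `Q` in `[0, limit_extraction(PtO2))`.
#' @seealso [oef()] for the transit-time-distribution average,
#'   [limit_extraction()] for the infinite-`k` ceiling.
#' @examples
#' cst <- oef_constants(PtO2 = 21.8, k = 68)
#' single_capillary_extraction(c(1, 4.52, 30), cst)
#' @export
single_capillary_extraction <- function(tau, constants = oef_constants()) {
  if (any(!is.finite(tau)) || any(tau < 0))
    stop("'tau' must be finite and >= 0", call. = FALSE)
  .check_gradient(constants)
  .Q_of_u(constants$k * tau, constants)
}

# Extraction as a function of u = k * tau. One lsoda call serves every u.
# u beyond .u_clamp is treated as fully equilibrated.
.u_clamp <- 1e5

.Q_of_u <- function(u, constants) {
  C0 <- .c_in(constants)
  Ceq <- .c_eq(constants)
  Q <- numeric(length(u))
  big <- u > .u_clamp
  Q[big] <- 1 - Ceq / C0
  us <- u[!big]
  if (length(us)) {
    uo <- sort(unique(c(0, us)))
    Cv <- .solve_capillary(uo, constants, C0, Ceq)
    Q[!big] <- 1 - Cv[match(us, uo)] / C0
  }
  Q
}

.solve_capillary <- function(uo, constants, C0, Ceq) {
  if (length(uo) == 1L) return(C0)
  B <- constants$B
  P50 <- constants$P50
  aH <- constants$alpha_H
  invh <- 1 / constants$h
  PtO2 <- constants$PtO2
  Cmax <- B * (1 - 1e-12)
  deriv <- function(s, y, parms) {
    # exact solution never leaves [Ceq, C0]; clamp guards roundoff excursions
    C <- min(max(y[1L], Ceq), Cmax)
    list(-aH * (P50 * (C / (B - C))^invh - PtO2))
  }
  sol <- deSolve::lsoda(c(C = C0), times = uo, func = deriv,
                        rtol = 1e-9, atol = 1e-12)
  pmin(pmax(sol[, "C"], Ceq), C0)
}
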