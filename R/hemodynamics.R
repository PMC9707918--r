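# Steady 0-D pressure-flow model of a stenosed vessel coupled to a
# microvascular outlet resistance. One unknown (flow q); the epicardial
# drop is R_v q + S q^2 and the microvascular bed takes pd = q * cmvr.

# Stable positive root of S q^2 + b q - p = 0 (b > 0, p >= 0). Written to
# avoid subtractive cancellation so the S -> 0 limit is exact: q = p / b.
.positive_root <- function(S, b, p) {
  2 * p / (b + sqrt(b^2 + 4 * S * p))
}

#' Forward vFFR solve for one vessel
#'
#' Solves the steady pressure-flow balance
#' `pa - (R_v q + S q^2) = q * cmvr` for the unique non-negative flow `q`,
#' where `R_v` and `S` are the vessel's lumped loss coefficients (see
#' [vessel_resistance()]) and `cmvr` is the distal microvascular
#' resistance applied as the outlet boundary condition. Distal pressure is
#' `pd = q * cmvr` and the virtual FFR is `pd / pa`.
#'
#' The root is computed in closed form, in a numerically stable
#' rationalised form so that the lossless (`S = 0`) limit reduces exactly
#' to the linear voltage-divider solution `q = pa / (R_v + cmvr)`.
#'
#' @param geometry a [vessel_geometry()].
#' @param fluid a [fluid_properties()].
#' @param pa aortic (inlet) pressure in Pa; must be > 0.
#' @param cmvr microvascular resistance in Pa s/m^3; must be > 0.
#' @return an object of class `hemodynamic_state`: a list with `pa`, `pd`
#'   (Pa), `q` (m^3/s), `ffr`, and `cmvr`.
#' @examples
#' g <- vessel_geometry(c(1.5, 0.7, 1.4), c(20, 12, 40),
#'                      stenosis_spec(1.4, 2.9))
#' solve_forward(g, pa = mmHg_to_Pa(90), cmvr = 1e10)
#' @export
solve_forward <- function(geometry, fluid = fluid_properties(), pa, cmvr) {
  stopifnot(is.finite(pa), is.finite(cmvr))
  if (pa <= 0) stop("aortic pressure must be > 0")
  if (cmvr <= 0) stop("cmvr must be > 0")
  rs <- vessel_resistance(geometry, fluid)
  q <- .positive_root(rs$S, rs$R_v + cmvr, pa)
  pd <- q * cmvr
  residual <- pa - rs$R_v * q - rs$S * q^2 - pd
  stopifnot(abs(residual) <= 1e-9 * pa)
  structure(list(pa = pa, pd = pd, q = q, ffr = pd / pa, cmvr = cmvr),
            class = "hemodynamic_state")
}

#' @export
print.hemodynamic_state <- function(x, ...) {
  cat(sprintf("Pa %.1f mmHg | Pd %.1f mmHg | FFR %.3f | Q %.1f mL/min | CMVR %.3g Pa s/m3\n",
              Pa_to_mmHg(x$pa), Pa_to_mmHg(x$pd), x$ffr, x$q * 6e7, x$cmvr))
  invisible(x)
}

#' Invert measured pressures to a vessel-specific CMVR
#'
#' The hydraulic analogue of Ohm's law: given measured aortic and distal
#' pressures, the epicardial pressure drop `pa - pd` fixes the flow
#' through the vessel (`R_v q + S q^2 = pa - pd`, unique positive root),
#' and the microvascular resistance follows as `cmvr = pd / q`. This is
#' the personalised-CMVR computation: each instrumented vessel yields its
#' own distal boundary value.
#'
#' @inheritParams solve_forward
#' @param pd distal pressure in Pa; requires `0 < pd < pa`.
#' @return list with `cmvr` (Pa s/m^3) and `q` (m^3/s).
#' @examples
#' g <- vessel_geometry(c(1.5, 0.7, 1.4), c(20, 12, 40),
#'                      stenosis_spec(1.4, 2.9))
#' st <- solve_forward(g, pa = 12000, cmvr = 8e9)
#' invert_cmvr(g, pa = st$pa, pd = st$pd)$cmvr   # recovers 8e9
#' @export
invert_cmvr <- function(geometry, fluid = fluid_properties(), pa, pd) {
  stopifnot(is.finite(pa), is.finite(pd))
  if (pd <= 0)
    stop("invalid measurement: distal pressure must be > 0 (got ", pd, " Pa)")
  if (pd >= pa)
    stop("cannot invert CMVR: distal pressure (", pd,
         " Pa) is not below aortic pressure (", pa,
         " Pa), implying no positive flow")
  rs <- vessel_resistance(geometry, fluid)
  if (rs$R_v <= 0 && rs$S <= 0)
    stop("vessel has zero resistance; flow is unidentifiable from pressures")
  q <- .positive_root(rs$S, rs$R_v, pa - pd)
  list(cmvr = pd / q, q = q)
}
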