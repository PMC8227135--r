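# Lipid-shelled microbubble linear resonance and the mechanical index.

#' Microbubble parameters
#'
#' Parameters of the linearized shelled-bubble oscillator: initial radius,
#' surrounding liquid density, polytropic gas constant, hydrostatic pressure,
#' interfacial tension and the lipid shell's elasticity modulus. Defaults
#' describe a perfluorocarbon-gas, lipid-shelled contrast agent in water;
#' with `sigma = chi = 0` the model reduces to the classical unshelled
#' (Minnaert) bubble.
#'
#' @param R0 Initial bubble radius in m (> 0).
#' @param rho Liquid density, kg/m^3.
#' @param gamma Polytropic gas constant (>= 1).
#' @param P0 Hydrostatic pressure, Pa.
#' @param sigma Interfacial tension, N/m (>= 0).
#' @param chi Shell elasticity modulus, N/m (>= 0).
#' @return An object of class `bubble_parameters`.
#' @examples
#' resonance_frequency(bubble_parameters(R0 = 3e-6))
#' @export
bubble_parameters <- function(R0, rho = 1000, gamma = 1.07, P0 = 101325,
                              sigma = 0.072, chi = 0.55) {
  stopifnot(is.numeric(R0), length(R0) == 1L)
  if (R0 <= 0) stop("R0 must be > 0", call. = FALSE)
  if (rho <= 0) stop("rho must be > 0", call. = FALSE)
  if (gamma < 1) stop("gamma must be >= 1", call. = FALSE)
  if (P0 <= 0) stop("P0 must be > 0", call. = FALSE)
  if (sigma < 0 || chi < 0) stop("sigma and chi must be >= 0", call. = FALSE)
  structure(list(R0 = R0, rho = rho, gamma = gamma, P0 = P0,
                 sigma = sigma, chi = chi),
            class = "bubble_parameters")
}

resonance_bracket <- function(p) {
  3 * p$gamma * (p$P0 + 2 * p$sigma / p$R0 + 2 * p$chi / p$R0) -
    2 * p$sigma / p$R0 - 6 * p$chi / p$R0
}

#' Linear resonance frequency of a shelled microbubble
#'
#' \deqn{\omega_0^2 = \frac{1}{\rho R_0^2}\left[3\gamma\left(P_0 +
#' \frac{2\sigma}{R_0} + \frac{2\chi}{R_0}\right) - \frac{2\sigma}{R_0} -
#' \frac{6\chi}{R_0}\right]}
#'
#' Shell stiffening (`chi > 0`) raises the resonance above the unshelled
#' value; `sigma = chi = 0` recovers the Minnaert resonance
#' `f0 = sqrt(3 gamma P0 / rho) / (2 pi R0)`.
#'
#' @param params A [bubble_parameters()].
#' @return Resonance frequency `f0 = omega0/(2 pi)` in Hz.
#' @export
resonance_frequency <- function(params) {
  stopifnot(inherits(params, "bubble_parameters"))
  br <- resonance_bracket(params)
  if (br <= 0) stop("no real resonance: bracketed term is not positive", call. = FALSE)
  sqrt(br / (params$rho * params$R0^2)) / (2 * pi)
}

#' Bubble radius resonant at a given frequency
#'
#' Numerically inverts [resonance_frequency()] by root bracketing on
#' `R0` in `[10 nm, 100 um]`.
#'
#' @param f Target resonance frequency, Hz (> 0).
#' @param params A [bubble_parameters()] whose `R0` is ignored.
#' @param interval Search bracket for `R0`, m.
#' @param tol Relative tolerance on the root.
#' @return The resonant radius in m.
#' @export
resonant_radius <- function(f, params = bubble_parameters(R0 = 1e-6),
                            interval = c(10e-9, 100e-6), tol = 1e-6) {
  stopifnot(is.numeric(f), length(f) == 1L, f > 0)
  g <- function(R) {
    p <- params
    p$R0 <- R
    resonance_frequency(p) - f
  }
  vals <- vapply(interval, g, numeric(1))
  if (prod(sign(vals)) > 0) {
    stop("no resonant radius in [", interval[1], ", ", interval[2],
         "] m for f = ", f, " Hz", call. = FALSE)
  }
  stats::uniroot(g, interval = interval, tol = tol * min(interval))$root
}

#' Mechanical index
#'
#' `MI = PNP / sqrt(f)` with the peak negative pressure in kPa and the
#' frequency in Hz; numerically identical to the conventional
#' MPa-per-root-MHz definition.
#'
#' @param pnp_kpa Peak negative pressure in kPa (>= 0); vectorized.
#' @param f_hz Frequency in Hz (> 0).
#' @return The dimensionless mechanical index.
#' @examples
#' mechanical_index(380, 1e6) # 0.38
#' @export
mechanical_index <- function(pnp_kpa, f_hz) {
  if (any(pnp_kpa < 0)) stop("pnp_kpa must be >= 0", call. = FALSE)
  if (any(f_hz <= 0)) stop("f_hz must be > 0", call. = FALSE)
  pnp_kpa / sqrt(f_hz)
}
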