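# Single-interface plane-wave coefficients: normal and oblique incidence,
# Snell refraction, critical and intromission angles.
#
# Public contract uses degrees (the chamber design quotes 26.5 degrees);
# radians internally.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Normal-incidence intensity transmission and reflection
#'
#' For two media of specific impedances `r1` and `r2`,
#' \eqn{T_i = 4 r_1 r_2 / (r_1 + r_2)^2} and
#' \eqn{R_i = (r_1 - r_2)^2 / (r_1 + r_2)^2}, with \eqn{T_i + R_i = 1}.
#' Matched impedances give total transmission.
#'
#' @param r1,r2 Specific acoustic impedances (Pa s/m, > 0); vectorized.
#' @return A tibble with columns `Ti` and `Ri`.
#' @examples
#' normal_coeffs(1.48e6, 1.48e6) # matched: Ti = 1
#' normal_coeffs(1.48e6, 413)    # water/air: almost total reflection
#' @export
normal_coeffs <- function(r1, r2) {
  if (any(r1 <= 0) || any(r2 <= 0)) {
    stop("impedances must be > 0", call. = FALSE)
  }
  Ti <- 4 * r1 * r2 / (r1 + r2)^2
  tibble::tibble(Ti = Ti, Ri = (r1 - r2)^2 / (r1 + r2)^2)
}

#' Snell refraction of a plane wave
#'
#' Solves `sin(theta_t) = (c2/c1) sin(theta_i)`. Beyond the critical angle
#' the refracted wave is evanescent and `NA` is returned.
#'
#' @param theta_i Incidence angle(s) from the normal, degrees in `[0, 90)`.
#' @param c1,c2 Sound speeds (m/s) in the incident and transmitting media.
#' @return Refraction angle(s) in degrees, `NA` where evanescent.
#' @export
refract <- function(theta_i, c1, c2) {
  if (any(theta_i < 0 | theta_i >= 90)) {
    stop("theta_i must be in [0, 90) degrees", call. = FALSE)
  }
  s <- (c2 / c1) * sin(deg2rad(theta_i))
  out <- rep(NA_real_, length(s))
  ok <- s <= 1
  out[ok] <- rad2deg(asin(s[ok]))
  out
}

#' Critical angles of a fluid/solid interface
#'
#' A branch has a critical angle `asin(c_fluid/c_branch)` only when the
#' solid-side speed exceeds the fluid speed; solids generally show a second,
#' larger critical angle for the slower shear branch.
#'
#' @param fluid,solid [acoustic_medium()] objects; `fluid` is the incident
#'   side.
#' @return A one-row tibble with `theta_c_long` and `theta_c_shear`
#'   (degrees, `NA` when no total-reflection branch exists).
#' @examples
#' mats <- sono_materials()
#' critical_angles(material(mats, "water"), material(mats, "glass"))
#' @export
critical_angles <- function(fluid, solid) {
  stopifnot(inherits(fluid, "acoustic_medium"), inherits(solid, "acoustic_medium"))
  cf <- fluid$c_long
  ang <- function(cs) if (cs > cf) rad2deg(asin(cf / cs)) else NA_real_
  tibble::tibble(
    theta_c_long = ang(solid$c_long),
    theta_c_shear = if (solid$c_shear > 0) ang(solid$c_shear) else NA_real_
  )
}

#' Oblique-incidence power transmission (longitudinal branch)
#'
#' Power transmission across a single interface,
#' \eqn{T_\pi = 4 (r_2/r_1)(\cos\theta_t/\cos\theta_i) /
#' (r_2/r_1 + \cos\theta_t/\cos\theta_i)^2}, with the refraction angle from
#' Snell's law. Both media are fluid-modelled (longitudinal branch only).
#' At and beyond the critical angle the refracted longitudinal wave is
#' evanescent and the transmitted power is reported as 0.
#'
#' @param theta_i Incidence angle(s), degrees in `[0, 90)`; vectorized.
#' @param medium1,medium2 [acoustic_medium()] objects.
#' @return Power transmission coefficient(s) in `[0, 1]`.
#' @export
oblique_power_transmission <- function(theta_i, medium1, medium2) {
  stopifnot(inherits(medium1, "acoustic_medium"), inherits(medium2, "acoustic_medium"))
  if (any(theta_i < 0 | theta_i >= 90)) {
    stop("theta_i must be in [0, 90) degrees", call. = FALSE)
  }
  theta_t <- refract(theta_i, medium1$c_long, medium2$c_long)
  ratio_r <- impedance(medium2) / impedance(medium1)
  out <- numeric(length(theta_i))
  ok <- !is.na(theta_t) & cos(deg2rad(theta_t)) > 0
  m <- ratio_r
  g <- cos(deg2rad(theta_t[ok])) / cos(deg2rad(theta_i[ok]))
  out[ok] <- 4 * m * g / (m + g)^2
  out
}

#' Intromission angle of a fluid pair
#'
#' The angle at which oblique transmission is total (the interface
#' impedances `r/cos(theta)` match on both sides). Solving
#' \eqn{T_\pi = 1} in closed form gives
#' \eqn{\sin^2\theta = (m - 1)/(m - n)} with \eqn{m = (r_2/r_1)^2} and
#' \eqn{n = (c_2/c_1)^2}; a real angle exists only for particular
#' impedance/speed combinations (e.g. water against a soft, slightly fast
#' polyurethane such as adiprene).
#'
#' @param medium1,medium2 [acoustic_medium()] objects (fluid-modelled pair).
#' @return The intromission angle in degrees, `0` for identical media
#'   (total transmission at every angle), or `NA` when none exists.
#' @examples
#' mats <- sono_materials()
#' intromission_angle(material(mats, "water"), material(mats, "adiprene"))
#' intromission_angle(material(mats, "water"), material(mats, "polystyrene"))
#' @export
intromission_angle <- function(medium1, medium2) {
  stopifnot(inherits(medium1, "acoustic_medium"), inherits(medium2, "acoustic_medium"))
  m <- (impedance(medium2) / impedance(medium1))^2
  n <- (medium2$c_long / medium1$c_long)^2
  if (abs(m - 1) < 1e-12 && abs(n - 1) < 1e-12) return(0)
  if (abs(m - n) < 1e-15) return(NA_real_)
  s2 <- (m - 1) / (m - n)
  if (is.na(s2) || s2 <= 0 || s2 >= 1) return(NA_real_)
  rad2deg(asin(sqrt(s2)))
}

#' Angle-resolved transmission curve for an interface
#'
#' Convenience sweep of [oblique_power_transmission()] over incidence
#' angles, suitable for plotting (see [plot_transmission_curve()]).
#'
#' @param medium1,medium2 [acoustic_medium()] objects.
#' @param theta Incidence angles in degrees (default a dense `[0, 90)` grid).
#' @return A tibble with `theta_i`, `theta_t` and `T_pi`, carrying the
#'   critical and intromission angles as attributes.
#' @export
transmission_curve <- function(medium1, medium2,
                               theta = seq(0, 89.9, by = 0.1)) {
  out <- tibble::tibble(
    theta_i = theta,
    theta_t = refract(theta, medium1$c_long, medium2$c_long),
    T_pi = oblique_power_transmission(theta, medium1, medium2)
  )
  attr(out, "pair") <- paste(medium1$name, medium2$name, sep = "/")
  attr(out, "theta_c") <- if (medium2$c_long > medium1$c_long)
    rad2deg(asin(medium1$c_long / medium2$c_long)) else NA_real_
  attr(out, "theta_intromission") <- intromission_angle(medium1, medium2)
  class(out) <- c("transmission_curve", class(out))
  out
}

#' Plot an angle-resolved transmission curve
#'
#' @param medium1,medium2 [acoustic_medium()] objects.
#' @param theta Incidence angles in degrees.
#' @return A ggplot showing transmitted power versus incidence angle, with
#'   the critical angle (dashed) and intromission angle (dotted) marked.
#' @export
plot_transmission_curve <- function(medium1, medium2,
                                    theta = seq(0, 89.9, by = 0.1)) {
  curve <- transmission_curve(medium1, medium2, theta)
  autoplot.transmission_curve(curve)
}

#' @rdname plot_transmission_curve
#' @param object A `transmission_curve` tibble.
#' @param ... Ignored.
#' @exportS3Method ggplot2::autoplot
autoplot.transmission_curve <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$theta_i, y = .data$T_pi)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "incidence angle (deg)", y = "power transmission",
      title = paste0("Oblique transmission: ", attr(object, "pair"))
    )
  tc <- attr(object, "theta_c")
  ti <- attr(object, "theta_intromission")
  if (!is.na(tc)) p <- p + ggplot2::geom_vline(xintercept = tc, linetype = "dashed")
  if (!is.na(ti) && ti > 0) p <- p + ggplot2::geom_vline(xintercept = ti, linetype = "dotted")
  p
}
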