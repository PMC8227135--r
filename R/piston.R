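# Semi-analytic free-field models for flat and focused circular piston
# transducers: closed-form on-axis pressure, Rayleigh-integral field maps,
# and focal metrics (distance, -6 dB length/width, iso-pressure surface
# areas).

#' Define a piston transducer
#'
#' @param geometry `"flat"` or `"focused"`.
#' @param a Active element radius in m (> 0).
#' @param f Drive frequency in Hz (> 0).
#' @param medium Propagation medium, an [acoustic_medium()] (default water
#'   from the shipped table).
#' @param p0 Source pressure amplitude `rho c v0` in Pa.
#' @param curvature_radius Radius of curvature in m (focused only; this is
#'   approximately the geometric focal distance).
#' @return An object of class `transducer_spec`.
#' @examples
#' spec <- transducer_spec("flat", a = 9.43e-3, f = 1e6)
#' last_axial_maximum(spec) # ~0.06 m
#' @export
transducer_spec <- function(geometry = c("flat", "focused"), a, f,
                            medium = NULL, p0 = 1,
                            curvature_radius = NULL) {
  geometry <- match.arg(geometry)
  if (is.null(medium)) medium <- material(sono_materials(), "water")
  stopifnot(inherits(medium, "acoustic_medium"))
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("a must be > 0", call. = FALSE)
  if (!is.numeric(f) || length(f) != 1L || f <= 0) stop("f must be > 0", call. = FALSE)
  if (geometry == "focused") {
    if (is.null(curvature_radius) || curvature_radius <= 0) {
      stop("focused geometry requires curvature_radius > 0", call. = FALSE)
    }
  }
  structure(
    list(geometry = geometry, a = a, f = f, medium = medium, p0 = p0,
         curvature_radius = curvature_radius),
    class = "transducer_spec"
  )
}

#' @export
print.transducer_spec <- function(x, ...) {
  cat(sprintf("<transducer_spec> %s piston: a = %g mm, f = %g MHz in %s\n",
              x$geometry, x$a * 1e3, x$f / 1e6, x$medium$name))
  if (x$geometry == "focused") {
    cat(sprintf("  curvature radius %g mm\n", x$curvature_radius * 1e3))
  }
  invisible(x)
}

wavelength <- function(spec) spec$medium$c_long / spec$f

#' On-axis pressure of a flat baffled piston
#'
#' Closed form
#' \eqn{|p(z)| = 2 p_0 |\sin((k/2)(\sqrt{z^2+a^2} - z))|}. The near field
#' oscillates between nulls and maxima of `2 p0`; beyond the last null the
#' field rises to the last maximum (the focal spot, near `a^2/lambda`) and
#' then decays as `1/z`.
#'
#' @param spec A flat [transducer_spec()].
#' @param z Axial distance(s) in m (> 0); vectorized.
#' @return `|p|` in Pa.
#' @export
on_axis_flat <- function(spec, z) {
  stopifnot(inherits(spec, "transducer_spec"))
  if (spec$geometry != "flat") stop("spec must be a flat piston", call. = FALSE)
  if (any(z <= 0)) stop("z must be > 0", call. = FALSE)
  k <- 2 * pi * spec$f / spec$medium$c_long
  2 * spec$p0 * abs(sin((k / 2) * (sqrt(z^2 + spec$a^2) - z)))
}

#' Focal distance of a flat piston (last on-axis maximum)
#'
#' Scans the closed-form on-axis field on a dense grid (1 um by default) and
#' refines the position of the last local maximum, which sits approximately
#' at `a^2/lambda - lambda/4`.
#'
#' @param spec A flat [transducer_spec()].
#' @param z_min,z_max Scan range in m (default 1 mm to the larger of 200 mm
#'   and twice `a^2/lambda`).
#' @param step Grid step in m.
#' @return The focal distance in m.
#' @export
last_axial_maximum <- function(spec, z_min = 1e-3, z_max = NULL, step = 1e-6) {
  stopifnot(inherits(spec, "transducer_spec"))
  if (spec$geometry != "flat") stop("spec must be a flat piston", call. = FALSE)
  lambda <- wavelength(spec)
  nf <- spec$a^2 / lambda
  if (is.null(z_max)) z_max <- max(0.2, 2 * nf)
  z <- seq(z_min, z_max, by = step)
  p <- on_axis_flat(spec, z)
  # last local maximum of the scan
  dp <- diff(p)
  turn <- which(dp[-1] < 0 & dp[-length(dp)] >= 0) + 1L
  if (length(turn) == 0) return(z[which.max(p)])
  i <- turn[length(turn)]
  obj <- function(zz) -on_axis_flat(spec, zz)
  stats::optimize(obj, lower = z[max(i - 2, 1)], upper = z[min(i + 2, length(z))],
                  tol = 1e-10)$minimum
}

#' On-axis pressure of a spherically focused piston
#'
#' O'Neil's spherical-cap model:
#' \eqn{|p(z)| = \frac{2 p_0}{|1 - z/R|}\left|\sin\left(\frac{k}{2}(r_e - z)\right)\right|}
#' with `r_e` the distance to the cap edge and `R` the curvature radius; at
#' `z = R` the analytic limit `p0 k h` is used (`h` the cap depth). The peak
#' lies slightly before the curvature centre.
#'
#' @param spec A focused [transducer_spec()].
#' @param z Axial distance(s) in m (> 0); vectorized.
#' @return `|p|` in Pa.
#' @export
on_axis_focused <- function(spec, z) {
  stopifnot(inherits(spec, "transducer_spec"))
  if (spec$geometry != "focused") stop("spec must be a focused piston", call. = FALSE)
  if (any(z <= 0)) stop("z must be > 0", call. = FALSE)
  R <- spec$curvature_radius
  a <- spec$a
  if (a >= R) stop("element radius must be smaller than curvature radius", call. = FALSE)
  k <- 2 * pi * spec$f / spec$medium$c_long
  h <- R - sqrt(R^2 - a^2)
  re <- sqrt(a^2 + (z - h)^2)
  out <- 2 * spec$p0 * abs(sin((k / 2) * (re - z))) / abs(1 - z / R)
  at_focus <- abs(1 - z / R) < 1e-9
  out[at_focus] <- spec$p0 * k * h
  out
}

#' Rayleigh-integral field map
#'
#' Numerically evaluates the Rayleigh surface integral over the piston face
#' on an axisymmetric `(r, z)` grid,
#' \eqn{p(r,z) = \frac{i k p_0}{2\pi}\int_S \frac{e^{-ikR'}}{R'}\,dS}.
#' For a focused spec the source carries the conjugate-spherical lens phase
#' `exp(+ik(sqrt(sigma^2 + R^2) - R))`, which brings all contributions into
#' phase at the geometric focus. The flat on-axis column reproduces
#' [on_axis_flat()] (the integral is then available in closed form).
#'
#' @param spec A [transducer_spec()].
#' @param r_grid Radial grid in m (>= 0, strictly increasing).
#' @param z_grid Axial grid in m (> 0, strictly increasing).
#' @param n_sigma,n_phi Gauss-Legendre node counts over the piston radius
#'   and azimuth.
#' @return A tibble of class `field_map` with columns `r`, `z` (m) and `p`
#'   (Pa), axisymmetric by construction.
#' @export
rayleigh_field_map <- function(spec, r_grid, z_grid, n_sigma = 96, n_phi = 96) {
  stopifnot(inherits(spec, "transducer_spec"))
  if (any(diff(r_grid) <= 0) || any(diff(z_grid) <= 0)) {
    stop("grids must be strictly increasing", call. = FALSE)
  }
  if (any(r_grid < 0) || any(z_grid <= 0)) {
    stop("r_grid must be >= 0 and z_grid > 0", call. = FALSE)
  }
  k <- 2 * pi * spec$f / spec$medium$c_long
  a <- spec$a
  gs <- pracma::gaussLegendre(n_sigma, 0, a)
  gphi <- pracma::gaussLegendre(n_phi, 0, 2 * pi)
  sigma <- gs$x
  wsig <- gs$w
  phi <- gphi$x
  wphi <- gphi$w
  lens <- if (spec$geometry == "focused") {
    R <- spec$curvature_radius
    exp(1i * k * (sqrt(sigma^2 + R^2) - R))
  } else rep(1 + 0i, n_sigma)
  # source nodes flattened: weight sigma dsigma dphi and lens phase
  src_w <- as.vector(outer(wsig * sigma * lens, wphi))
  sig_v <- rep(sigma, times = n_phi)
  cphi_v <- rep(cos(phi), each = n_sigma)
  pts <- tidyr::expand_grid(z = z_grid, r = r_grid)
  pres <- numeric(nrow(pts))
  chunk <- max(1L, floor(2e6 / length(src_w)))
  idx <- split(seq_len(nrow(pts)), ceiling(seq_len(nrow(pts)) / chunk))
  for (ii in idx) {
    rr <- pts$r[ii]
    zz <- pts$z[ii]
    # distances field point -> source node, |points| x |nodes|
    Rp <- sqrt(outer(zz^2 + rr^2, sig_v^2, "+") -
                 2 * outer(rr, sig_v * cphi_v))
    pres[ii] <- Mod((exp(-1i * k * Rp) / Rp) %*% src_w) *
      (k * spec$p0 / (2 * pi))
  }
  out <- tibble::tibble(r = pts$r, z = pts$z, p = pres)
  attr(out, "spec") <- spec
  class(out) <- c("field_map", class(out))
  out
}

#' Plot a field map
#'
#' @param object A `field_map` tibble.
#' @param ... Ignored.
#' @return A ggplot raster of `|p|` over the `(z, r)` plane.
#' @exportS3Method ggplot2::autoplot
autoplot.field_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z * 1e3, y = .data$r * 1e3,
                                       fill = .data$p)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|p| (Pa)") +
    ggplot2::labs(x = "z (mm)", y = "r (mm)", title = "Piston pressure field")
}

#' Focal metrics of a field map
#'
#' Locates the on-axis focal peak and reports, in the units of the chamber
#' design tables:
#' * `focal_distance_mm` - axial position of the peak;
#' * `focal_length_mm` / `focal_width_mm` - extent of the -6 dB region
#'   (|p| >= peak/2) along and across the axis;
#' * `iso_area_5/15/25_mm2` - surface area (by revolution of the 2D contour
#'   about the axis) of the region within +/-5, 15, 25 % of the focal peak.
#'
#' Only the connected region containing the focal peak is measured, so
#' near-field lobes of equal amplitude are excluded.
#'
#' @param map A `field_map` from [rayleigh_field_map()] covering the focal
#'   region (the peak must not sit on the z- or outer r-boundary).
#' @param bands Iso-pressure bands as fractions of the peak.
#' @return A one-row tibble of class `focal_metrics`.
#' @export
focal_metrics <- function(map, bands = c(0.05, 0.15, 0.25)) {
  stopifnot(inherits(map, "field_map"))
  r_grid <- sort(unique(map$r))
  z_grid <- sort(unique(map$z))
  P <- matrix(map$p[order(map$r, map$z)], nrow = length(z_grid))
  # P[i, j] = p at (z_grid[i], r_grid[j])
  peak <- max(P)
  if (!is.finite(peak) || peak <= 0 || diff(range(P)) < 1e-12 * peak) {
    stop("field map has no unique focal peak", call. = FALSE)
  }
  pk <- which(P == peak, arr.ind = TRUE)[1, ]
  iz <- pk[1]; ir <- pk[2]
  if (iz == 1 || iz == length(z_grid) || ir == length(r_grid)) {
    stop("focal peak on grid boundary: enlarge grid", call. = FALSE)
  }
  # -6 dB axial extent within the connected above-half region holding the peak
  on_axis <- P[, ir]
  half <- peak / 2
  lo <- iz; while (lo > 1 && on_axis[lo - 1] >= half) lo <- lo - 1
  hi <- iz; while (hi < length(z_grid) && on_axis[hi + 1] >= half) hi <- hi + 1
  focal_length <- z_grid[hi] - z_grid[lo]
  row <- P[iz, ]
  rhi <- ir; while (rhi < length(r_grid) && row[rhi + 1] >= half) rhi <- rhi + 1
  focal_width <- 2 * r_grid[rhi]
  areas <- vapply(bands, function(b) {
    iso_revolution_area(P, z_grid, r_grid, level = peak * (1 - b),
                        seed = c(iz, ir))
  }, numeric(1))
  out <- tibble::tibble(
    focal_distance_mm = z_grid[iz] * 1e3,
    focal_length_mm = focal_length * 1e3,
    focal_width_mm = focal_width * 1e3
  )
  for (i in seq_along(bands)) {
    out[[sprintf("iso_area_%g_mm2", bands[i] * 100)]] <- areas[i] * 1e6
  }
  attr(out, "width_criterion") <- "-6 dB"
  class(out) <- c("focal_metrics", class(out))
  out
}

# surface of revolution (about r = 0) of the iso-pressure contour bounding
# the connected region >= level that contains the seed cell
iso_revolution_area <- function(P, z_grid, r_grid, level, seed) {
  mask <- P >= level
  comp <- flood_fill(mask, seed)
  lines <- grDevices::contourLines(x = z_grid, y = r_grid, z = P, levels = level)
  if (length(lines) == 0) return(0)
  area <- 0
  for (ln in lines) {
    # keep contour pieces that bound the focal component
    zi <- findInterval(ln$x, z_grid, all.inside = TRUE)
    ri <- findInterval(ln$y, r_grid, all.inside = TRUE)
    near <- mapply(function(i, j) {
      any(comp[max(i - 1, 1):min(i + 1, nrow(comp)),
               max(j - 1, 1):min(j + 1, ncol(comp))])
    }, zi, ri)
    if (mean(near) < 0.5) next
    dz <- diff(ln$x)
    dr <- diff(ln$y)
    rbar <- (ln$y[-1] + ln$y[-length(ln$y)]) / 2
    area <- area + sum(2 * pi * rbar * sqrt(dz^2 + dr^2))
  }
  area
}

flood_fill <- function(mask, seed) {
  comp <- matrix(FALSE, nrow(mask), ncol(mask))
  if (!mask[seed[1], seed[2]]) return(comp)
  queue <- matrix(seed, ncol = 2)
  comp[seed[1], seed[2]] <- TRUE
  while (nrow(queue) > 0) {
    cur <- queue[nrow(queue), , drop = FALSE]
    queue <- queue[-nrow(queue), , drop = FALSE]
    for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      ni <- cur[1] + dd[1]; nj <- cur[2] + dd[2]
      if (ni >= 1 && ni <= nrow(mask) && nj >= 1 && nj <= ncol(mask) &&
          mask[ni, nj] && !comp[ni, nj]) {
        comp[ni, nj] <- TRUE
        queue <- rbind(queue, c(ni, nj))
      }
    }
  }
  comp
}
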