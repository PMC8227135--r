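# Material property registry and elementary acoustic quantities.
#
# All internal computation is SI (kg/m^3, m/s, Pa, Np/m). Table I/O uses the
# engineering units of the shipped CSV (dB/cm at a reference frequency).

# 1 dB/cm = 100 dB/m; 1 dB = 1/(20 log10 e) Np  =>  ~11.513 Np/m per dB/cm
db_cm_to_np_m <- 100 / (20 * log10(exp(1)))

#' Define an acoustic medium
#'
#' An `acoustic_medium` bundles the properties the layered-media and
#' plane-wave solvers need: density, longitudinal (and, for solids, shear)
#' sound speed, and a power-law attenuation coefficient
#' \eqn{\alpha(f) = \alpha_0 (f/f_{ref})^n}. Optional elastic moduli (bulk
#' `K`, shear `G`, Young `E`, all Pa) may be attached; when present, the
#' speeds they imply (`sqrt((K + 4G/3)/rho)` and `sqrt(G/rho)`) must agree
#' with the stored speeds within `moduli_rel_tol`.
#'
#' @param name Material name (used to resolve stack configurations).
#' @param density Density in kg/m^3 (> 0).
#' @param c_long Longitudinal sound speed in m/s (> 0). For thin solid parts
#'   such as microscope slides the bar speed may be the better choice; the
#'   registry stores whichever speed the stack should propagate with.
#' @param c_shear Shear speed in m/s; 0 for fluids.
#' @param alpha0_db_per_cm Attenuation at the reference frequency, dB/cm.
#' @param f_ref_hz Reference frequency for the attenuation law, Hz.
#' @param alpha_exponent Power-law exponent (>= 0).
#' @param K,G,E Optional bulk, shear and Young moduli in Pa (`NA` to omit).
#' @param moduli_rel_tol Relative tolerance for the speed/moduli cross-check.
#'
#' @return An object of class `acoustic_medium`.
#' @examples
#' water <- acoustic_medium("water", 1000, 1480, alpha0_db_per_cm = 0.0022,
#'                          alpha_exponent = 2)
#' impedance(water)
#' @export
acoustic_medium <- function(name, density, c_long, c_shear = 0,
                            alpha0_db_per_cm = 0, f_ref_hz = 1e6,
                            alpha_exponent = 1,
                            K = NA_real_, G = NA_real_, E = NA_real_,
                            moduli_rel_tol = 2e-3) {
  stopifnot(is.character(name), length(name) == 1L)
  num1 <- function(x, what) {
    if (!is.numeric(x) || length(x) != 1L || is.nan(x)) {
      stop("`", what, "` must be a single number for medium '", name, "'",
           call. = FALSE)
    }
    as.double(x)
  }
  density <- num1(density, "density")
  c_long <- num1(c_long, "c_long")
  c_shear <- num1(c_shear, "c_shear")
  alpha0_db_per_cm <- num1(alpha0_db_per_cm, "alpha0_db_per_cm")
  f_ref_hz <- num1(f_ref_hz, "f_ref_hz")
  alpha_exponent <- num1(alpha_exponent, "alpha_exponent")
  if (density <= 0) stop("density must be > 0 for medium '", name, "'", call. = FALSE)
  if (c_long <= 0) stop("c_long must be > 0 for medium '", name, "'", call. = FALSE)
  if (c_shear < 0) stop("c_shear must be >= 0 for medium '", name, "'", call. = FALSE)
  if (alpha0_db_per_cm < 0) stop("alpha0 must be >= 0 for medium '", name, "'", call. = FALSE)
  if (alpha_exponent < 0) stop("alpha_exponent must be >= 0 for medium '", name, "'", call. = FALSE)
  if (f_ref_hz <= 0) stop("f_ref_hz must be > 0 for medium '", name, "'", call. = FALSE)
  for (m in list(K = K, G = G, E = E)) {
    if (!is.na(m) && m < 0) stop("moduli must be >= 0 for medium '", name, "'", call. = FALSE)
  }
  if (!is.na(K) && !is.na(G)) {
    bulk <- sqrt((K + 4 * G / 3) / density)
    if (abs(bulk - c_long) / c_long > moduli_rel_tol) {
      stop("medium '", name, "': bulk speed from moduli (", signif(bulk, 6),
           " m/s) disagrees with stored c_long (", c_long, " m/s)", call. = FALSE)
    }
    if (G > 0 && c_shear > 0) {
      cs <- sqrt(G / density)
      if (abs(cs - c_shear) / c_shear > moduli_rel_tol) {
        stop("medium '", name, "': shear speed from G (", signif(cs, 6),
             " m/s) disagrees with stored c_shear (", c_shear, " m/s)",
             call. = FALSE)
      }
    }
  }
  structure(
    list(name = name, density = density, c_long = c_long, c_shear = c_shear,
         alpha0_db_per_cm = alpha0_db_per_cm, f_ref_hz = f_ref_hz,
         alpha_exponent = alpha_exponent, K = K, G = G, E = E),
    class = "acoustic_medium"
  )
}

#' @export
print.acoustic_medium <- function(x, ...) {
  cat(sprintf("<acoustic_medium> %s: rho = %g kg/m^3, c_long = %g m/s, c_shear = %g m/s\n",
              x$name, x$density, x$c_long, x$c_shear))
  cat(sprintf("  alpha = %g dB/cm at %g MHz (exponent %g)\n",
              x$alpha0_db_per_cm, x$f_ref_hz / 1e6, x$alpha_exponent))
  invisible(x)
}

#' Is a medium fluid (no shear branch)?
#' @param medium An [acoustic_medium()].
#' @return `TRUE` when `c_shear` is zero.
#' @export
is_fluid <- function(medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  medium$c_shear <= 0
}

#' Specific acoustic impedance r = rho c
#'
#' The product of density and longitudinal sound speed; impedance mismatch
#' between adjacent media governs reflection at their interface.
#'
#' @param medium An [acoustic_medium()].
#' @return Impedance in Pa s/m.
#' @export
impedance <- function(medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  medium$density * medium$c_long
}

#' Shear-wave impedance rho c_shear
#'
#' Solids carry a shear branch with its own, lower impedance. Fluids have no
#' shear branch and signal an error.
#'
#' @param medium An [acoustic_medium()].
#' @return Shear impedance in Pa s/m.
#' @export
shear_impedance <- function(medium) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (is_fluid(medium)) {
    stop("medium '", medium$name, "' is fluid: no shear branch", call. = FALSE)
  }
  medium$density * medium$c_shear
}

#' Longitudinal speeds from elastic moduli
#'
#' For extended solids the bulk longitudinal speed
#' \eqn{\sqrt{(K + 4G/3)/\rho}} applies; for slender parts (bars, slides,
#' coverslips) the bar speed \eqn{\sqrt{E/\rho}} is the relevant one.
#' Either speed is reported only when its moduli are supplied.
#'
#' @param density Density, kg/m^3.
#' @param K,G,E Bulk, shear and Young moduli in Pa (`NA` to omit).
#' @return A one-row tibble with `bulk_speed` and `bar_speed` (m/s, `NA`
#'   when the needed moduli are absent).
#' @examples
#' speeds_from_moduli(2500, K = 3.9867e10, G = 2.89e10, E = 7e10)
#' @export
speeds_from_moduli <- function(density, K = NA_real_, G = NA_real_, E = NA_real_) {
  stopifnot(is.numeric(density), length(density) == 1L, density > 0)
  if ((is.na(K) || is.na(G)) && is.na(E)) {
    stop("supply at least (K, G) or E", call. = FALSE)
  }
  for (m in list(K = K, G = G, E = E)) {
    if (!is.na(m) && m < 0) stop("moduli must be >= 0", call. = FALSE)
  }
  bulk <- if (!is.na(K) && !is.na(G)) sqrt((K + 4 * G / 3) / density) else NA_real_
  bar <- if (!is.na(E)) sqrt(E / density) else NA_real_
  tibble::tibble(bulk_speed = bulk, bar_speed = bar)
}

#' Attenuation coefficient at a frequency
#'
#' Evaluates the medium's power law
#' \eqn{\alpha(f) = \alpha_0 (f/f_{ref})^n} and converts from dB/cm to Np/m
#' (1 dB/cm = 11.513 Np/m). Amplitude decays as `exp(-alpha z)`; power at
#' twice that rate.
#'
#' @param medium An [acoustic_medium()].
#' @param f Frequency in Hz (> 0); vectorized.
#' @return Attenuation in Np/m.
#' @export
attenuation_at <- function(medium, f) {
  stopifnot(inherits(medium, "acoustic_medium"))
  if (any(f <= 0)) stop("f must be > 0", call. = FALSE)
  medium$alpha0_db_per_cm * db_cm_to_np_m *
    (f / medium$f_ref_hz)^medium$alpha_exponent
}

material_table_cols <- c("name", "density", "c_long", "c_shear",
                         "alpha0_db_per_cm", "f_ref_hz", "alpha_exponent")

#' Load a material table
#'
#' Reads a CSV material registry with header
#' `name,density,c_long,c_shear,alpha0_db_per_cm,f_ref_hz,alpha_exponent[,K,G,E]`
#' and validates every row by constructing its [acoustic_medium()].
#'
#' @param path Path to a CSV file.
#' @return A tibble of class `sono_materials`, one row per material.
#' @seealso [sono_materials()] for the shipped default table, [material()]
#'   to extract one medium.
#' @export
load_material_table <- function(path) {
  if (!file.exists(path)) stop("material table not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(material_table_cols, names(tab))
  if (length(missing) > 0) {
    stop("material table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in c("K", "G", "E")) {
    if (!col %in% names(tab)) tab[[col]] <- NA_real_
  }
  tab <- tab[, c(material_table_cols, "K", "G", "E")]
  for (col in setdiff(names(tab), "name")) {
    if (!is.numeric(tab[[col]])) {
      stop("material table column '", col, "' is not numeric", call. = FALSE)
    }
  }
  for (i in seq_len(nrow(tab))) {
    row <- tab[i, ]
    for (col in material_table_cols[-1]) {
      if (is.na(row[[col]])) {
        stop("material table row '", row$name, "': column '", col,
             "' is missing or non-numeric", call. = FALSE)
      }
    }
    # full invariant check (throws naming the medium)
    tryCatch(material_from_row(row), error = function(e) {
      stop("material table row '", row$name, "': ", conditionMessage(e),
           call. = FALSE)
    })
  }
  class(tab) <- c("sono_materials", class(tab))
  tab
}

#' Default material registry
#'
#' The registry shipped with the package: water, borosilicate glass,
#' polystyrene, adiprene (a soft polyurethane), polyethylene and air, with
#' pinned handbook-range constants so that results are reproducible.
#'
#' @param path Optional path to an alternative CSV table.
#' @return A `sono_materials` tibble.
#' @examples
#' mats <- sono_materials()
#' material(mats, "water")
#' @export
sono_materials <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "materials.csv", package = "sonochamber",
                        mustWork = TRUE)
  }
  load_material_table(path)
}

#' Write a material table
#'
#' Serializes a registry back to CSV in the same layout [load_material_table()]
#' reads, so that a write/read round trip is the identity.
#'
#' @param materials A `sono_materials` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_material_table <- function(materials, path) {
  stopifnot(inherits(materials, "sono_materials"))
  readr::write_csv(materials, path, progress = FALSE)
  invisible(path)
}

material_from_row <- function(row) {
  acoustic_medium(
    name = row$name, density = row$density, c_long = row$c_long,
    c_shear = row$c_shear, alpha0_db_per_cm = row$alpha0_db_per_cm,
    f_ref_hz = row$f_ref_hz, alpha_exponent = row$alpha_exponent,
    K = row$K, G = row$G, E = row$E
  )
}

#' Extract one medium from a registry
#'
#' @param materials A `sono_materials` tibble.
#' @param name Material name to look up.
#' @return An [acoustic_medium()].
#' @export
material <- function(materials, name) {
  stopifnot(inherits(materials, "sono_materials"))
  hit <- which(materials$name == name)
  if (length(hit) != 1L) {
    stop("unknown material '", name, "' (available: ",
         paste(materials$name, collapse = ", "), ")", call. = FALSE)
  }
  material_from_row(materials[hit, ])
}
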