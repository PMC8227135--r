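# Chamber design data model and the end-to-end evaluation pipeline: a
# calibrated piston source feeding a five-layer bath/slide/sample/coverslip/
# backing stack under oblique incidence, with standing-wave, attenuation,
# critical-angle, microbubble and bath-volume summaries.

#' Describe a chamber design
#'
#' The default values reproduce the reference design: a 1 MHz flat immersion
#' transducer calibrated to a 500 kPa free-field focal pressure at 60 mm,
#' aimed at 26.5 degrees from the normal onto a 1.2 mm glass slide; the
#' sample liquid sits in a 10-20 um gap between the slide and a 0.17 mm
#' glass coverslip backed by air.
#'
#' @param incidence_angle Design incidence angle in degrees, `[0, 90)`.
#' @param bath Bath medium name (the transducer's coupling liquid).
#' @param slide_material,slide_thickness Slide (first rigid wall) material
#'   name and thickness in m.
#' @param sample_medium Sample liquid material name.
#' @param gap Sample gap L in m. Give either `gap` or both `volume` and
#'   `contact_area`.
#' @param volume,contact_area Droplet volume (m^3) and wetted coverslip area
#'   (m^2); the gap is then `volume / contact_area`.
#' @param coverslip_material,coverslip_thickness Coverslip material name and
#'   thickness in m.
#' @param backing Backing half-space material name.
#' @param frequency Drive frequency in Hz.
#' @param element_radius Piston active element radius in m (default sized so
#'   that `a^2/lambda` puts the free-field focal spot at 60 mm in water).
#' @param transducer_external_radius External transducer radius in m (used
#'   only for the classical-bath minimum-volume comparison).
#' @param focal_distance Nominal focal distance in m.
#' @param calibration_focal_pressure Measured free-field focal peak pressure
#'   in Pa that the source amplitude is scaled to.
#' @param gap_range Declared range of achievable gaps, m (length 2).
#' @param bubble_R0 Microbubble radius reported in the design summary, m.
#' @param bubble Optional [bubble_parameters()] overriding the defaults at
#'   `bubble_R0`.
#' @return An object of class `chamber_design`.
#' @export
chamber_design <- function(incidence_angle = 26.5,
                           bath = "water",
                           slide_material = "glass", slide_thickness = 1.2e-3,
                           sample_medium = "water",
                           gap = NULL, volume = NULL, contact_area = NULL,
                           coverslip_material = "glass",
                           coverslip_thickness = 0.17e-3,
                           backing = "air",
                           frequency = 1e6,
                           element_radius = 9.43e-3,
                           transducer_external_radius = 12.5e-3,
                           focal_distance = 60e-3,
                           calibration_focal_pressure = 500e3,
                           gap_range = c(10e-6, 20e-6),
                           bubble_R0 = 3e-6,
                           bubble = NULL) {
  if (incidence_angle < 0 || incidence_angle >= 90) {
    stop("incidence_angle must be in [0, 90) degrees", call. = FALSE)
  }
  if (slide_thickness <= 0 || coverslip_thickness <= 0) {
    stop("wall thicknesses must be > 0", call. = FALSE)
  }
  from_volume <- !is.null(volume) || !is.null(contact_area)
  if (!is.null(gap) && from_volume) {
    stop("give exactly one of `gap` or (`volume` + `contact_area`)", call. = FALSE)
  }
  if (from_volume) {
    if (is.null(volume) || is.null(contact_area)) {
      stop("both `volume` and `contact_area` are needed", call. = FALSE)
    }
    gap <- gap_from_volume(volume, contact_area)
  }
  if (is.null(gap)) gap <- 15e-6 # midpoint of the typical 10-20 um range
  if (gap <= 0) stop("sample gap must be > 0", call. = FALSE)
  stopifnot(length(gap_range) == 2, all(gap_range > 0))
  if (is.null(bubble)) bubble <- bubble_parameters(R0 = bubble_R0)
  structure(
    list(incidence_angle = incidence_angle, bath = bath,
         slide_material = slide_material, slide_thickness = slide_thickness,
         sample_medium = sample_medium, gap = gap,
         coverslip_material = coverslip_material,
         coverslip_thickness = coverslip_thickness, backing = backing,
         frequency = frequency, element_radius = element_radius,
         transducer_external_radius = transducer_external_radius,
         focal_distance = focal_distance,
         calibration_focal_pressure = calibration_focal_pressure,
         gap_range = sort(gap_range), bubble_R0 = bubble_R0, bubble = bubble),
    class = "chamber_design"
  )
}

#' Sample gap from droplet volume
#'
#' The gap between slide and coverslip is set by the trapped droplet:
#' `L = volume / contact_area`.
#'
#' @param volume Droplet volume in m^3 (>= 0).
#' @param area Wetted coverslip area in m^2 (> 0).
#' @return The gap L in m.
#' @examples
#' gap_from_volume(3.24e-9, 18e-3 * 18e-3) # 10 um
#' @export
gap_from_volume <- function(volume, area) {
  if (any(volume < 0)) stop("volume must be >= 0", call. = FALSE)
  if (any(area <= 0)) stop("area must be > 0", call. = FALSE)
  volume / area
}

#' Minimum classical-bath volume
#'
#' The smallest water bath that fits a fully immersed transducer aiming at
#' its focal spot is a cylinder of radius `R` (at least the transducer's
#' external radius) and height `H` (at least the focal distance):
#' `V = pi R^2 H`, rounded up to whole millilitres since both dimensions are
#' lower bounds.
#'
#' @param R Cylinder radius in m (>= 0).
#' @param H Cylinder height in m (>= 0).
#' @return Volume in integer mL.
#' @examples
#' minimum_bath_volume(12.5e-3, 60e-3) # 30 mL
#' @export
minimum_bath_volume <- function(R, H) {
  if (any(R < 0) || any(H < 0)) stop("R and H must be >= 0", call. = FALSE)
  as.integer(ceiling(pi * R^2 * H * 1e6))
}

#' Build the five-layer stack of a chamber design
#'
#' @param design A [chamber_design()].
#' @param materials A `sono_materials` registry.
#' @param gap Optional gap override in m.
#' @param wall_material Optional material name overriding both walls.
#' @return A [layer_stack()]: bath / slide / sample / coverslip / backing.
#' @export
chamber_stack <- function(design, materials = sono_materials(), gap = NULL,
                          wall_material = NULL) {
  stopifnot(inherits(design, "chamber_design"))
  if (is.null(gap)) gap <- design$gap
  slide <- if (is.null(wall_material)) design$slide_material else wall_material
  slip <- if (is.null(wall_material)) design$coverslip_material else wall_material
  layer_stack(
    list(material(materials, design$bath),
         material(materials, slide),
         material(materials, design$sample_medium),
         material(materials, slip),
         material(materials, design$backing)),
    c(Inf, design$slide_thickness, gap, design$coverslip_thickness, Inf)
  )
}

#' Evaluate a chamber design
#'
#' Runs the design pipeline:
#' 1. scales the piston source so the free-field focal peak equals the
#'    calibration pressure;
#' 2. solves the five-layer stack at the design incidence angle
#'    (focal-zone plane-wave approximation, lateral wavenumber conserved);
#' 3. reports the transmitted sample-layer peak pressure, per-layer
#'    attenuation losses, the standing-wave excursion over the declared gap
#'    range, critical-angle verdicts for the bath/slide interface, the
#'    microbubble resonance and the mechanical index at the transmitted
#'    pressure;
#' 4. attaches the classical-bath minimum-volume comparison.
#'
#' @param design A [chamber_design()].
#' @param materials A `sono_materials` registry.
#' @return An object of class `design_report`.
#' @examples
#' \donttest{
#' report <- evaluate_design(chamber_design())
#' report
#' }
#' @export
evaluate_design <- function(design, materials = sono_materials()) {
  stopifnot(inherits(design, "chamber_design"))
  f <- design$frequency
  bath <- material(materials, design$bath)
  slide <- material(materials, design$slide_material)
  slip <- material(materials, design$coverslip_material)
  sample <- material(materials, design$sample_medium)

  # (1) calibration: source amplitude such that the free-field focal peak
  # equals the measured calibration pressure
  spec1 <- transducer_spec("flat", a = design$element_radius, f = f,
                           medium = bath, p0 = 1)
  focal <- last_axial_maximum(spec1)
  peak_per_p0 <- on_axis_flat(spec1, focal)
  p0 <- design$calibration_focal_pressure / peak_per_p0
  cal <- design$calibration_focal_pressure

  # (2) layered solve at the design angle
  stack <- chamber_stack(design, materials)
  field <- if (design$incidence_angle == 0) solve_normal(stack, f)
           else solve_oblique(stack, f, design$incidence_angle)
  samp <- layer_pressure(field, 3, seq(0, design$gap, length.out = 201))
  sample_ratio <- max(samp$p_abs)
  transmitted <- sample_ratio * cal

  # (3) summaries
  crit <- critical_angles(bath, slide)
  beyond_long <- !is.na(crit$theta_c_long) && design$incidence_angle >= crit$theta_c_long
  beyond_shear <- !is.na(crit$theta_c_shear) && design$incidence_angle >= crit$theta_c_shear
  sweep <- sample_amplitude_vs_gap(
    stack, seq(design$gap_range[1], design$gap_range[2], length.out = 41),
    f, theta_i = design$incidence_angle
  )
  losses <- tibble::tibble(
    layer = c("slide", "sample", "coverslip"),
    material = c(slide$name, sample$name, slip$name),
    thickness_mm = c(design$slide_thickness, design$gap,
                     design$coverslip_thickness) * 1e3,
    attenuation_loss_pct = 100 * c(
      power_loss_through(slide, design$slide_thickness, f),
      power_loss_through(sample, design$gap, f),
      power_loss_through(slip, design$coverslip_thickness, f)
    )
  )
  f0 <- resonance_frequency(design$bubble)
  mi <- mechanical_index(transmitted / 1e3, f)
  bath_ml <- minimum_bath_volume(design$transducer_external_radius,
                                 design$focal_distance)
  assumptions <- c(
    sprintf("piston element radius a = %.4g mm chosen so a^2/lambda matches the %.3g mm focal distance (active radius not independently measured)",
            design$element_radius * 1e3, design$focal_distance * 1e3),
    "free-field semi-analytic piston model; no tube-wall reverberation",
    "focal-zone plane-wave approximation at the stack; no beam-spread correction over the 60 mm path",
    sprintf("26.5 degrees is treated as the design incidence angle, not identified with a specific acoustic angle (shear critical angle of %s is %.3g deg)",
            slide$name, crit$theta_c_shear),
    "transmitted pressure is this model's value; a full-wave simulation including tube walls reported 380 kPa for the reference design (model difference, not reproduced here)",
    sprintf("shelled-bubble defaults gamma = %.3g, sigma = %.3g N/m, chi = %.3g N/m",
            design$bubble$gamma, design$bubble$sigma, design$bubble$chi)
  )
  structure(
    list(
      design = design,
      free_field_focal_pressure_kpa = cal / 1e3,
      source_amplitude_kpa = p0 / 1e3,
      focal_distance_mm = focal * 1e3,
      sample_amplitude_ratio = sample_ratio,
      transmitted_sample_pressure_kpa = transmitted / 1e3,
      reference_transmitted_pressure_kpa = 380,
      attenuation_losses = losses,
      standing_wave = list(
        gap_range_um = design$gap_range * 1e6,
        min_ratio = min(sweep$amplitude_ratio),
        max_ratio = max(sweep$amplitude_ratio),
        sweep = sweep
      ),
      critical_angles_deg = crit,
      beyond_longitudinal_critical = beyond_long,
      beyond_shear_critical = beyond_shear,
      no_transmission = beyond_long && beyond_shear && sample_ratio < 1e-9,
      field = field,
      T_power = field$T_power,
      R_power = field$R_power,
      bubble_R0_um = design$bubble_R0 * 1e6,
      bubble_f0_mhz = f0 / 1e6,
      mechanical_index = mi,
      minimum_bath_volume_ml = bath_ml,
      assumptions = assumptions
    ),
    class = "design_report"
  )
}

#' @export
print.design_report <- function(x, ...) {
  d <- x$design
  cat("<design_report>\n")
  cat(sprintf("  incidence %g deg | %s %.3g mm / %s gap %.3g um / %s %.3g mm / %s backing\n",
              d$incidence_angle, d$slide_material, d$slide_thickness * 1e3,
              d$sample_medium, d$gap * 1e6, d$coverslip_material,
              d$coverslip_thickness * 1e3, d$backing))
  cat(sprintf("  free-field focal pressure : %.4g kPa at %.4g mm\n",
              x$free_field_focal_pressure_kpa, x$focal_distance_mm))
  cat(sprintf("  sample-plane peak pressure: %.4g kPa (ratio %.4g; reference full-wave value %g kPa)\n",
              x$transmitted_sample_pressure_kpa, x$sample_amplitude_ratio,
              x$reference_transmitted_pressure_kpa))
  cat(sprintf("  standing wave over %g-%g um: ratio %.4g-%.4g\n",
              x$standing_wave$gap_range_um[1], x$standing_wave$gap_range_um[2],
              x$standing_wave$min_ratio, x$standing_wave$max_ratio))
  cat(sprintf("  critical angles (bath/slide): long %.4g deg%s, shear %.4g deg%s\n",
              x$critical_angles_deg$theta_c_long,
              if (x$beyond_longitudinal_critical) " (exceeded)" else "",
              x$critical_angles_deg$theta_c_shear,
              if (x$beyond_shear_critical) " (exceeded)" else ""))
  if (x$no_transmission) cat("  ** no transmission at this angle **\n")
  cat(sprintf("  bubble f0(R0 = %g um) = %.4g MHz | MI at sample = %.4g\n",
              x$bubble_R0_um, x$bubble_f0_mhz, x$mechanical_index))
  cat(sprintf("  classical bath would need >= %d mL\n", x$minimum_bath_volume_ml))
  cat("  assumptions: ", length(x$assumptions), " recorded (see $assumptions)\n", sep = "")
  invisible(x)
}

#' Tidy a design report
#'
#' @param x A `design_report`.
#' @param ... Ignored.
#' @return A tibble of (quantity, value, units) rows.
#' @exportS3Method generics::tidy
tidy.design_report <- function(x, ...) {
  tibble::tribble(
    ~quantity, ~value, ~units,
    "free_field_focal_pressure", x$free_field_focal_pressure_kpa, "kPa",
    "focal_distance", x$focal_distance_mm, "mm",
    "sample_amplitude_ratio", x$sample_amplitude_ratio, "1",
    "transmitted_sample_pressure", x$transmitted_sample_pressure_kpa, "kPa",
    "standing_wave_min_ratio", x$standing_wave$min_ratio, "1",
    "standing_wave_max_ratio", x$standing_wave$max_ratio, "1",
    "critical_angle_longitudinal", x$critical_angles_deg$theta_c_long, "deg",
    "critical_angle_shear", x$critical_angles_deg$theta_c_shear, "deg",
    "power_transmission", x$T_power, "1",
    "power_reflection", x$R_power, "1",
    "bubble_resonance", x$bubble_f0_mhz, "MHz",
    "mechanical_index", x$mechanical_index, "1",
    "minimum_bath_volume", as.numeric(x$minimum_bath_volume_ml), "mL"
  )
}

#' One-row design summary
#'
#' @param x A `design_report`.
#' @param ... Ignored.
#' @return A one-row tibble with the headline quantities.
#' @exportS3Method generics::glance
glance.design_report <- function(x, ...) {
  tibble::tibble(
    incidence_angle_deg = x$design$incidence_angle,
    free_field_focal_pressure_kpa = x$free_field_focal_pressure_kpa,
    transmitted_sample_pressure_kpa = x$transmitted_sample_pressure_kpa,
    sample_amplitude_ratio = x$sample_amplitude_ratio,
    bubble_f0_mhz = x$bubble_f0_mhz,
    mechanical_index = x$mechanical_index,
    minimum_bath_volume_ml = x$minimum_bath_volume_ml,
    no_transmission = x$no_transmission
  )
}

#' Wall-material sensitivity of the gap dependence
#'
#' Sweeps the sample gap for each candidate wall material and compares the
#' (max - min) excursion of the sample-layer standing-wave amplitude. Stiff,
#' high-impedance walls (glass) make the in-gap pressure much more sensitive
#' to the exact gap than softer polystyrene walls.
#'
#' @param design A [chamber_design()].
#' @param L_range Gaps to sweep, m (non-empty).
#' @param materials A `sono_materials` registry.
#' @param wall_materials Candidate wall material names.
#' @param theta_i Incidence angle for the sweep in degrees (default the
#'   design angle; 0 gives the normal-incidence appendix-style comparison).
#' @return A tibble with one row per wall material (`min`, `max`,
#'   `excursion`), the per-gap sweeps in the `sweep` list-column, and the
#'   excursion ordering recorded in the `ordering` attribute.
#' @export
material_sensitivity_sweep <- function(design, L_range,
                                       materials = sono_materials(),
                                       wall_materials = c("glass", "polystyrene"),
                                       theta_i = NULL) {
  stopifnot(inherits(design, "chamber_design"))
  if (length(L_range) == 0) stop("L_range must be non-empty", call. = FALSE)
  if (is.null(theta_i)) theta_i <- design$incidence_angle
  res <- purrr::map_dfr(wall_materials, function(w) {
    st <- chamber_stack(design, materials, wall_material = w)
    sw <- sample_amplitude_vs_gap(st, L_range, design$frequency, theta_i = theta_i)
    tibble::tibble(
      wall_material = w,
      min_ratio = min(sw$amplitude_ratio),
      max_ratio = max(sw$amplitude_ratio),
      excursion = max(sw$amplitude_ratio) - min(sw$amplitude_ratio),
      sweep = list(sw)
    )
  })
  ord <- res$wall_material[order(res$excursion, decreasing = TRUE)]
  attr(res, "ordering") <- paste(ord, collapse = " > ")
  res
}
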