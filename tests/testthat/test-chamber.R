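test_that("the sample gap follows from droplet volume and contact area", {
  expect_equal(gap_from_volume(3.24e-9, 18e-3 * 18e-3), 10e-6)
  expect_equal(gap_from_volume(0, 1e-4), 0)
  expect_equal(gap_from_volume(1e-8, pi * 0.0126^2), 20e-6, tolerance = 3e-3)
  expect_error(gap_from_volume(1e-9, 0), "area")
})

test_that("the classical bath volume rounds pi R^2 H up to whole millilitres", {
  expect_identical(minimum_bath_volume(12.5e-3, 60e-3), 30L)
  expect_identical(minimum_bath_volume(0, 60e-3), 0L)
  expect_identical(minimum_bath_volume(12.5e-3, 0), 0L)
  expect_identical(minimum_bath_volume(10e-3, 50e-3), 16L)
  # monotone in both dimensions
  R <- seq(5e-3, 25e-3, length.out = 9)
  expect_true(all(diff(minimum_bath_volume(R, 60e-3)) >= 0))
  expect_true(all(diff(minimum_bath_volume(12.5e-3, R)) >= 0))
  expect_error(minimum_bath_volume(-1, 1), ">= 0")
})

test_that("chamber designs validate their gap specification", {
  expect_error(chamber_design(gap = 15e-6, volume = 1e-8, contact_area = 1e-4),
               "exactly one")
  expect_error(chamber_design(volume = 1e-8), "contact_area")
  d <- chamber_design(volume = 3.24e-9, contact_area = 3.24e-4)
  expect_equal(d$gap, 10e-6)
  expect_equal(chamber_design()$gap, 15e-6)
  expect_error(chamber_design(incidence_angle = 95), "90")
})

test_that("the default design transmits less than the free-field calibration", {
  report <- evaluate_design(chamber_design())
  expect_lt(report$transmitted_sample_pressure_kpa, 500)
  expect_gt(report$transmitted_sample_pressure_kpa, 0)
  expect_equal(report$free_field_focal_pressure_kpa, 500)
  expect_equal(report$focal_distance_mm, 59.7, tolerance = 0.01)
  expect_identical(report$minimum_bath_volume_ml, 30L)
  expect_false(report$no_transmission)
  # 26.5 deg exceeds both glass critical angles yet tunnelling transmits
  expect_true(report$beyond_shear_critical)
  expect_gt(report$sample_amplitude_ratio, 1e-3)
  expect_gt(length(report$assumptions), 0)
  expect_equal(report$standing_wave$gap_range_um, c(10, 20))
  expect_lte(report$standing_wave$min_ratio, report$sample_amplitude_ratio)
  expect_gte(report$standing_wave$max_ratio, report$sample_amplitude_ratio)
  expect_output(print(report), "sample-plane peak pressure")
})

test_that("water walls pass the calibration pressure through unchanged", {
  d <- chamber_design(slide_material = "water", coverslip_material = "water")
  report <- evaluate_design(d, lossless_materials())
  # no walls: the forward (transmitted) wave in the sample keeps the full
  # calibration amplitude; the reported peak additionally carries the
  # standing wave reflected off the air backing
  expect_equal(Mod(report$field$layers$p_down[3]), 1, tolerance = 1e-9)
  expect_gte(report$sample_amplitude_ratio, 1 - 1e-9)
})

test_that("the pipeline matches the brute-force oracle for a lossless normal design", {
  mats <- lossless_materials()
  d <- chamber_design(incidence_angle = 0)
  report <- evaluate_design(d, mats)
  st <- chamber_stack(d, mats)
  oracle <- brute_force_five_layer(st, d$frequency)
  expect_equal(report$T_power, oracle$T_power, tolerance = 1e-10)
  peak <- sonochamber:::fluid_layer_peak(oracle, 3, d$gap)
  expect_equal(report$sample_amplitude_ratio, peak, tolerance = 1e-10)
})

test_that("design summaries tidy into labelled tables", {
  report <- evaluate_design(chamber_design())
  td <- tidy(report)
  expect_true(all(c("quantity", "value", "units") %in% names(td)))
  expect_true("transmitted_sample_pressure" %in% td$quantity)
  expect_false(any(td$units == ""))
  gl <- glance(report)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$minimum_bath_volume_ml, 30L)
})

test_that("wall-material sensitivity ranks glass above polystyrene", {
  d <- chamber_design()
  L <- seq(1e-6, 740e-6, length.out = 99)
  sens <- material_sensitivity_sweep(d, L, materials = lossless_materials(),
                                     theta_i = 0)
  eg <- sens$excursion[sens$wall_material == "glass"]
  ep <- sens$excursion[sens$wall_material == "polystyrene"]
  expect_gt(eg, ep)
  expect_match(attr(sens, "ordering"), "glass > polystyrene")
  # degenerate single-gap sweep has zero excursion
  one <- material_sensitivity_sweep(d, 15e-6, theta_i = 0)
  expect_true(all(one$excursion == 0))
  # walls matching the sample erase the gap dependence (gaps beyond the
  # half-wavelength saturation of the air-backing standing wave)
  Lsat <- seq(740e-6, 1.5e-3, length.out = 25)
  ww <- material_sensitivity_sweep(d, Lsat, materials = lossless_materials(),
                                   wall_materials = c("water", "water"),
                                   theta_i = 0)
  expect_true(all(ww$excursion < 1e-9))
})

test_that("chamber configs round-trip through the YAML reader", {
  cfg <- system.file("extdata", "default_chamber.yaml", package = "sonochamber")
  d <- read_chamber_config(cfg)
  expect_equal(d$incidence_angle, 26.5)
  expect_equal(d$slide_thickness, 1.2e-3)
  expect_equal(d$gap, 15e-6)
  expect_equal(d$calibration_focal_pressure, 500e3)
  expect_equal(d$bubble$chi, 0.55)
})

test_that("the CLI evaluates configs deterministically and flags bad input", {
  cfg <- system.file("extdata", "default_chamber.yaml", package = "sonochamber")
  out1 <- withr::local_tempfile(fileext = ".json")
  out2 <- withr::local_tempfile(fileext = ".json")
  expect_identical(run_cli(c("evaluate", "--config", cfg, "--out", out1)), 0L)
  expect_identical(run_cli(c("evaluate", "--config", cfg, "--out", out2)), 0L)
  expect_identical(readLines(out1), readLines(out2))
  rep <- jsonlite::read_json(out1)
  expect_lt(rep$transmitted_sample_pressure_kpa, 500)
  expect_equal(rep$minimum_bath_volume_ml, 30)

  # unknown material: nonzero exit, message names the material
  bad <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("chamber:", "  slide:", "    material: unobtainium"), bad)
  msgs <- capture_messages(
    code <- run_cli(c("evaluate", "--config", bad, "--out", out1))
  )
  expect_identical(code, 1L)
  expect_match(paste(msgs, collapse = " "), "unobtainium")
  expect_identical(run_cli(c("frobnicate")), 1L) |> suppressMessages()
})

test_that("the CLI sweep, bubble and materials subcommands produce their files", {
  cfg <- system.file("extdata", "default_chamber.yaml", package = "sonochamber")
  csv <- withr::local_tempfile(fileext = ".csv")
  expect_identical(
    run_cli(c("sweep-gap", "--config", cfg, "--out", csv,
              "--l-min-um", "5", "--l-max-um", "30", "--n", "6",
              "--theta", "0")),
    0L
  )
  sw <- readr::read_csv(csv, show_col_types = FALSE)
  expect_named(sw, c("L_um", "amplitude_ratio"))
  expect_equal(nrow(sw), 6)

  js <- withr::local_tempfile(fileext = ".json")
  expect_identical(
    run_cli(c("bubble", "--radius-um", "3", "--pnp-kpa", "380", "--out", js)),
    0L
  )
  bj <- jsonlite::read_json(js)
  expect_equal(bj$f0_mhz, 1.196, tolerance = 1e-3)
  expect_equal(bj$mechanical_index, 0.38)

  listed <- capture.output(code <- run_cli(c("materials", "list")))
  expect_identical(code, 0L)
  expect_match(paste(listed, collapse = "\n"), "polystyrene")
})
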