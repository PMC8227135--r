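test_that("specific impedance is density times longitudinal speed", {
  expect_equal(impedance(water0()), 1.48e6)
  expect_equal(impedance(acoustic_medium("unit", 1, 1)), 1)
  expect_equal(impedance(air0()), 412.972, tolerance = 1e-6)
  # bilinearity: scaling density scales impedance
  m2 <- acoustic_medium("w2", 3000, 1480)
  expect_equal(impedance(m2), 3 * impedance(water0()))
})

test_that("shear impedance exists for solids only", {
  expect_equal(shear_impedance(glass0()), 8.5e6)
  expect_equal(shear_impedance(acoustic_medium("u", 1, 1, 1)), 1)
  expect_error(shear_impedance(water0()), "no shear branch")
})

test_that("medium invariants are enforced at construction", {
  expect_error(acoustic_medium("bad", -1, 1480), "density")
  expect_error(acoustic_medium("bad", 1000, 0), "c_long")
  expect_error(acoustic_medium("bad", 1000, 1480, c_shear = -1), "c_shear")
  expect_error(acoustic_medium("bad", 1000, 1480, alpha0_db_per_cm = -0.1), "alpha0")
  expect_error(acoustic_medium("bad", 1000, 1480, K = -1, G = 0), "moduli")
  # stored speed must match the speed the moduli imply
  expect_error(acoustic_medium("bad", 1000, 3000, K = 2.2e9, G = 0),
               "disagrees")
  expect_silent(acoustic_medium("ok", 1000, 1483.24, K = 2.2e9, G = 0))
})

test_that("speeds from moduli cover the bar and bulk branches", {
  s <- speeds_from_moduli(2500, E = 70e9)
  expect_equal(s$bar_speed, sqrt(70e9 / 2500), tolerance = 1e-12)
  expect_equal(s$bar_speed, 5291.5, tolerance = 1e-4)
  expect_true(is.na(s$bulk_speed))
  s2 <- speeds_from_moduli(1000, K = 2.2e9, G = 0)
  expect_equal(s2$bulk_speed, 1483.24, tolerance = 1e-4)
  expect_equal(speeds_from_moduli(1, E = 1)$bar_speed, 1)
  # fluid limit: G = 0 reduces the bulk speed to sqrt(K/rho)
  for (K in c(1e9, 2.2e9, 1e10)) {
    expect_equal(speeds_from_moduli(1000, K = K, G = 0)$bulk_speed,
                 sqrt(K / 1000))
  }
  expect_error(speeds_from_moduli(1000), "supply at least")
  expect_error(speeds_from_moduli(1000, K = -1, G = 1), ">= 0")
})

test_that("attenuation follows the power law and unit conversion", {
  m <- acoustic_medium("m", 1000, 1500, alpha0_db_per_cm = 1,
                       f_ref_hz = 1e6, alpha_exponent = 2)
  # 1 dB/cm at the reference frequency is ~11.513 Np/m
  expect_equal(attenuation_at(m, 1e6), 11.5129, tolerance = 1e-4)
  expect_equal(attenuation_at(m, 2e6), 4 * attenuation_at(m, 1e6))
  expect_error(attenuation_at(m, 0), "f must be > 0")
  # monotone non-decreasing in f for non-negative exponents
  for (ex in c(0, 0.5, 1, 2)) {
    mm <- acoustic_medium("m", 1000, 1500, alpha0_db_per_cm = 0.3,
                          alpha_exponent = ex)
    f <- seq(1e5, 1e7, length.out = 40)
    expect_true(all(diff(attenuation_at(mm, f)) >= 0))
  }
})

test_that("the shipped registry contains the chamber materials", {
  mats <- sono_materials()
  expect_true(all(c("water", "glass", "polystyrene", "adiprene",
                    "polyethylene", "air") %in% mats$name))
  w <- material(mats, "water")
  expect_equal(w$density, 1000)
  expect_equal(w$c_long, 1480)
  g <- material(mats, "glass")
  expect_equal(g$c_shear, 3400)
  expect_error(material(mats, "adamantium"), "adamantium")
})

test_that("material tables round-trip through CSV", {
  mats <- sono_materials()
  path <- withr::local_tempfile(fileext = ".csv")
  write_material_table(mats, path)
  again <- load_material_table(path)
  expect_equal(as.data.frame(again), as.data.frame(mats))
})

test_that("malformed material tables fail with located errors", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("name,density,c_long", "water,1000,1480"), path)
  expect_error(load_material_table(path), "missing column")
  writeLines(c(
    "name,density,c_long,c_shear,alpha0_db_per_cm,f_ref_hz,alpha_exponent",
    "ghost,-5,1480,0,0,1e6,1"
  ), path)
  expect_error(load_material_table(path), "ghost")
  writeLines(c(
    "name,density,c_long,c_shear,alpha0_db_per_cm,f_ref_hz,alpha_exponent",
    "water,abc,1480,0,0,1e6,1"
  ), path)
  expect_error(load_material_table(path), "density")
  expect_error(load_material_table(withr::local_tempfile()), "not found")
})
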