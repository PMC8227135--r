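test_that("stack construction enforces the half-space layout", {
  w <- water0()
  expect_error(layer_stack(list(w), Inf), "two half-spaces")
  expect_error(layer_stack(list(w, w, w), c(Inf, Inf, Inf)), "half-space")
  expect_error(layer_stack(list(w, w, w), c(1e-3, 1e-3, Inf)), "half-space")
  expect_error(layer_stack(list(w, glass0(), w), c(Inf, -1e-3, Inf)), ">= 0")
  # zero-thickness interior layers are elided
  st <- layer_stack(list(w, glass0(), w), c(Inf, 0, Inf))
  expect_length(st$media, 2)
})

test_that("a bare interface reproduces the normal-incidence coefficients", {
  w <- water0()
  g <- glass0()
  st <- layer_stack(list(w, g), c(Inf, Inf))
  fld <- solve_normal(st, 1e6)
  expect_equal(fld$T_power, normal_coeffs(impedance(w), impedance(g))$Ti,
               tolerance = 1e-12)
  expect_equal(fld$T_power + fld$R_power, 1, tolerance = 1e-12)
  # backward amplitude in the final half-space is exactly zero
  expect_identical(fld$layers$p_up[2], 0 + 0i)
})

test_that("transfer matrix and brute-force oracle agree on the chamber stack", {
  # lossless fixture stack
  st <- chamber_stack0()
  a <- solve_normal(st, 1e6)
  b <- brute_force_five_layer(st, 1e6)
  expect_lt(rel_diff(c(a$layers$p_down, a$layers$p_up),
                     c(b$layers$p_down, b$layers$p_up)), 1e-10)
  # and on the shipped (attenuating) materials
  mats <- sono_materials()
  stl <- layer_stack(
    list(material(mats, "water"), material(mats, "glass"),
         material(mats, "water"), material(mats, "glass"),
         material(mats, "air")),
    c(Inf, 1.2e-3, 15e-6, 0.17e-3, Inf)
  )
  a2 <- solve_normal(stl, 1e6)
  b2 <- brute_force_five_layer(stl, 1e6)
  expect_lt(rel_diff(c(a2$layers$p_down, a2$layers$p_up),
                     c(b2$layers$p_down, b2$layers$p_up)), 1e-10)
})

test_that("identity layers leave the overall coefficients unchanged", {
  w <- water0()
  g <- glass0()
  base <- solve_normal(layer_stack(list(w, g, air0()), c(Inf, 1.2e-3, Inf)), 1e6)
  # an interior layer identical to both neighbours is acoustically absent
  padded <- solve_normal(
    layer_stack(list(w, w, g, air0()), c(Inf, 3.7e-4, 1.2e-3, Inf)), 1e6
  )
  expect_equal(Mod(padded$p_r), Mod(base$p_r), tolerance = 1e-12)
  expect_equal(padded$T_power, base$T_power, tolerance = 1e-12)
  # zero-thickness elision gives the limit of a vanishing layer
  thin <- solve_normal(
    layer_stack(list(w, glass0(), w, g, air0()), c(Inf, 1e-12, 0, 1.2e-3, Inf)), 1e6
  )
  expect_equal(thin$T_power, base$T_power, tolerance = 1e-6)
})

test_that("lossless transmission is reciprocal under stack reversal", {
  for (seed in 1:20) {
    st <- generate_random_stack(seed, 4)
    f <- 1e6 * (1 + (seed %% 5))
    fwd <- solve_normal(st, f)
    bwd <- solve_normal(reverse_stack(st), f)
    expect_equal(fwd$T_power, bwd$T_power, tolerance = 1e-10)
  }
})

test_that("an air-backed water-incident stack reflects almost everything", {
  fld <- solve_normal(chamber_stack0(), 1e6)
  expect_gt(fld$R_power, 0.99)
})

test_that("the oblique solver reduces to the normal solver at zero angle", {
  st <- chamber_stack0()
  a <- solve_oblique(st, 1e6, 0)
  b <- solve_normal(st, 1e6)
  expect_lt(rel_diff(c(a$layers$p_down, a$layers$p_up),
                     c(b$layers$p_down, b$layers$p_up)), 1e-10)
  expect_equal(a$T_power, b$T_power, tolerance = 1e-12)
  # continuity: a tiny angle changes nothing appreciably
  eps <- solve_oblique(st, 1e6, 1e-4)
  expect_equal(eps$T_power, b$T_power, tolerance = 1e-4)
})

test_that("the global matrix matches the fluid transfer matrix on all-fluid stacks", {
  f1 <- acoustic_medium("f1", 1000, 1480)
  f2 <- acoustic_medium("f2", 1200, 1700, alpha0_db_per_cm = 0.5)
  f3 <- acoustic_medium("f3", 900, 1100)
  st <- layer_stack(list(f1, f2, f3, f1), c(Inf, 0.8e-3, 0.3e-3, Inf))
  for (th in c(5, 20, 40, 55)) { # below the 60.5 deg critical angle of f2
    gm <- solve_oblique(st, 1e6, th)
    tm <- sonochamber:::fluid_oblique_tm(st, 1e6, th)
    expect_lt(Mod(gm$p_r - tm$r), 1e-10)
    expect_lt(Mod(gm$p_t - tm$t), 1e-10)
    expect_equal(gm$T_power, tm$T_power, tolerance = 1e-10)
  }
})

test_that("lossless elastic stacks conserve energy at any angle", {
  st <- chamber_stack0()
  for (th in c(0, 5, 14, 20, 26.5, 40, 60, 80)) {
    fld <- solve_oblique(st, 1e6, th)
    expect_lt(abs(fld$T_power + fld$R_power - 1), 1e-9)
  }
  # water-backed variant with real transmission through both branches
  st2 <- layer_stack(list(water0(), glass0(), water0()), c(Inf, 1.2e-3, Inf))
  for (th in c(5, 14, 20, 26.5, 40)) {
    fld <- solve_oblique(st2, 1e6, th)
    expect_lt(abs(fld$T_power + fld$R_power - 1), 1e-9)
    expect_gt(fld$T_power, 0)
  }
})

test_that("shear conversion transmits power between the two critical angles", {
  # between the longitudinal (15.3 deg) and shear (25.8 deg) critical angles
  # of water/glass, transmission survives through the shear branch only
  st <- layer_stack(list(water0(), glass0(), water0()), c(Inf, 1.2e-3, Inf))
  mid <- solve_oblique(st, 1e6, 20)
  expect_gt(mid$T_power, 1e-4)
})

test_that("the sample-gap sweep shows half-wavelength periodicity when lossless", {
  st <- chamber_stack0()
  half <- 1480 / 1e6 / 2 # lambda/2 in the water sample
  withr::with_seed(7, L <- runif(15, half, 2.5e-3))
  s1 <- sample_amplitude_vs_gap(st, L, 1e6)
  s2 <- sample_amplitude_vs_gap(st, L + half, 1e6)
  expect_equal(s2$amplitude_ratio, s1$amplitude_ratio, tolerance = 1e-9)
  expect_error(sample_amplitude_vs_gap(st, numeric(0), 1e6), "non-empty")
})

test_that("walls identical to the sample make the gap irrelevant", {
  # fully homogeneous medium: no reflections, unit amplitude at any gap
  w <- water0()
  st <- layer_stack(list(w, w, w, w, w), c(Inf, 1.2e-3, 15e-6, 0.17e-3, Inf))
  sw <- sample_amplitude_vs_gap(st, seq(10e-6, 1e-3, length.out = 25), 1e6)
  expect_lt(diff(range(sw$amplitude_ratio)), 1e-9)
  expect_equal(sw$amplitude_ratio[1], 1, tolerance = 1e-9)
  # with the air backing kept, the backing's standing wave is anchored at its
  # own interface: once the gap spans a half wavelength the in-gap peak
  # saturates and becomes gap-independent
  st2 <- layer_stack(list(w, w, w, w, air0()), c(Inf, 1.2e-3, 15e-6, 0.17e-3, Inf))
  sw2 <- sample_amplitude_vs_gap(st2, seq(740e-6, 2e-3, length.out = 25), 1e6)
  expect_lt(diff(range(sw2$amplitude_ratio)), 1e-9)
})

test_that("glass walls amplify the gap sensitivity relative to polystyrene", {
  L <- seq(1e-6, 740e-6, length.out = 149)
  eg <- diff(range(sample_amplitude_vs_gap(chamber_stack0(glass0()), L, 1e6)$amplitude_ratio))
  ep <- diff(range(sample_amplitude_vs_gap(chamber_stack0(polystyrene0()), L, 1e6)$amplitude_ratio))
  expect_gt(eg, ep)
})

test_that("attenuation power loss follows the exponential law", {
  mats <- sono_materials()
  g <- material(mats, "glass")
  expect_equal(power_loss_through(water0(), 0.01, 1e6), 0) # alpha = 0
  expect_lte(power_loss_through(g, 10e-3, 1e6), 0.05)
  d <- 3.7e-3
  s1 <- 1 - power_loss_through(g, d, 1e6)
  s2 <- 1 - power_loss_through(g, 2 * d, 1e6)
  expect_equal(s2, s1^2, tolerance = 1e-12)
  expect_error(power_loss_through(g, -1, 1e6), ">= 0")
})

test_that("random stacks are deterministic and leave the RNG alone", {
  a <- generate_random_stack(123, 5)
  b <- generate_random_stack(123, 5)
  expect_identical(a, b)
  expect_length(generate_random_stack(1, 2)$media, 2)
  withr::with_seed(99, {
    before <- .Random.seed
    invisible(generate_random_stack(5, 6))
    expect_identical(.Random.seed, before)
  })
  expect_error(generate_random_stack(1, 1), "n_layers")
})

test_that("the brute-force oracle honours its own limits", {
  w <- water0()
  st <- layer_stack(list(w, w, w, w, w), c(Inf, 1e-3, 1e-4, 1e-3, Inf))
  fld <- brute_force_five_layer(st, 1e6)
  expect_equal(Mod(fld$p_t), 1, tolerance = 1e-12)
  expect_lt(Mod(fld$p_r), 1e-12)
  # near-rigid backing reflects the full incident amplitude
  rigid <- acoustic_medium("rigid", 1e9, 6000)
  st2 <- layer_stack(list(w, w, w, w, rigid), c(Inf, 1e-3, 1e-4, 1e-3, Inf))
  expect_equal(Mod(brute_force_five_layer(st2, 1e6)$p_r), 1, tolerance = 1e-3)
  expect_error(brute_force_five_layer(layer_stack(list(w, w), c(Inf, Inf)), 1e6),
               "5 layers")
})

test_that("pressure profiles and field summaries are well-formed", {
  st <- chamber_stack0()
  fld <- solve_oblique(st, 1e6, 26.5)
  prof <- pressure_profile(fld, n_per_layer = 21)
  expect_true(all(prof$p_abs >= 0))
  expect_equal(sort(unique(prof$layer)), 1:5)
  td <- tidy(fld)
  expect_equal(nrow(td), 5)
  expect_true(all(c("p_down_abs", "psi_up_abs") %in% names(td)))
  gl <- glance(fld)
  expect_equal(gl$theta_i_deg, 26.5)
  expect_s3_class(autoplot(fld), "ggplot")
  expect_s3_class(autoplot(sample_amplitude_vs_gap(st, c(1e-5, 2e-5), 1e6)),
                  "ggplot")
})
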