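test_that("volume fractions match printed, derived and degenerate cases", {
  vf <- volume_fractions(fix_spray())
  expect_equal(sum(vf), 100, tolerance = 1e-8)
  expect_equal(round(vf[["isopropyl alcohol"]], 2), 25.17)

  single <- list(component("only", 1, 0.9))
  expect_equal(unname(volume_fractions(single)), 100)

  # equal masses, densities 1 and 2 g/ml: (1/1) / (1/1 + 1/2) = 2/3
  two <- list(component("a", 0.5, 1), component("b", 0.5, 2))
  expect_equal(unname(volume_fractions(two)), c(200 / 3, 100 / 3),
    tolerance = 1e-12)

  bad <- list(component("a", 0.5, 1), component("b", 0.5, 1))
  bad[[2L]]$density <- 0 # bypass the constructor check deliberately
  expect_error(volume_fractions(bad), "b")
})

test_that("mass and volume fractions are mutually inverse", {
  f <- fix_spray()
  vf <- volume_fractions(f)
  w <- mass_fractions_from_volume(vf, comp_field(f, "density"))
  expect_equal(unname(w), unname(comp_field(f, "mass_fraction")),
    tolerance = 1e-9)
})

test_that("mixture density reproduces printed values and degenerate case", {
  prim <- fix_spray()
  expect_equal(round(mixture_density(prim), 2), 0.83)
  expect_equal(round(mixture_density(derive_tertiary(prim)), 2), 0.85)
  # tertiary (volatiles removed, lighter components) is denser than primary
  expect_gt(mixture_density(derive_tertiary(prim)), mixture_density(prim))

  same <- list(component("a", 0.3, 1.1), component("b", 0.7, 1.1))
  expect_equal(mixture_density(same), 1.1, tolerance = 1e-14)
  expect_error(mixture_density(list()), "empty")
})

test_that("tertiary derivation renormalises the non-volatile components", {
  tert <- derive_tertiary(fix_spray())
  w <- 100 * comp_field(tert, "mass_fraction")
  names(w) <- comp_names(tert)
  expect_equal(round(w[["desoximetasone"]], 2), 0.33)
  expect_equal(round(w[["isopropyl myristate"]], 2), 40.96)
  expect_equal(round(w[["mineral oil"]], 2), 57.47)
  expect_equal(w[["isopropyl alcohol"]], 0)
  expect_equal(sum(w), 100, tolerance = 1e-9)

  # no volatile components: identity
  expect_equal(
    comp_field(derive_tertiary(fix_binary()), "mass_fraction"),
    comp_field(fix_binary(), "mass_fraction")
  )
  allvol <- formulation(
    list(component("solvent", 1, 0.8, volatile = TRUE)),
    viscosity = 1, api_solubility = 1, evaporation_rate = 1
  )
  expect_error(derive_tertiary(allvol), "volatile")
})

test_that("continuous-phase fractions renormalise the tertiary volumes", {
  tert <- derive_tertiary(fix_spray())
  cp <- continuous_phase_fractions(
    tert, c("mineral oil", "isopropyl myristate")
  )
  expect_equal(round(unname(cp), 2), c(58.39, 41.61))
  expect_equal(unname(continuous_phase_fractions(tert, "mineral oil")), 100)

  # three-member phase: renormalisation of the printed tertiary %v/v
  # column (57.64 / 41.08 / 1.00) gives 57.80 / 41.19 / 1.00
  cp3 <- continuous_phase_fractions(
    tert, c("mineral oil", "isopropyl myristate", "glyceryl oleate")
  )
  hand <- 100 * c(57.64, 41.08, 1.00) / sum(c(57.64, 41.08, 1.00))
  expect_equal(unname(cp3), hand, tolerance = 2e-3)

  expect_error(continuous_phase_fractions(tert, character()), "empty")
  expect_error(continuous_phase_fractions(tert, "petrolatum"), "unknown")
})

test_that("vehicle diffusivity follows Stokes-Einstein", {
  vm <- 376.46 / 1.3
  d100 <- vehicle_diffusivity(100, vm, 305.15)
  # frozen closed-form evaluation: r = 4.8601e-8 cm, D = 4.5989e-12 m^2/s
  expect_equal(d100, 1.65559e-4, tolerance = 1e-4)
  # inverse proportionality in viscosity, D * eta constant
  for (eta in c(1, 40, 1e4)) {
    expect_equal(vehicle_diffusivity(eta, vm) * eta,
      vehicle_diffusivity(1, vm), tolerance = 1e-12)
  }
  expect_equal(d100 / vehicle_diffusivity(1, vm, 305.15), 0.01,
    tolerance = 1e-12)
  expect_error(vehicle_diffusivity(-1, vm), "positive")
})

test_that("evaporation conserves API and saturates at the volatile cap", {
  f <- fix_spray() # 25.17 %v/v volatiles, 5 ml/h
  s0 <- formulation_state(f, volume = 5e-3)
  api0 <- s0$api_amount_dissolved

  # zero rate: state unchanged
  f0 <- fix_spray(evaporation_rate = 0)
  expect_equal(evaporation_step(s0, f0, dt = 3), s0)

  # closed form: complete volatile loss at t = fmax * V0 / rate
  t_done <- f$max_evaporated_fraction * s0$volume / f$evaporation_rate
  s1 <- evaporation_step(s0, f, dt = t_done)
  expect_equal(s1$evaporated_volume, f$max_evaporated_fraction * 5e-3,
    tolerance = 1e-12)
  # saturation beyond the cap; Table-2 numbers: 5 uL -> 3.7413 uL
  s2 <- evaporation_step(s1, f, dt = 100)
  expect_equal(s2$volume * 1e3, 3.7413, tolerance = 1e-4)
  expect_equal(s2$api_amount_dissolved, api0)
  expect_equal(s2$api_concentration, api0 / s2$volume)
  expect_equal(s2$api_concentration / s0$api_concentration, 5 / 3.7413,
    tolerance = 1e-4)
})

test_that("sprays convert to dose and back to sprays per area", {
  f <- fix_spray()
  d1 <- sprays_to_dose(1, f)
  expect_equal(d1$mass_mg, 2.4)
  # 0.25 %w/w of 2.4 mg (the printed column sums to 100.01%, so the
  # renormalised fraction is 0.249975%)
  expect_equal(d1$api_mg, 0.006, tolerance = 1e-3)
  d0 <- sprays_to_dose(0, f)
  expect_equal(unlist(d0), c(mass_mg = 0, volume_ml = 0, api_mg = 0))
  # the 5 uL / 0.5 cm2 Franz dose is ~3.5 sprays per cm2
  expect_equal(sprays_per_cm2(5, 0.5, f), 3.5, tolerance = 0.02)
})

test_that("formulation constructor validates and renormalises composition", {
  expect_error(
    formulation(list(component("a", 0.4, 1)), viscosity = 1,
      api_solubility = 1),
    "sum"
  )
  f <- fix_spray() # printed column sums to 100.01 %
  expect_equal(sum(comp_field(f, "mass_fraction")), 1, tolerance = 1e-12)
  expect_error(component("x", 0.1, -2), "density")
  expect_error(component("x", 1.2, 1), "mass_fraction")
  # default volatile cap equals the volatile volume fraction
  expect_equal(f$max_evaporated_fraction, 0.2517, tolerance = 1e-3)
})

test_that("composition report round-trips the derived quantities", {
  df <- formulation_report(fix_spray())
  expect_equal(nrow(df), 6L)
  dens <- attr(df, "mixture_density")
  expect_equal(round(unname(dens), 2), c(0.83, 0.85))
  ipa <- df[df$component == "isopropyl alcohol", ]
  expect_equal(round(ipa$primary_v_v_pct, 2), 25.17)
  expect_equal(ipa$tertiary_w_w_pct, 0)
})
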