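# Shared fixtures: everything is built in code, nothing is read from disk.

# internal accessors used throughout the tests
comp_field <- function(...) dermvbe:::comp_field(...)
comp_names <- function(...) dermvbe:::comp_names(...)

fix_compound <- function() desoximetasone()

fix_spray <- function(...) topicort_spray(...)

# a minimal two-component oil solution used where the six-component spray
# would only add noise to the arithmetic
fix_binary <- function(viscosity = 100, api_solubility = 0.5,
                       evaporation_rate = 0, max_evap = 0) {
  formulation(
    list(
      component("drug", 0.0025, 1.3, api = TRUE),
      component("oil", 0.9975, 0.85)
    ),
    viscosity = viscosity, api_solubility = api_solubility,
    max_evaporated_fraction = max_evap, evaporation_rate = evaporation_rate
  )
}

# analytic series-membrane permeability (water-referenced activity scale):
# 1/P = sum h_i / (K_i D_i); the discrete compartment chain must reproduce
# the corresponding steady-state flux
analytic_series_flux <- function(compound, formulation, physiology, area,
                                 donor_conc) {
  K_v <- formulation$api_solubility / compound$water_solubility
  a_v <- donor_conc / K_v
  h_sc <- physiology$sc_layer_thickness * 1e-4
  K_sc <- physiology$K_sclip_vehicle * K_v
  R <- physiology$n_sc_layers * h_sc / (K_sc * physiology$D_sclip) +
    physiology$viable_epidermis_thickness * 1e-4 /
      (physiology$K_ve_water * physiology$D_ve) +
    physiology$dermis_thickness * 1e-4 /
      (physiology$K_dermis_water * physiology$D_dermis)
  area * a_v / R
}

# simulated quasi-steady flux into the receptor under an effectively
# constant donor (huge well-stirred film, negligible vehicle resistance)
simulated_series_flux <- function(compound, formulation, physiology, area,
                                  donor_conc, t_end = 2000) {
  sys <- build_skin(compound, formulation, physiology,
    dose_api = donor_conc * 1000, dose_volume = 1000, area = area,
    mode = "ivpt"
  )
  res <- simulate_system(sys, t_end = t_end,
    t_eval = c(0, t_end - 50, t_end))
  rec <- res$amounts[, "receptor"]
  (rec[3L] - rec[2L]) / 50
}

receptor24 <- function(compound, formulation, physiology,
                       design = ivpt_design()) {
  r <- run_ivpt(compound, formulation, physiology, design)
  utils::tail(r$cumulative_receptor$cumulative_ug_cm2, 1L)
}

# per-value joint pass flags of a safe-space sweep result
sweep_pass <- function(sw, values) {
  vapply(values, function(v) all(sw$pass[sw$value == v]), TRUE)
}
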