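#' Define a formulation component
#'
#' One entry of the quantitative composition (Q2) of a topical formulation.
#'
#' @param name Component name.
#' @param mass_fraction Mass fraction of the total formulation (dimensionless;
#'   a %w/w value divided by 100).
#' @param density Component density (g/ml); must be positive.
#' @param volatile Logical; does this component evaporate during formulation
#'   metamorphosis?
#' @param api Logical; is this the active ingredient?
#'
#' @return An object of class `component`.
#' @export
component <- function(name, mass_fraction, density, volatile = FALSE,
                      api = FALSE) {
  if (!is.numeric(density) || length(density) != 1L || is.na(density) ||
    density <= 0) {
    stop("component '", name, "' must have a positive density")
  }
  if (mass_fraction < 0 || mass_fraction > 1) {
    stop("component '", name, "' mass_fraction must be in [0, 1]")
  }
  structure(
    list(
      name = name, mass_fraction = mass_fraction, density = density,
      volatile = isTRUE(volatile), api = isTRUE(api)
    ),
    class = "component"
  )
}

#' Define a formulation (Q2 composition plus Q3 attributes)
#'
#' A single-continuous-phase solution formulation: a list of components with
#' mass fractions and densities, plus the physical attributes that drive the
#' vehicle-side transport model (viscosity, drug solubility in the continuous
#' phase, evaporation kinetics).
#'
#' Mass fractions are renormalised to sum exactly to 1 when the supplied
#' values sum to 1 within 0.5% (printed compositions routinely sum to
#' e.g. 100.01%); renormalisation does not change any derived ratio
#' (densities, tertiary fractions, volume fractions).
#'
#' @param components List of [component()] objects.
#' @param viscosity Viscosity of the formulation (cP).
#' @param api_solubility Solubility of the API in the continuous (non-volatile)
#'   phase (mg/ml). The API concentration is allowed to exceed this value
#'   during metamorphosis; the excess is flagged as supersaturation but kept
#'   dissolved (no precipitation model).
#' @param max_evaporated_fraction Maximum fraction of the initial volume that
#'   can evaporate (dimensionless, %v/v volatiles / 100). Defaults to the
#'   volume fraction of the components flagged volatile.
#' @param evaporation_rate Zero-order evaporation rate (ml/h), interpreted per
#'   applied dose by default (see `evaporation_basis`).
#' @param molar_volume_cont_phase Molar volume of the continuous phase
#'   (cm^3/mol); stored as supplied, not recomputed (a mineral-oil mixture has
#'   no defined molar mass).
#' @param evaporation_basis Either `"per_dose"` (rate applies to the applied
#'   dose as a whole) or `"per_cm2"` (rate is multiplied by the application
#'   area). The literature value of 5 ml/h is consistent with near-instant
#'   volatile loss of a thin film under either reading; both are supported.
#'
#' @return An object of class `formulation`.
#' @seealso [topicort_spray()], [derive_tertiary()], [mixture_density()]
#' @export
formulation <- function(components, viscosity, api_solubility,
                        max_evaporated_fraction = NULL,
                        evaporation_rate = 5,
                        molar_volume_cont_phase = NA_real_,
                        evaporation_basis = c("per_dose", "per_cm2")) {
  evaporation_basis <- match.arg(evaporation_basis)
  if (!length(components)) stop("formulation needs at least one component")
  components <- lapply(components, function(x) {
    if (!inherits(x, "component")) stop("components must be 'component' objects")
    x
  })
  tot <- sum(vapply(components, `[[`, 0, "mass_fraction"))
  if (abs(tot - 1) > 5e-3) {
    stop(sprintf("mass fractions sum to %.4f, not 1", tot))
  }
  components <- lapply(components, function(x) {
    x$mass_fraction <- x$mass_fraction / tot
    x
  })
  stopifnot(viscosity > 0, api_solubility > 0)
  if (is.null(max_evaporated_fraction)) {
    vf <- volume_fractions(components) / 100
    max_evaporated_fraction <-
      sum(vf[vapply(components, `[[`, TRUE, "volatile")])
  }
  if (max_evaporated_fraction < 0 || max_evaporated_fraction > 1) {
    stop("max_evaporated_fraction must be in [0, 1]")
  }
  stopifnot(evaporation_rate >= 0)
  structure(
    list(
      components = components,
      viscosity = viscosity,
      api_solubility = api_solubility,
      # activity anchor of the vehicle phase; stays at the calibrated
      # reference value when a sweep modifies api_solubility
      solubility_anchor = api_solubility,
      max_evaporated_fraction = max_evaporated_fraction,
      evaporation_rate = evaporation_rate,
      molar_volume_cont_phase = molar_volume_cont_phase,
      evaporation_basis = evaporation_basis
    ),
    class = "formulation"
  )
}

comp_field <- function(components, field) {
  if (inherits(components, "formulation")) components <- components$components
  vapply(components, `[[`, vector(mode = "numeric", 1L), field)
}

comp_names <- function(components) {
  if (inherits(components, "formulation")) components <- components$components
  vapply(components, `[[`, "", "name")
}

comp_flag <- function(components, field) {
  if (inherits(components, "formulation")) components <- components$components
  vapply(components, `[[`, TRUE, field)
}

#' API mass fraction of a formulation
#'
#' @param x A [formulation()].
#' @return Mass fraction (dimensionless) of the component flagged as API.
#' @export
api_mass_fraction <- function(x) {
  w <- comp_field(x, "mass_fraction")
  sum(w[comp_flag(x, "api")])
}

#' Per-component volume fractions
#'
#' Converts mass fractions to volume percentages: each component's volume
#' contribution is `w_i / rho_i`, normalised over the mixture.
#'
#' @param components A list of [component()] objects or a [formulation()].
#' @return Named numeric vector of %v/v values summing to 100.
#' @export
#' @examples
#' volume_fractions(topicort_spray())[["isopropyl alcohol"]] # 25.17 %v/v
volume_fractions <- function(components) {
  if (inherits(components, "formulation")) components <- components$components
  if (!length(components)) stop("empty component list")
  w <- comp_field(components, "mass_fraction")
  rho <- comp_field(components, "density")
  bad <- rho <= 0
  if (any(bad)) {
    stop("zero or negative density for component: ",
      paste(comp_names(components)[bad], collapse = ", "))
  }
  v <- w / rho
  setNames(100 * v / sum(v), comp_names(components))
}

#' Recover mass fractions from volume fractions
#'
#' Inverse of [volume_fractions()]: `w_i = v_i * rho_i / sum(v_j * rho_j)`.
#'
#' @param volume_pct Named numeric vector of %v/v values.
#' @param densities Numeric vector of densities (g/ml) in the same order.
#' @return Mass fractions (dimensionless, summing to 1).
#' @export
mass_fractions_from_volume <- function(volume_pct, densities) {
  stopifnot(length(volume_pct) == length(densities), all(densities > 0))
  m <- volume_pct * densities
  setNames(m / sum(m), names(volume_pct))
}

#' Volume-weighted mixture density
#'
#' Density of an ideal mixture: total mass over total component volume,
#' `sum(w_i) / sum(w_i / rho_i)`.
#'
#' @inheritParams volume_fractions
#' @return Density in g/ml.
#' @export
#' @examples
#' round(mixture_density(topicort_spray()), 2) # 0.83
mixture_density <- function(components) {
  if (inherits(components, "formulation")) components <- components$components
  if (!length(components)) stop("empty component list")
  w <- comp_field(components, "mass_fraction")
  rho <- comp_field(components, "density")
  if (sum(w) <= 0) stop("total mass fraction is zero")
  sum(w) / sum(w / rho)
}

#' Derive the tertiary (post-metamorphosis) formulation
#'
#' Removes the volatile components and renormalises the remaining mass
#' fractions, keeping their relative proportions. Volatile components are
#' retained in the component list with mass fraction 0 so the composition
#' report keeps the full Q2 ledger. The tertiary formulation no longer
#' evaporates (`max_evaporated_fraction = 0`); viscosity and API solubility
#' refer to the continuous phase and are carried over unchanged.
#'
#' @param primary A [formulation()] describing the primary (in-container)
#'   composition.
#' @return A [formulation()] for the tertiary state.
#' @export
#' @examples
#' tert <- derive_tertiary(topicort_spray())
#' round(100 * api_mass_fraction(tert), 2) # 0.33 %w/w
derive_tertiary <- function(primary) {
  stopifnot(inherits(primary, "formulation"))
  vol <- comp_flag(primary, "volatile")
  w <- comp_field(primary, "mass_fraction")
  keep <- sum(w[!vol])
  if (keep <= 0) stop("all components are volatile; no tertiary formulation")
  comps <- lapply(primary$components, function(x) {
    x$mass_fraction <- if (x$volatile) 0 else x$mass_fraction / keep
    x
  })
  out <- primary
  out$components <- comps
  out$max_evaporated_fraction <- 0
  out
}

#' Normalised continuous-phase volume fractions
#'
#' Restricts the tertiary %v/v composition to the named phase members and
#' renormalises to 100%. Used to characterise the continuous phase when minor
#' components are neglected.
#'
#' @param tertiary A tertiary [formulation()] (see [derive_tertiary()]).
#' @param phase_members Character vector of component names making up the
#'   continuous phase.
#' @return Named numeric vector of %v/v values summing to 100.
#' @export
#' @examples
#' cp <- continuous_phase_fractions(
#'   derive_tertiary(topicort_spray()),
#'   c("mineral oil", "isopropyl myristate")
#' )
#' round(cp, 2) # 58.39 / 41.61
continuous_phase_fractions <- function(tertiary, phase_members) {
  if (!length(phase_members)) stop("empty phase member set")
  nm <- comp_names(tertiary)
  missing <- setdiff(phase_members, nm)
  if (length(missing)) {
    stop("unknown component(s): ", paste(missing, collapse = ", "))
  }
  v <- volume_fractions(tertiary)[phase_members]
  100 * v / sum(v)
}

#' Diffusivity of the API in the vehicle (Stokes-Einstein)
#'
#' `D = kB * T / (6 * pi * eta * r)` with the solute radius derived from its
#' molar volume (`r = (3 Vm / (4 pi NA))^(1/3)`). This makes vehicle-side
#' diffusion inversely proportional to viscosity, so the formulation film
#' becomes rate limiting only at extreme viscosities.
#'
#' @param viscosity Vehicle viscosity (cP).
#' @param molar_volume Solute molar volume (cm^3/mol), e.g. MW / density.
#' @param temperature Absolute temperature (K).
#' @return Diffusion coefficient in cm^2/h.
#' @export
vehicle_diffusivity <- function(viscosity, molar_volume, temperature = 305.15) {
  if (any(c(viscosity, molar_volume, temperature) <= 0)) {
    stop("viscosity, molar_volume and temperature must all be positive")
  }
  kB <- 1.380649e-23 # J/K
  NA_ <- 6.02214076e23 # 1/mol
  v_cm3 <- molar_volume / NA_ # molecular volume, cm^3
  r_m <- (3 * v_cm3 / (4 * pi))^(1 / 3) * 1e-2 # m
  eta <- viscosity * 1e-3 # Pa s
  d_si <- kB * temperature / (6 * pi * eta * r_m) # m^2/s
  d_si * 1e4 * 3600 # cm^2/h
}

#' Initialise the state of an applied formulation dose
#'
#' @param formulation A [formulation()].
#' @param volume Applied volume (ml).
#' @param api_amount API amount in the dose (mg); defaults to
#'   `volume * density * 1000 * api_mass_fraction`.
#' @return An object of class `formulation_state` with fields `volume` (ml),
#'   `api_amount_dissolved` (mg), `api_concentration` (mg/ml),
#'   `evaporated_volume` (ml), `initial_volume` (ml) and `supersaturated`.
#' @export
formulation_state <- function(formulation, volume, api_amount = NULL) {
  stopifnot(volume >= 0)
  if (is.null(api_amount)) {
    api_amount <- volume * mixture_density(formulation) * 1000 *
      api_mass_fraction(formulation)
  }
  conc <- if (volume > 0) api_amount / volume else 0
  structure(
    list(
      volume = volume,
      api_amount_dissolved = api_amount,
      api_concentration = conc,
      evaporated_volume = 0,
      initial_volume = volume,
      supersaturated = conc > formulation$api_solubility
    ),
    class = "formulation_state"
  )
}

#' Advance formulation metamorphosis by one time step
#'
#' Zero-order loss of volatile volume at `evaporation_rate`, saturating when
#' the evaporated volume reaches `max_evaporated_fraction` of the initial
#' volume. The API is non-volatile: its amount is conserved and its
#' concentration rises as the volume shrinks; supersaturation is flagged but
#' the drug is kept dissolved.
#'
#' @param state A [formulation_state()].
#' @param formulation The [formulation()] the state belongs to.
#' @param dt Time step (h), non-negative.
#' @param area Application area (cm^2); only used when the formulation's
#'   `evaporation_basis` is `"per_cm2"`.
#' @return Updated `formulation_state`.
#' @export
evaporation_step <- function(state, formulation, dt, area = 1) {
  stopifnot(dt >= 0)
  rate <- formulation$evaporation_rate
  if (identical(formulation$evaporation_basis, "per_cm2")) rate <- rate * area
  cap <- formulation$max_evaporated_fraction * state$initial_volume
  ev <- min(cap, state$evaporated_volume + rate * dt)
  state$evaporated_volume <- ev
  state$volume <- state$initial_volume - ev
  state$api_concentration <-
    if (state$volume > 0) state$api_amount_dissolved / state$volume else 0
  state$supersaturated <- state$api_concentration > formulation$api_solubility
  state
}

#' Convert a number of sprays into an applied dose
#'
#' @param n_sprays Number of sprays (non-negative; may be fractional).
#' @param formulation A [formulation()]; its density converts mass to volume.
#' @param per_spray_mass Deposited formulation mass per spray (mg); the
#'   reference product deposits approximately 2.4 mg per spray.
#' @return List with `mass_mg` (formulation), `volume_ml`, and `api_mg`.
#' @export
#' @examples
#' sprays_to_dose(1, topicort_spray())$api_mg # 0.006 mg DSM
sprays_to_dose <- function(n_sprays, formulation, per_spray_mass = 2.4) {
  stopifnot(n_sprays >= 0, per_spray_mass > 0)
  mass <- n_sprays * per_spray_mass
  list(
    mass_mg = mass,
    volume_ml = mass / 1000 / mixture_density(formulation),
    api_mg = mass * api_mass_fraction(formulation)
  )
}

#' Equivalent sprays per square centimetre of an applied volume
#'
#' Dose bookkeeping helper: converts an applied volume per area into the
#' equivalent number of sprays per cm^2 via the formulation density and the
#' per-spray deposited mass.
#'
#' @param dose_volume_ul Applied volume (microlitres).
#' @param area Application area (cm^2).
#' @inheritParams sprays_to_dose
#' @return Sprays per cm^2 (numeric).
#' @export
#' @examples
#' # the 5 uL / 0.5 cm2 Franz-cell dose is ~3.5 sprays per cm2
#' round(sprays_per_cm2(5, 0.5, topicort_spray()), 1)
sprays_per_cm2 <- function(dose_volume_ul, area, formulation,
                           per_spray_mass = 2.4) {
  stopifnot(dose_volume_ul >= 0, area > 0)
  mass <- dose_volume_ul / 1000 * mixture_density(formulation) * 1000
  mass / per_spray_mass / area
}

#' The reference 0.25% w/w corticosteroid spray formulation
#'
#' Quantitative composition of the reference desoximetasone spray: six
#' components with isopropyl alcohol as the single volatile; the continuous
#' phase is mineral oil / isopropyl myristate. Q3 attributes are assumptions
#' exposed as arguments: viscosity 100 cP, API solubility in the continuous
#' phase 0.55 mg/ml (the calibrated reference value; see the package
#' vignette), zero-order evaporation at 5 ml/h, and a continuous-phase molar
#' volume of 415.8 cm^3/mol taken as an input.
#'
#' @param viscosity Viscosity (cP).
#' @param api_solubility API solubility in the continuous phase (mg/ml).
#' @param evaporation_rate Evaporation rate (ml/h).
#' @return A [formulation()].
#' @export
topicort_spray <- function(viscosity = 100, api_solubility = 0.55,
                           evaporation_rate = 5) {
  formulation(
    components = list(
      component("desoximetasone", 0.0025, 1.3, api = TRUE),
      component("glyceryl oleate", 0.009, 1.0),
      component("isopropyl alcohol", 0.234, 0.774, volatile = TRUE),
      component("isopropyl myristate", 0.3138, 0.85),
      component("l-menthol", 0.0005, 0.89),
      component("mineral oil", 0.4403, 0.85)
    ),
    viscosity = viscosity,
    api_solubility = api_solubility,
    evaporation_rate = evaporation_rate,
    molar_volume_cont_phase = 415.8
  )
}

#' @export
print.formulation <- function(x, ...) {
  cat("<formulation>", length(x$components), "components\n")
  df <- formulation_report(x)
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf(
    "  viscosity %.4g cP | API solubility %.4g mg/ml | evap %.4g ml/h (max %.1f %%v/v)\n",
    x$viscosity, x$api_solubility, x$evaporation_rate,
    100 * x$max_evaporated_fraction
  ))
  invisible(x)
}

#' Composition report (primary and tertiary, %w/w and %v/v)
#'
#' @param primary A primary [formulation()].
#' @param path Optional path; when given the table is written as CSV.
#' @return A data frame with one row per component: densities, primary and
#'   tertiary mass and volume percentages, and the mixture densities as an
#'   attribute `mixture_density`.
#' @export
formulation_report <- function(primary, path = NULL) {
  tert <- if (any(comp_flag(primary, "volatile"))) {
    derive_tertiary(primary)
  } else {
    primary
  }
  df <- data.frame(
    component = comp_names(primary),
    density_g_ml = comp_field(primary, "density"),
    primary_w_w_pct = 100 * comp_field(primary, "mass_fraction"),
    tertiary_w_w_pct = 100 * comp_field(tert, "mass_fraction"),
    primary_v_v_pct = as.numeric(volume_fractions(primary)),
    tertiary_v_v_pct = as.numeric(volume_fractions(tert)),
    stringsAsFactors = FALSE
  )
  attr(df, "mixture_density") <- c(
    primary = mixture_density(primary),
    tertiary = mixture_density(tert)
  )
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
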