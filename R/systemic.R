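#' Minimal systemic disposition model
#'
#' A two-compartment systemic model standing in for whole-body PBPK
#' distribution. The central/peripheral volumes and inter-compartment
#' clearance are configuration parameters chosen to give a plausible terminal
#' half-life; bioequivalence ratios are insensitive to this choice because
#' test and reference arms share it (a property exercised by the test suite,
#' not an assumption).
#'
#' @param compound A [compound()]; supplies the elimination clearance.
#' @param central_volume Central volume of distribution (L).
#' @param peripheral_volume Peripheral volume (L).
#' @param intercompartment_clearance Distribution clearance (L/h).
#' @param clearance Elimination clearance (L/h); defaults to the compound's
#'   intravenous clearance.
#' @return An object of class `systemic_model`.
#' @export
systemic_model <- function(compound, central_volume = 40,
                           peripheral_volume = 60,
                           intercompartment_clearance = 20,
                           clearance = compound$clearance_iv) {
  stopifnot(
    central_volume > 0, peripheral_volume > 0,
    intercompartment_clearance > 0, clearance > 0
  )
  structure(
    list(
      central_volume = central_volume,
      peripheral_volume = peripheral_volume,
      intercompartment_clearance = intercompartment_clearance,
      clearance = clearance
    ),
    class = "systemic_model"
  )
}

#' Define a topical dosing schedule
#'
#' A sequence of application events on one skin site. Wear periods must not
#' overlap; each application is wiped off at the end of its duration (drug
#' already in the stratum corneum continues to absorb).
#'
#' @param start_h Numeric vector of application start times (h).
#' @param duration_h Wear duration of each application (h); scalar or vector.
#' @param n_sprays Sprays per application; scalar or vector.
#' @param area_cm2 Application area (cm^2); must be the same for all events.
#' @return An object of class `dosing_schedule` (a data frame).
#' @export
#' @examples
#' # twice-daily thin film: two 12-h applications on 50 cm2
#' dosing_schedule(c(0, 12), 12, n_sprays = 50, area_cm2 = 50)
dosing_schedule <- function(start_h, duration_h, n_sprays, area_cm2) {
  stopifnot(length(start_h) >= 1, all(duration_h > 0), all(n_sprays >= 0),
    length(area_cm2) == 1L, area_cm2 > 0)
  df <- data.frame(
    start_h = start_h,
    duration_h = rep_len(duration_h, length(start_h)),
    n_sprays = rep_len(n_sprays, length(start_h)),
    area_cm2 = area_cm2
  )
  df <- df[order(df$start_h), , drop = FALSE]
  if (nrow(df) > 1L) {
    ends <- df$start_h + df$duration_h
    if (any(df$start_h[-1L] < ends[-nrow(df)] - 1e-9)) {
      stop("overlapping applications in dosing schedule")
    }
  }
  class(df) <- c("dosing_schedule", class(df))
  df
}

#' Standard dose scenarios
#'
#' Four dose intensities on a 50 cm^2 site, two 12-h applications, 72-h
#' study: (1) low, 1 spray per 10 cm^2; (2) middle, 1 spray per 2 cm^2;
#' (3) default, 1 spray per cm^2; (4) the Franz-cell dose intensity of
#' approximately 3.5 sprays per cm^2.
#'
#' @param scenario Integer 1-4.
#' @param area_cm2 Application area (cm^2).
#' @return A [dosing_schedule()].
#' @export
dose_scenario <- function(scenario, area_cm2 = 50) {
  sprays_per_cm2 <- c(0.1, 0.5, 1, 3.5)[scenario]
  if (is.na(sprays_per_cm2)) stop("dose scenario must be 1, 2, 3 or 4")
  dosing_schedule(
    start_h = c(0, 12), duration_h = 12,
    n_sprays = sprays_per_cm2 * area_cm2, area_cm2 = area_cm2
  )
}

#' Simulate in-vivo pharmacokinetics after topical dosing
#'
#' Runs the layered skin model with restored in-vivo physiology (dermal
#' perfusion uptake) coupled to the systemic model, for a schedule of
#' application/removal events.
#'
#' @param compound A [compound()].
#' @param formulation A [formulation()].
#' @param physiology A [skin_physiology()].
#' @param dosing A [dosing_schedule()].
#' @param systemic A [systemic_model()]; defaults to
#'   `systemic_model(compound)`.
#' @param duration Study duration (h).
#' @param dt Output resolution (h).
#' @param temperature Skin surface temperature (K).
#' @return An object of class `in_vivo_result`: the [simulate_system()]
#'   result plus `profiles`, a data frame of plasma (mg/L) and dermis
#'   (mg/ml) concentrations over time.
#' @export
run_in_vivo <- function(compound, formulation, physiology, dosing,
                        systemic = NULL, duration = 72, dt = 0.5,
                        temperature = 305.15) {
  stopifnot(inherits(dosing, "dosing_schedule"))
  if (is.null(systemic)) systemic <- systemic_model(compound)
  area <- dosing$area_cm2[1L]
  doses <- lapply(dosing$n_sprays, sprays_to_dose, formulation = formulation)
  sys <- build_skin(
    compound, formulation, physiology,
    dose_api = doses[[1L]]$api_mg, dose_volume = doses[[1L]]$volume_ml,
    area = area, mode = "in_vivo", systemic = systemic,
    temperature = temperature
  )
  events <- do.call(rbind, lapply(seq_len(nrow(dosing)), function(i) {
    data.frame(
      time = c(dosing$start_h[i], dosing$start_h[i] + dosing$duration_h[i]),
      action = c("apply", "wipe"),
      api_mg = c(doses[[i]]$api_mg, 0),
      volume_ml = c(doses[[i]]$volume_ml, 0),
      stringsAsFactors = FALSE
    )
  }))
  events <- events[events$time <= duration, , drop = FALSE]
  t_eval <- seq(0, duration, by = dt)
  res <- simulate_system(sys, t_end = duration, t_eval = t_eval,
    events = events)
  dermis_vol <- area * physiology$dermis_thickness * 1e-4
  profiles <- rbind(
    data.frame(
      time_h = res$time, matrix = "plasma",
      concentration = res$amounts[, "central"] / systemic$central_volume
    ),
    data.frame(
      time_h = res$time, matrix = "dermis",
      concentration = res$amounts[, "dermis"] / dermis_vol
    )
  )
  structure(
    c(res, list(profiles = profiles, dosing = dosing)),
    class = c("in_vivo_result", "simulation_result")
  )
}

#' Fraction of the applied drug remaining in the formulation
#'
#' @param result An [run_in_vivo()] or [simulate_system()] result.
#' @param t Time (h); must lie within the simulated range.
#' @return Fraction in `[0, 1]` of the API applied up to `t` that is still in
#'   the formulation film.
#' @export
fraction_remaining <- function(result, t) {
  stopifnot(inherits(result, "simulation_result"), length(t) == 1L)
  if (t < min(result$time) - 1e-9 || t > max(result$time) + 1e-9) {
    stop("t is outside the simulated time range")
  }
  veh <- approx(result$time, result$amounts[, "vehicle"], xout = t)$y
  dosed <- approx(result$time, result$dosed, xout = t, method = "constant",
    f = 0)$y
  if (dosed <= 0) return(1)
  min(1, max(0, veh / dosed))
}

#' Tidy concentration profiles
#'
#' @param result An [run_in_vivo()] result.
#' @param subject Optional subject identifier added as a column.
#' @param path Optional CSV path.
#' @return Data frame `subject`, `time_h`, `matrix`, `concentration`.
#' @export
profiles_to_df <- function(result, subject = 1L, path = NULL) {
  df <- cbind(subject = subject, result$profiles)
  if (!is.null(path)) write.csv(df, path, row.names = FALSE)
  df
}
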