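# YAML configuration readers/writers.  The on-disk dialects are the ones
# emitted by make_fixture_suite(); every reader validates through the
# corresponding constructor so malformed files fail loudly.

formulation_to_list <- function(f) {
  list(
    components = lapply(f$components, function(x) {
      list(
        name = x$name, w_w_percent = 100 * x$mass_fraction,
        density_g_ml = x$density, volatile = x$volatile, api = x$api
      )
    }),
    q3 = list(
      viscosity_cP = f$viscosity,
      solubility_mg_ml = f$api_solubility,
      max_evaporated_pct_vv = 100 * f$max_evaporated_fraction,
      evaporation_rate_ml_h = f$evaporation_rate,
      molar_volume_cont_phase = f$molar_volume_cont_phase,
      evaporation_basis = f$evaporation_basis
    )
  )
}

#' Read a formulation definition file
#'
#' @param path YAML file with a `components` list (`name`, `w_w_percent`,
#'   `density_g_ml`, `volatile`, `api`) and a `q3` block (`viscosity_cP`,
#'   `solubility_mg_ml`, `max_evaporated_pct_vv`, `evaporation_rate_ml_h`,
#'   optional `molar_volume_cont_phase`, `evaporation_basis`).
#' @return A [formulation()].
#' @export
read_formulation <- function(path) {
  x <- yaml::read_yaml(path)
  comps <- lapply(x$components, function(cc) {
    component(
      cc$name, cc$w_w_percent / 100, cc$density_g_ml,
      volatile = isTRUE(cc$volatile), api = isTRUE(cc$api)
    )
  })
  q3 <- x$q3
  formulation(
    comps,
    viscosity = q3$viscosity_cP,
    api_solubility = q3$solubility_mg_ml,
    max_evaporated_fraction =
      if (!is.null(q3$max_evaporated_pct_vv)) {
        q3$max_evaporated_pct_vv / 100
      } else {
        NULL
      },
    evaporation_rate = q3$evaporation_rate_ml_h,
    molar_volume_cont_phase = q3$molar_volume_cont_phase %||% NA_real_,
    evaporation_basis = q3$evaporation_basis %||% "per_dose"
  )
}

#' Read a compound definition file
#'
#' @param path YAML file with the [compound()] fields.
#' @return A [compound()].
#' @export
read_compound <- function(path) {
  x <- yaml::read_yaml(path)
  compound(
    name = x$name, molecular_weight = x$molecular_weight, log_p = x$log_p,
    water_solubility = x$water_solubility,
    blood_plasma_ratio = x$blood_plasma_ratio, fu_plasma = x$fu_plasma,
    clearance_iv = x$clearance_iv, density = x$density %||% 1.2,
    compound_type = x$compound_type %||% "neutral"
  )
}

#' Read a skin physiology file
#'
#' @param path YAML file with [skin_physiology()] fields.
#' @return A [skin_physiology()].
#' @export
read_physiology <- function(path) {
  x <- yaml::read_yaml(path)
  keep <- intersect(names(x), names(formals(skin_physiology)))
  do.call(skin_physiology, x[keep])
}

#' Read an IVPT design file
#'
#' @param path YAML file with [ivpt_design()] fields.
#' @return An [ivpt_design()].
#' @export
read_ivpt_design <- function(path) {
  x <- yaml::read_yaml(path)
  keep <- intersect(names(x), names(formals(ivpt_design)))
  x$sampling_times <- unlist(x$sampling_times)
  do.call(ivpt_design, x[keep])
}

#' Read a dosing schedule file
#'
#' @param path YAML file with an `events` list of
#'   `{start_h, duration_h, n_sprays, area_cm2}`; or a file containing a
#'   list of dose scenarios, in which case `scenario` selects one.
#' @param scenario Optional scenario number when the file holds several.
#' @return A [dosing_schedule()].
#' @export
read_dosing_schedule <- function(path, scenario = NULL) {
  x <- yaml::read_yaml(path)
  if (!is.null(scenario)) {
    hit <- Filter(function(e) identical(e$scenario, as.integer(scenario)) ||
      identical(e$scenario, scenario), x)
    if (!length(hit)) stop("scenario ", scenario, " not found in ", path)
    x <- hit[[1L]]
  }
  ev <- x$events
  dosing_schedule(
    start_h = vapply(ev, `[[`, 0, "start_h"),
    duration_h = vapply(ev, `[[`, 0, "duration_h"),
    n_sprays = vapply(ev, `[[`, 0, "n_sprays"),
    area_cm2 = ev[[1L]]$area_cm2
  )
}

#' Path to a packaged example configuration file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return A file path (or a vector of file names).
#' @export
#' @examples
#' dermvbe_example()
#' read_compound(dermvbe_example("compound.yaml"))$clearance_iv
dermvbe_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "dermvbe")))
  }
  p <- system.file("extdata", file, package = "dermvbe")
  if (p == "") stop("no packaged file named ", file)
  p
}
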