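#' Simulate per-subject PK metrics for a cohort
#'
#' Runs the in-vivo model for every subject in a sampled population and
#' summarises each plasma and dermis concentration profile by
#' non-compartmental analysis.
#'
#' @param subjects A [sample_population()] data frame.
#' @param compound,formulation,physiology,dosing,systemic Model configuration
#'   shared by the cohort; per-subject multipliers are applied on top.
#' @param duration,dt Study duration and output resolution (h).
#' @return Data frame with one row per subject x matrix: `subject`, `matrix`,
#'   `cmax`, `auc_last`, `auc_inf`.
#' @export
simulate_cohort <- function(subjects, compound, formulation, physiology,
                            dosing, systemic = NULL, duration = 72,
                            dt = 0.5) {
  if (is.null(systemic)) systemic <- systemic_model(compound)
  rows <- vector("list", nrow(subjects) * 2L)
  for (i in seq_len(nrow(subjects))) {
    mods <- subject_models(subjects[i, ], physiology, systemic)
    res <- run_in_vivo(
      compound, formulation, mods$physiology, dosing,
      systemic = mods$systemic, duration = duration, dt = dt
    )
    for (mx in c("plasma", "dermis")) {
      pr <- res$profiles[res$profiles$matrix == mx, ]
      m <- nca(pr$time_h, pr$concentration)
      rows[[2L * (i - 1L) + match(mx, c("plasma", "dermis"))]] <- data.frame(
        subject = subjects$subject[i], matrix = mx,
        cmax = m$cmax, auc_last = m$auc_last, auc_inf = m$auc_inf,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Run a virtual bioequivalence trial
#'
#' Parallel-design trial of a test against a reference formulation on
#' virtual populations. With `paired = TRUE` both arms use the same subjects
#' (same seed), so all between-arm differences are formulation-driven and a
#' reference-vs-reference run returns a geometric mean ratio of exactly
#' 100%; with `paired = FALSE` the arms are sampled independently, which is
#' the configuration used for power analysis.
#'
#' @param compound A [compound()].
#' @param test_formulation,ref_formulation [formulation()] objects.
#' @param physiology Reference-arm [skin_physiology()].
#' @param dosing A [dosing_schedule()].
#' @param n Subjects per arm.
#' @param variability A [variability_spec()].
#' @param seed Integer seed.
#' @param paired Share the population between arms?
#' @param test_physiology Optional physiology for the test arm; used when a
#'   formulation change implies a partition-coefficient change (see
#'   [partition_from_solubility()]). Defaults to `physiology`.
#' @param systemic,duration,dt Passed to [simulate_cohort()].
#' @return List of class `vbe_trial` with elements `be` (a [be_assessment()]
#'   table), `test_metrics`, `ref_metrics`.
#' @export
run_vbe_trial <- function(compound, test_formulation, ref_formulation,
                          physiology, dosing, n = 40,
                          variability = variability_spec(), seed = 1L,
                          paired = FALSE, test_physiology = NULL,
                          systemic = NULL, duration = 72, dt = 0.5) {
  if (is.null(test_physiology)) test_physiology <- physiology
  ref_subjects <- sample_population(n, variability, seed = seed)
  test_subjects <- if (paired) {
    ref_subjects
  } else {
    sample_population(n, variability, seed = seed + 500009L)
  }
  ref_metrics <- simulate_cohort(
    ref_subjects, compound, ref_formulation, physiology, dosing,
    systemic = systemic, duration = duration, dt = dt
  )
  test_metrics <- simulate_cohort(
    test_subjects, compound, test_formulation, test_physiology, dosing,
    systemic = systemic, duration = duration, dt = dt
  )
  structure(
    list(
      be = be_assessment(test_metrics, ref_metrics),
      test_metrics = test_metrics,
      ref_metrics = ref_metrics
    ),
    class = "vbe_trial"
  )
}

#' @export
print.vbe_trial <- function(x, ...) {
  print(x$be)
  invisible(x)
}

#' Power analysis by reference-vs-reference simulation
#'
#' Replicates parallel trials of the reference formulation against itself
#' with independently sampled arms, for a grid of per-arm sample sizes, and
#' reports the fraction of trials in which the 90% CI lies within the
#' acceptance limits. A trial "shows BE" in a matrix when all three metrics
#' (Cmax, AUC_last, AUC_inf) pass jointly.
#'
#' @param compound,formulation,physiology,dosing Model configuration.
#' @param n_grid Per-arm sample sizes to test.
#' @param n_replicates Trials per sample size.
#' @param variability A [variability_spec()].
#' @param seed Integer seed; replicate seeds are derived from it.
#' @param systemic,duration,dt Passed to [simulate_cohort()].
#' @return List of class `power_result`: `per_metric` (pass fraction and
#'   mean CI bounds per n x matrix x metric) and `joint` (per n x matrix
#'   fraction of trials passing all metrics).
#' @export
power_analysis <- function(compound, formulation, physiology, dosing,
                           n_grid = c(10, 20, 40), n_replicates = 200,
                           variability = variability_spec(), seed = 1L,
                           systemic = NULL, duration = 72, dt = 0.5) {
  stopifnot(length(n_grid) >= 1)
  per <- list()
  joint <- list()
  counter <- 0L
  for (n in n_grid) {
    bes <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      counter <- counter + 1L
      tr <- run_vbe_trial(
        compound, formulation, formulation, physiology, dosing,
        n = n, variability = variability,
        seed = (seed + 104729L * counter) %% 2147483629L,
        paired = FALSE, systemic = systemic, duration = duration, dt = dt
      )
      bes[[r]] <- tr$be
    }
    all_be <- do.call(rbind, lapply(seq_along(bes), function(r) {
      cbind(replicate = r, as.data.frame(bes[[r]]))
    }))
    agg <- stats::aggregate(
      cbind(pass = all_be$pass, ci90_lower = all_be$ci90_lower,
        ci90_upper = all_be$ci90_upper),
      by = list(matrix = all_be$matrix, metric = all_be$metric),
      FUN = mean
    )
    agg$n <- n
    per[[length(per) + 1L]] <- agg
    jt <- stats::aggregate(
      list(pass_all = all_be$pass),
      by = list(replicate = all_be$replicate, matrix = all_be$matrix),
      FUN = all
    )
    jagg <- stats::aggregate(
      list(power = jt$pass_all),
      by = list(matrix = jt$matrix), FUN = mean
    )
    jagg$n <- n
    joint[[length(joint) + 1L]] <- jagg
  }
  structure(
    list(
      per_metric = do.call(rbind, per),
      joint = do.call(rbind, joint)
    ),
    class = "power_result"
  )
}

#' @export
print.power_result <- function(x, ...) {
  cat("<power_result> reference-vs-reference pass fractions\n")
  print(x$joint, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Derive a test formulation for a safe-space sweep
#'
#' Modifies one formulation parameter at a time. Changing the continuous
#' phase solubility also rescales the SC lipid : vehicle partition
#' coefficient via [partition_from_solubility()] (solubility acts on the
#' partitioning driving force); the other parameters leave the physiology
#' untouched.
#'
#' @param ref_formulation Reference [formulation()].
#' @param physiology Reference [skin_physiology()] (calibrated against the
#'   reference formulation).
#' @param parameter One of `"solubility"` (mg/ml), `"viscosity"` (cP),
#'   `"volatile_fraction"` (fraction of initial volume, 0-1),
#'   `"evaporation_rate"` (ml/h).
#' @param value New parameter value; must be physically admissible.
#' @return List with modified `formulation` and `physiology`.
#' @export
modify_formulation <- function(ref_formulation, physiology, parameter, value) {
  parameter <- match.arg(parameter, c(
    "solubility", "viscosity", "volatile_fraction", "evaporation_rate"
  ))
  f <- ref_formulation
  p <- physiology
  switch(parameter,
    solubility = {
      if (value <= 0) stop("solubility must be positive")
      p$K_sclip_vehicle <- partition_from_solubility(
        value, physiology$K_sclip_vehicle, ref_formulation$api_solubility
      )
      f$api_solubility <- value
    },
    viscosity = {
      if (value <= 0) stop("viscosity must be positive")
      f$viscosity <- value
    },
    volatile_fraction = {
      if (value < 0 || value > 1) stop("volatile fraction must be in [0, 1]")
      f$max_evaporated_fraction <- value
    },
    evaporation_rate = {
      if (value < 0) stop("evaporation rate must be non-negative")
      f$evaporation_rate <- value
    }
  )
  list(formulation = f, physiology = p)
}

#' Formulation safe-space sweep
#'
#' Varies one formulation parameter of the test product at a time across a
#' grid of values and assesses bioequivalence against the fixed reference.
#' Both arms share the same population (shared seed), so differences are
#' formulation-driven: at the reference value the geometric mean ratio is
#' exactly 100%.
#'
#' @param parameter,values Parameter to sweep (see [modify_formulation()])
#'   and its grid.
#' @param compound,ref_formulation,physiology,dosing Model configuration.
#' @param n Subjects per arm.
#' @param variability,seed Population sampling controls.
#' @param systemic,duration,dt Passed to [simulate_cohort()].
#' @return Data frame of class `safe_space_result`: one row per value x
#'   matrix x metric with the GMR, CI and pass flag.
#' @export
safe_space_sweep <- function(parameter, values, compound, ref_formulation,
                             physiology, dosing, n = 40,
                             variability = variability_spec(), seed = 1L,
                             systemic = NULL, duration = 72, dt = 0.5) {
  stopifnot(length(values) >= 1)
  if (is.null(systemic)) systemic <- systemic_model(compound)
  subjects <- sample_population(n, variability, seed = seed)
  ref_metrics <- simulate_cohort(
    subjects, compound, ref_formulation, physiology, dosing,
    systemic = systemic, duration = duration, dt = dt
  )
  out <- list()
  for (v in values) {
    mod <- modify_formulation(ref_formulation, physiology, parameter, v)
    test_metrics <- simulate_cohort(
      subjects, compound, mod$formulation, mod$physiology, dosing,
      systemic = systemic, duration = duration, dt = dt
    )
    be <- as.data.frame(be_assessment(test_metrics, ref_metrics))
    be$parameter <- parameter
    be$value <- v
    out[[length(out) + 1L]] <- be
  }
  res <- do.call(rbind, out)
  class(res) <- c("safe_space_result", class(res))
  res
}

#' Physiology x dose scenario matrix
#'
#' Crosses physiology scenarios (see [physiology_scenario()]) with dose
#' scenarios (see [dose_scenario()]) and, in each cell, assesses
#' bioequivalence of the formulation-parameter bound values against the
#' reference. Both arms are assigned the same physiology and population.
#'
#' @param scenarios Character vector of physiology scenarios (`"A"`-`"D"`).
#' @param dose_scenarios Integer vector of dose scenarios (1-4).
#' @param bounds Named list: for each swept parameter a vector of bound
#'   values, e.g. `list(solubility = c(0.4, 0.7))`.
#' @param compound,ref_formulation,base_physiology Model configuration; the
#'   base physiology must be the healthy, non-vasoconstricted state from
#'   which the scenarios are derived.
#' @param n,variability,seed Trial size and population controls.
#' @param systemic,duration,dt Passed to [simulate_cohort()].
#' @param area_cm2 Application area of every dose scenario.
#' @return Data frame: one row per scenario x dose x parameter x bound x
#'   matrix x metric, including the dose-normalised Cmax of both arms
#'   (`cmax_per_spray_test`, `cmax_per_spray_ref`, geometric means).
#' @export
scenario_matrix <- function(scenarios = c("A", "B", "C", "D"),
                            dose_scenarios = 1:4, bounds,
                            compound, ref_formulation,
                            base_physiology = skin_physiology(),
                            n = 40, variability = variability_spec(),
                            seed = 1L, systemic = NULL, duration = 72,
                            dt = 0.5, area_cm2 = 50) {
  stopifnot(is.list(bounds), length(bounds) >= 1, !is.null(names(bounds)))
  if (is.null(systemic)) systemic <- systemic_model(compound)
  subjects <- sample_population(n, variability, seed = seed)
  out <- list()
  for (sc in scenarios) {
    phys <- physiology_scenario(sc, base_physiology)
    for (ds in dose_scenarios) {
      dosing <- dose_scenario(ds, area_cm2 = area_cm2)
      n_sprays <- dosing$n_sprays[1L]
      ref_metrics <- simulate_cohort(
        subjects, compound, ref_formulation, phys, dosing,
        systemic = systemic, duration = duration, dt = dt
      )
      for (par in names(bounds)) {
        for (v in bounds[[par]]) {
          mod <- modify_formulation(ref_formulation, phys, par, v)
          test_metrics <- simulate_cohort(
            subjects, compound, mod$formulation, mod$physiology, dosing,
            systemic = systemic, duration = duration, dt = dt
          )
          be <- as.data.frame(be_assessment(test_metrics, ref_metrics))
          gm <- function(x) exp(mean(log(x)))
          cps_t <- vapply(split(test_metrics$cmax, test_metrics$matrix),
            gm, 0) / n_sprays
          cps_r <- vapply(split(ref_metrics$cmax, ref_metrics$matrix),
            gm, 0) / n_sprays
          be$scenario <- sc
          be$dose_scenario <- ds
          be$parameter <- par
          be$bound_value <- v
          be$cmax_per_spray_test <- cps_t[be$matrix]
          be$cmax_per_spray_ref <- cps_r[be$matrix]
          out[[length(out) + 1L]] <- be
        }
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("scenario_matrix_result", class(res))
  res
}
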