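#' Specification for synthetic IVPT observations
#'
#' Describes the "true" model and the replicate-level noise used to emulate
#' an observed Franz-cell dataset (cumulative receptor amounts over time plus
#' end-of-study epidermis/dermis amounts). Noise is applied multiplicatively
#' to the per-interval receptor increments, never to the cumulative levels,
#' so every synthetic replicate keeps a monotone cumulative profile. An
#' optional biased replicate emulates a divergent study that a calibration
#' may need to exclude.
#'
#' @param K_sclip_vehicle,P_cell True values of the two calibrated skin
#'   parameters.
#' @param n_replicates Number of replicates (>= 1).
#' @param noise_cv_receptor Lognormal CV applied to receptor increments.
#' @param noise_cv_local Lognormal CV applied to local amounts.
#' @param outlier_replicate Optional replicate index whose amounts are
#'   multiplied by `outlier_bias`.
#' @param outlier_bias Multiplicative bias of the outlier replicate.
#' @param seed Integer seed.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(K_sclip_vehicle = 2, P_cell = 0.02,
                       n_replicates = 5, noise_cv_receptor = 0.25,
                       noise_cv_local = 0.40, outlier_replicate = NULL,
                       outlier_bias = 3, seed = 1L) {
  stopifnot(
    n_replicates >= 1, noise_cv_receptor >= 0, noise_cv_local >= 0,
    K_sclip_vehicle > 0, P_cell >= 0
  )
  if (!is.null(outlier_replicate)) {
    stopifnot(outlier_replicate >= 1, outlier_replicate <= n_replicates)
  }
  structure(
    list(
      K_sclip_vehicle = K_sclip_vehicle, P_cell = P_cell,
      n_replicates = n_replicates,
      noise_cv_receptor = noise_cv_receptor,
      noise_cv_local = noise_cv_local,
      outlier_replicate = outlier_replicate,
      outlier_bias = outlier_bias,
      seed = seed
    ),
    class = "synth_spec"
  )
}

#' Generate a synthetic observed IVPT dataset
#'
#' Simulates the true model, then adds replicate-level lognormal noise to
#' the per-interval permeated increments and to the local amounts. The
#' output uses exactly the tabular formats consumed by [calibrate_ivpt()].
#'
#' @param spec A [synth_spec()].
#' @param design An [ivpt_design()].
#' @param compound,formulation,physiology Model configuration; the true
#'   parameters in `spec` override the physiology's values.
#' @param outdir Optional directory; when given, writes
#'   `ivpt_receptor.csv` and `ivpt_local.csv`.
#' @return List with `receptor` (replicate, time_h, cumulative_ug_cm2),
#'   `local` (replicate, compartment, amount_ug) and `truth` (the noise-free
#'   [run_ivpt()] result).
#' @export
generate_ivpt_observations <- function(spec, design, compound, formulation,
                                       physiology, outdir = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  p <- physiology
  p$K_sclip_vehicle <- spec$K_sclip_vehicle
  p$P_cell <- spec$P_cell
  truth <- run_ivpt(compound, formulation, p, design)

  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  times <- truth$cumulative_receptor$time_h
  cum <- truth$cumulative_receptor$cumulative_ug_cm2
  inc <- diff(c(0, cum))
  sd_r <- cv_to_sdlog(spec$noise_cv_receptor)
  sd_l <- cv_to_sdlog(spec$noise_cv_local)
  receptor <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    noisy <- inc * rlnorm(length(inc), 0, sd_r)
    data.frame(
      replicate = r, time_h = times, cumulative_ug_cm2 = cumsum(noisy)
    )
  }))
  local <- do.call(rbind, lapply(seq_len(spec$n_replicates), function(r) {
    data.frame(
      replicate = r,
      compartment = c("epidermis", "dermis"),
      amount_ug = c(
        truth$epidermis_amount_ug * rlnorm(1, 0, sd_l),
        truth$dermis_amount_ug * rlnorm(1, 0, sd_l)
      )
    )
  }))
  if (!is.null(spec$outlier_replicate)) {
    r <- spec$outlier_replicate
    i <- receptor$replicate == r
    receptor$cumulative_ug_cm2[i] <-
      receptor$cumulative_ug_cm2[i] * spec$outlier_bias
    j <- local$replicate == r
    local$amount_ug[j] <- local$amount_ug[j] * spec$outlier_bias
  }
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write.csv(receptor, file.path(outdir, "ivpt_receptor.csv"),
      row.names = FALSE)
    write.csv(local, file.path(outdir, "ivpt_local.csv"), row.names = FALSE)
  }
  list(receptor = receptor, local = local, truth = truth)
}

#' Write the packaged configuration fixture suite
#'
#' Emits the complete set of plain-text configuration files the pipeline
#' consumes: the compound parameters, the reference spray formulation
#' (composition plus Q3 assumptions), the four physiology scenario presets,
#' the four dose scenarios, the IVPT study design, and the derived
#' composition report. The same files ship with the package under
#' `inst/extdata`.
#'
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the vector of written file paths.
#' @export
make_fixture_suite <- function(outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  w <- function(x, name) {
    p <- file.path(outdir, name)
    yaml::write_yaml(x, p)
    paths <<- c(paths, p)
  }
  cmp <- desoximetasone()
  w(unclass(cmp), "compound.yaml")
  f <- topicort_spray()
  w(formulation_to_list(f), "topicort.yaml")
  for (sc in c("A", "B", "C", "D")) {
    w(unclass(physiology_scenario(sc)), paste0("physiology_", sc, ".yaml"))
  }
  dosing <- lapply(1:4, function(i) {
    d <- dose_scenario(i)
    list(
      scenario = i,
      events = lapply(seq_len(nrow(d)), function(j) {
        list(
          start_h = d$start_h[j], duration_h = d$duration_h[j],
          n_sprays = d$n_sprays[j], area_cm2 = d$area_cm2[j]
        )
      })
    )
  })
  w(dosing, "dosing_scenarios.yaml")
  w(unclass(ivpt_design()), "ivpt_design.yaml")
  rp <- file.path(outdir, "table_composition_report.csv")
  formulation_report(f, rp)
  paths <- c(paths, rp)
  invisible(paths)
}
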