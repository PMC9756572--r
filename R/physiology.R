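#' Define the skin physiology
#'
#' Parameters of the layered skin barrier and of dermal perfusion. The two
#' permeation parameters that are calibrated against IVPT data are
#' `K_sclip_vehicle` (stratum-corneum lipid : vehicle partition coefficient)
#' and `P_cell` (corneocyte, i.e. transcellular, permeability per SC layer,
#' referenced to the aqueous activity scale).
#'
#' The default healthy stratum corneum has 20 layers of 0.75 um (abdomen);
#' the diseased-skin scenarios halve the layer count to 10. Dermal blood flow
#' is `baseline_dermis_blood_flow * capillary_radius_scale^2 *
#' fraction_capillaries_perfused` (flow taken proportional to the capillary
#' cross-section, so a two-fold radius reduction gives the four-fold flow
#' reduction used for vasoconstriction; see [apply_vasoconstriction()]).
#'
#' @param n_sc_layers Number of stratum-corneum layers (>= 1).
#' @param sc_layer_thickness Thickness of one SC layer (um).
#' @param viable_epidermis_thickness Viable epidermis thickness (um).
#' @param dermis_thickness Dermis thickness (um).
#' @param K_sclip_vehicle SC lipid : vehicle partition coefficient
#'   (dimensionless). Calibrated against the receptor profile.
#' @param P_cell Corneocyte (transcellular) permeability per SC layer (cm/h,
#'   aqueous reference). Calibrated against local amounts.
#' @param D_sclip Effective diffusivity of the SC lipid pathway (cm^2/h).
#' @param f_sc_lipid Volume fraction of the SC occupied by the intercellular
#'   lipid phase; the remainder is corneocyte. Partitions SC storage between
#'   the vehicle-dependent lipid phase and the corneocyte phase.
#' @param K_corneocyte_water Corneocyte : water partition coefficient
#'   (storage only; transcellular transport is `P_cell`).
#' @param D_ve Diffusivity in the viable epidermis (cm^2/h).
#' @param D_dermis Diffusivity in the dermis (cm^2/h).
#' @param K_ve_water Viable epidermis : water partition coefficient.
#' @param K_dermis_water Dermis : water partition coefficient.
#' @param fu_dermis Fraction unbound in dermis.
#' @param capillary_radius_scale Multiplier on capillary radius
#'   (dimensionless, > 0).
#' @param fraction_capillaries_perfused Fraction of dermal capillaries
#'   perfused (0 < f <= 1).
#' @param baseline_dermis_blood_flow Dermal blood flow without
#'   vasoconstriction (ml/h/cm^2).
#' @param body_site Label for the application site.
#'
#' @return An object of class `skin_physiology`.
#' @seealso [physiology_scenario()] for the A-D presets,
#'   [apply_vasoconstriction()].
#' @export
skin_physiology <- function(n_sc_layers = 20,
                            sc_layer_thickness = 0.75,
                            viable_epidermis_thickness = 100,
                            dermis_thickness = 500,
                            K_sclip_vehicle = 2,
                            P_cell = 0.02,
                            D_sclip = 3.85e-7,
                            f_sc_lipid = 0.1,
                            K_corneocyte_water = 3,
                            D_ve = 8.3e-4,
                            D_dermis = 3.7e-3,
                            K_ve_water = 0.6,
                            K_dermis_water = 0.17,
                            fu_dermis = 0.054,
                            capillary_radius_scale = 1,
                            fraction_capillaries_perfused = 1,
                            baseline_dermis_blood_flow = 4,
                            body_site = "abdomen") {
  stopifnot(
    n_sc_layers >= 1, n_sc_layers == round(n_sc_layers),
    sc_layer_thickness > 0, viable_epidermis_thickness > 0,
    dermis_thickness > 0, K_sclip_vehicle >= 0, P_cell >= 0,
    D_sclip > 0, D_ve > 0, D_dermis > 0,
    f_sc_lipid > 0, f_sc_lipid <= 1, K_corneocyte_water >= 0,
    K_ve_water > 0, K_dermis_water > 0,
    fu_dermis > 0, fu_dermis <= 1,
    capillary_radius_scale > 0,
    fraction_capillaries_perfused > 0, fraction_capillaries_perfused <= 1,
    baseline_dermis_blood_flow >= 0
  )
  structure(
    list(
      n_sc_layers = as.integer(n_sc_layers),
      sc_layer_thickness = sc_layer_thickness,
      viable_epidermis_thickness = viable_epidermis_thickness,
      dermis_thickness = dermis_thickness,
      K_sclip_vehicle = K_sclip_vehicle,
      P_cell = P_cell,
      D_sclip = D_sclip,
      f_sc_lipid = f_sc_lipid,
      K_corneocyte_water = K_corneocyte_water,
      D_ve = D_ve,
      D_dermis = D_dermis,
      K_ve_water = K_ve_water,
      K_dermis_water = K_dermis_water,
      fu_dermis = fu_dermis,
      capillary_radius_scale = capillary_radius_scale,
      fraction_capillaries_perfused = fraction_capillaries_perfused,
      baseline_dermis_blood_flow = baseline_dermis_blood_flow,
      body_site = body_site
    ),
    class = "skin_physiology"
  )
}

#' Apply vasoconstriction scaling to dermal perfusion
#'
#' Corticosteroid-induced vasoconstriction narrows dermal capillaries and
#' de-recruits part of the capillary bed. Blood flow scales with the capillary
#' cross-sectional area, i.e. with the square of the radius scale, times the
#' perfused fraction: a radius scale of 0.5 gives a four-fold flow reduction,
#' and together with a perfused-fraction scale of 0.5 an eight-fold reduction.
#'
#' @param physiology A [skin_physiology()].
#' @param radius_scale Multiplier applied to `capillary_radius_scale` (> 0).
#' @param perfused_scale Multiplier applied to
#'   `fraction_capillaries_perfused` (> 0).
#' @return The modified `skin_physiology`.
#' @export
#' @examples
#' p <- skin_physiology()
#' pv <- apply_vasoconstriction(p, 0.5, 0.5)
#' dermis_blood_flow(p) / dermis_blood_flow(pv) # 8
apply_vasoconstriction <- function(physiology, radius_scale = 0.5,
                                   perfused_scale = 0.5) {
  stopifnot(inherits(physiology, "skin_physiology"),
    radius_scale > 0, perfused_scale > 0)
  physiology$capillary_radius_scale <-
    physiology$capillary_radius_scale * radius_scale
  physiology$fraction_capillaries_perfused <-
    min(1, physiology$fraction_capillaries_perfused * perfused_scale)
  physiology
}

#' Effective dermal blood flow
#'
#' @param physiology A [skin_physiology()].
#' @return Blood flow in ml/h/cm^2:
#'   `baseline * radius_scale^2 * fraction_perfused`.
#' @export
dermis_blood_flow <- function(physiology) {
  physiology$baseline_dermis_blood_flow *
    physiology$capillary_radius_scale^2 *
    physiology$fraction_capillaries_perfused
}

#' Physiology scenario presets
#'
#' Four scenarios used in the bioequivalence analyses:
#' \describe{
#'   \item{A}{default patient: vasoconstricted dermis (0.5x capillary radius
#'     and 0.5x fraction perfused, i.e. eight-fold flow reduction), 20 SC
#'     layers.}
#'   \item{B}{no vasoconstriction, 20 SC layers.}
#'   \item{C}{as A but 10 SC layers (reduced barrier, e.g. psoriatic skin).}
#'   \item{D}{as B but 10 SC layers.}
#' }
#'
#' @param scenario One of `"A"`, `"B"`, `"C"`, `"D"`.
#' @param base A [skin_physiology()] to start from (healthy,
#'   non-vasoconstricted).
#' @return A `skin_physiology`.
#' @export
physiology_scenario <- function(scenario = c("A", "B", "C", "D"),
                                base = skin_physiology()) {
  scenario <- match.arg(scenario)
  p <- base
  if (scenario %in% c("C", "D")) p$n_sc_layers <- 10L
  if (scenario %in% c("A", "C")) p <- apply_vasoconstriction(p, 0.5, 0.5)
  p$body_site <- paste0(p$body_site, " (scenario ", scenario, ")")
  p
}

#' @export
print.skin_physiology <- function(x, ...) {
  cat("<skin_physiology>", x$body_site, "\n")
  cat(sprintf(
    "  SC: %d x %.2f um | VE %.0f um | dermis %.0f um\n",
    x$n_sc_layers, x$sc_layer_thickness, x$viable_epidermis_thickness,
    x$dermis_thickness
  ))
  cat(sprintf(
    "  K_sclip:vehicle %.3g | P_cell %.3g cm/h | blood flow %.3g ml/h/cm2\n",
    x$K_sclip_vehicle, x$P_cell, dermis_blood_flow(x)
  ))
  invisible(x)
}
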