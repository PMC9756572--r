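#' Define a compound (active pharmaceutical ingredient)
#'
#' Physicochemical and pharmacokinetic parameters of the permeant. All
#' parameters are taken as inputs; nothing is predicted from structure.
#'
#' @param name Compound name.
#' @param molecular_weight Molecular weight (g/mol).
#' @param log_p Octanol:water log partition coefficient (dimensionless).
#' @param water_solubility Aqueous solubility (mg/ml). Used as the anchor for
#'   the thermodynamic-activity scale of all partition coefficients.
#' @param blood_plasma_ratio Blood:plasma concentration ratio (dimensionless).
#' @param fu_plasma Fraction unbound in plasma (dimensionless, 0-1).
#' @param clearance_iv Systemic (intravenous) clearance (L/h).
#' @param density Solid density of the compound (g/ml); used to derive the
#'   solute radius for Stokes-Einstein diffusivity.
#' @param compound_type Ionisation class; only `"neutral"` is supported.
#'
#' @return An object of class `compound`.
#' @seealso [desoximetasone()] for the built-in corticosteroid parameter set.
#' @export
#' @examples
#' dsm <- desoximetasone()
#' dsm$clearance_iv
compound <- function(name, molecular_weight, log_p, water_solubility,
                     blood_plasma_ratio, fu_plasma, clearance_iv,
                     density = 1.2, compound_type = "neutral") {
  stopifnot(
    molecular_weight > 0, water_solubility > 0, density > 0,
    blood_plasma_ratio > 0, fu_plasma > 0, fu_plasma <= 1,
    clearance_iv > 0
  )
  compound_type <- match.arg(compound_type, "neutral")
  structure(
    list(
      name = name,
      molecular_weight = molecular_weight,
      log_p = log_p,
      water_solubility = water_solubility,
      blood_plasma_ratio = blood_plasma_ratio,
      fu_plasma = fu_plasma,
      clearance_iv = clearance_iv,
      density = density,
      compound_type = compound_type
    ),
    class = "compound"
  )
}

#' Desoximetasone parameter set
#'
#' Desoximetasone (DSM) is the mid-potency topical corticosteroid used as the
#' worked example throughout this package (0.25% w/w spray formulation, see
#' [topicort_spray()]). Values are literature-reported inputs: MW 376.46
#' g/mol, logP 2.35, water solubility 0.0421 mg/ml, blood/plasma ratio 0.76,
#' fu plasma 0.145 and intravenous clearance 16.95 L/h.
#'
#' @return A [compound()] object.
#' @export
desoximetasone <- function() {
  compound(
    name = "desoximetasone",
    molecular_weight = 376.46,
    log_p = 2.35,
    water_solubility = 0.0421,
    blood_plasma_ratio = 0.76,
    fu_plasma = 0.145,
    clearance_iv = 16.95,
    density = 1.3
  )
}

#' @export
print.compound <- function(x, ...) {
  cat("<compound>", x$name, "\n")
  cat(sprintf(
    "  MW %.2f g/mol, logP %.2f, Sw %.4g mg/ml, CLiv %.2f L/h\n",
    x$molecular_weight, x$log_p, x$water_solubility, x$clearance_iv
  ))
  invisible(x)
}

# molar volume of the solute (cm^3/mol) from MW and solid density
solute_molar_volume <- function(compound) {
  compound$molecular_weight / compound$density
}
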