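## Modified Wilson expanded-liquid model.
##
## The supercritical phase is treated as an expanded liquid; because the
## solute is present at trace levels its activity coefficient is taken at
## infinite dilution.  The solubility is then the ideal solid solubility
## divided by that coefficient:
##   y2 = exp[(-dHf/R) (1/T - 1/Tm)] / gamma_inf
##   ln gamma_inf = 1 - L12 - ln L21
##   L12 = v2 * rho_cl * rho_r * exp(-lam12 / Tr)
##   L21 = exp(-lam21 / Tr) / (v2 * rho_cl * rho_r)
##   v2  = alpha * rho_r + beta        (solute molar volume, m^3/mol)
## with rho_r = rho / rho_c (mass basis), Tr = T / Tc of the solvent,
## rho_cl the solvent's critical molar density (mol/m^3), and lam12, lam21
## the interaction energies scaled by R*Tc (dimensionless).  rho_r is on
## the mass basis while v2*rho_cl is molar; this is the combination that
## leaves L12 and L21 dimensionless with alpha, beta in m^3/mol.

#' Wilson-model thermodynamic constants
#'
#' Fixed constants of the modified Wilson expanded-liquid model: the
#' solute's fusion enthalpy and melting point and the solvent's critical
#' temperature and densities.
#'
#' @param fusion_enthalpy Enthalpy of fusion of the solute (J/mol).  The
#'   default applies Walden's rule (fusion entropy 56.5 J/mol/K at the
#'   melting point) to the supplied melting temperature.
#' @param melting_T Solute melting point (K).
#' @param solvent A [solvent_properties()] object supplying the critical
#'   temperature and densities.
#' @return A list of class `"wilson_constants"`.
#' @export
wilson_constants <- function(melting_T = apz_properties()$melting_T,
                             fusion_enthalpy = 56.5 * melting_T,
                             solvent = co2_properties()) {
  stopifnot(fusion_enthalpy > 0, melting_T > 0)
  structure(list(fusion_enthalpy = fusion_enthalpy, melting_T = melting_T,
                 solvent_critical_T = solvent$critical_T,
                 solvent_critical_mass_density = solvent$critical_mass_density,
                 solvent_critical_molar_density = solvent$critical_molar_density,
                 gas_constant = R_GAS),
            class = "wilson_constants")
}

#' Ideal solubility of a solid solute
#'
#' Mole-fraction solubility of the solid in an ideal solution,
#' `exp[(-dHf/R) (1/T - 1/Tm)]`; equals 1 at the melting point and
#' decreases with subcooling.
#'
#' @param T_K Temperature (K), at or below the melting point.
#' @param constants A [wilson_constants()] object.
#' @return Ideal mole-fraction solubility in `(0, 1]`.
#' @export
ideal_solubility <- function(T_K, constants = wilson_constants()) {
  if (any(T_K <= 0)) stop("temperature must be positive")
  if (any(T_K > constants$melting_T))
    stop("ideal solid solubility is undefined above the melting point")
  exp((-constants$fusion_enthalpy / constants$gas_constant) *
        (1 / T_K - 1 / constants$melting_T))
}

#' Wilson interaction terms at infinite dilution
#'
#' Evaluates the density- and temperature-dependent Wilson terms
#' `Lambda_12` and `Lambda_21` (see the model notes above).  The solute
#' molar volume follows the linear reduced-density rule
#' `v2 = alpha * rho_r + beta` and must remain positive.
#'
#' @param params Named numeric vector with `lam12`, `lam21`
#'   (dimensionless) and `alpha`, `beta` (m^3/mol).
#' @param rho Fluid density (kg/m^3).
#' @param T_K Temperature (K).
#' @param constants A [wilson_constants()] object.
#' @return List with components `L12`, `L21`, `v2`, `rho_r`, `T_r`.
#' @export
wilson_lambdas <- function(params, rho, T_K,
                           constants = wilson_constants()) {
  if (any(rho <= 0) || any(T_K <= 0)) stop("rho and T must be positive")
  rho_r <- rho / constants$solvent_critical_mass_density
  T_r <- T_K / constants$solvent_critical_T
  v2 <- params[["alpha"]] * rho_r + params[["beta"]]
  if (any(v2 <= 0))
    stop("solute molar volume v2 = alpha*rho_r + beta must stay positive")
  g <- v2 * constants$solvent_critical_molar_density * rho_r
  list(L12 = g * exp(-params[["lam12"]] / T_r),
       L21 = exp(-params[["lam21"]] / T_r) / g,
       v2 = v2, rho_r = rho_r, T_r = T_r)
}

#' Infinite-dilution activity coefficient
#'
#' `gamma_inf = exp(1 - Lambda_12 - ln Lambda_21)`.
#'
#' @param L12,L21 Positive Wilson interaction terms.
#' @return Activity coefficient (positive).
#' @export
gamma_infinity <- function(L12, L21) {
  if (any(L12 <= 0) || any(L21 <= 0))
    stop("Wilson terms must be positive")
  exp(1 - L12 - log(L21))
}

#' Predict solubility with the modified Wilson model
#'
#' Chains the ideal solid solubility and the infinite-dilution activity
#' coefficient: `y2 = y2_ideal / gamma_inf`.
#'
#' @inheritParams wilson_lambdas
#' @return Mole-fraction predictions (positive).
#' @export
predict_y2_wilson <- function(params, T_K, rho,
                              constants = wilson_constants()) {
  lam <- wilson_lambdas(params, rho, T_K, constants)
  ideal_solubility(T_K, constants) / gamma_infinity(lam$L12, lam$L21)
}

## Vectorized, non-stopping Wilson prediction for the optimizer: returns
## NA where v2 <= 0 so the objective can penalize instead of erroring.
wilson_predict_safe <- function(par, T_K, rho, constants, fusion_enthalpy) {
  rho_r <- rho / constants$solvent_critical_mass_density
  T_r <- T_K / constants$solvent_critical_T
  v2 <- par[["alpha"]] * rho_r + par[["beta"]]
  g <- v2 * constants$solvent_critical_molar_density * rho_r
  bad <- v2 <= 0
  g[bad] <- NA_real_
  L12 <- g * exp(-par[["lam12"]] / T_r)
  L21 <- exp(-par[["lam21"]] / T_r) / g
  ideal <- exp((-fusion_enthalpy / constants$gas_constant) *
                 (1 / T_K - 1 / constants$melting_T))
  ideal / exp(1 - L12 - log(L21))
}
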