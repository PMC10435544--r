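## Density-based semi-empirical correlations.
##
## Each model regresses a transform of the solubility (its "fit space") on
## density, temperature and sometimes pressure:
##   chrastil   ln s        = a0 ln(rho) + a1 + a2/T
##   bartle     ln(y2 P/Pref) = a0 + a1 (rho - rho_ref) + a2/T
##   kj         ln s        = a0 + a1 rho + a2/T            (Kumar-Johnston)
##   mst        ln(y2 P)    = a0 + a1 rho + a2 T            (Mendez-Santiago-Teja)
##   sodeifian  ln y2       = a0 + (a1 + a2 rho) ln(rho) + a3/T + a4 ln(rho T)
##   jouyban    ln y2       = a0 + a1 rho + a2 P^2 + a3 P T + a4 T/P + a5 ln(rho)
## Units: T in K, P in MPa, rho in kg/m^3, s in g/L, y2 dimensionless.
##
## `n_coef` is the number of regression coefficients in the written formula;
## `z` is the parameter count used in the AARD denominator (the Sodeifian
## model is conventionally counted as a 6-parameter model although its
## written form carries 5 coefficients); `q` is the number of independent
## variables entering the adjusted correlation coefficient.

BARTLE_RHO_REF <- 700    # kg/m^3
BARTLE_P_REF <- 0.1      # MPa

model_registry <- function() {
  list(
    chrastil = list(id = "chrastil", label = "Chrastil", n_coef = 3L, z = 3L,
                    q = 2L, fit_space = "ln_s",
                    coef_names = c("a0", "a1", "a2")),
    bartle = list(id = "bartle", label = "Bartle et al.", n_coef = 3L, z = 3L,
                  q = 2L, fit_space = "ln_yP_over_Pref",
                  coef_names = c("a0", "a1", "a2")),
    kj = list(id = "kj", label = "Kumar-Johnston", n_coef = 3L, z = 3L,
              q = 2L, fit_space = "ln_s",
              coef_names = c("a0", "a1", "a2")),
    mst = list(id = "mst", label = "Mendez-Santiago-Teja", n_coef = 3L,
               z = 3L, q = 2L, fit_space = "ln_y2P",
               coef_names = c("a0", "a1", "a2")),
    sodeifian = list(id = "sodeifian", label = "Sodeifian et al.",
                     n_coef = 5L, z = 6L, q = 2L, fit_space = "ln_y2",
                     coef_names = c("a0", "a1", "a2", "a3", "a4")),
    jouyban = list(id = "jouyban", label = "Jouyban et al.", n_coef = 6L,
                   z = 6L, q = 3L, fit_space = "ln_y2",
                   coef_names = c("a0", "a1", "a2", "a3", "a4", "a5")),
    wilson = list(id = "wilson", label = "modified Wilson", n_coef = 4L,
                  z = 4L, q = 2L, fit_space = "y2",
                  coef_names = c("lam12", "lam21", "alpha", "beta"))
  )
}

#' List the available solubility correlation models
#'
#' @return Data frame with one row per model: id, label, number of fitted
#'   coefficients, parameter count `Z` used in the AARD denominator,
#'   independent-variable count `Q`, and the fit-space transform.
#' @export
solubility_models <- function() {
  reg <- model_registry()
  data.frame(
    id = vapply(reg, `[[`, "", "id"),
    label = vapply(reg, `[[`, "", "label"),
    n_coef = vapply(reg, `[[`, 0L, "n_coef"),
    z = vapply(reg, `[[`, 0L, "z"),
    q = vapply(reg, `[[`, 0L, "q"),
    fit_space = vapply(reg, `[[`, "", "fit_space"),
    row.names = NULL)
}

get_model <- function(model) {
  reg <- model_registry()
  if (!model %in% names(reg))
    stop("unknown model id: ", model, " (see solubility_models())")
  reg[[model]]
}

check_params <- function(def, params) {
  if (length(params) != def$n_coef)
    stop(sprintf("model %s expects %d coefficients, got %d",
                 def$id, def$n_coef, length(params)))
  if (any(!is.finite(params))) stop("coefficients must be finite")
  invisible(params)
}

## Regression design matrix in fit space (density models only).
model_design <- function(model, T_K, P_MPa, rho) {
  switch(model,
    chrastil = cbind(log(rho), 1, 1 / T_K),
    bartle = cbind(1, rho - BARTLE_RHO_REF, 1 / T_K),
    kj = cbind(1, rho, 1 / T_K),
    mst = cbind(1, rho, T_K),
    sodeifian = cbind(1, log(rho), rho * log(rho), 1 / T_K, log(rho * T_K)),
    jouyban = cbind(1, rho, P_MPa^2, P_MPa * T_K, T_K / P_MPa, log(rho)),
    stop("no linear fit-space design for model ", model))
}

## Experimental fit-space target values (what the design matrix regresses on).
model_target <- function(model, data, mst_classic = FALSE,
                         bartle_form = "conventional") {
  r <- data$records
  Ms <- data$solute$molar_mass; Mc <- data$solvent$molar_mass
  switch(model,
    chrastil = ,
    kj = log(s_from_y2(r$rho_kg_m3, r$y2, Ms, Mc)),
    bartle = log(r$y2 * r$P_MPa /
                 if (bartle_form == "conventional") BARTLE_P_REF
                 else BARTLE_RHO_REF),
    mst = if (mst_classic) r$T_K * log(r$y2 * r$P_MPa)
          else log(r$y2 * r$P_MPa),
    sodeifian = ,
    jouyban = log(r$y2),
    stop("no fit-space target for model ", model))
}

#' Evaluate a density model in its fit space
#'
#' Returns the model's left-hand-side value (e.g. `ln s` for Chrastil,
#' `ln(y2 P)` for Mendez-Santiago-Teja) at the given conditions.  All
#' arguments are vectorized over conditions.
#'
#' @param model Model id; one of `"chrastil"`, `"bartle"`, `"kj"`, `"mst"`,
#'   `"sodeifian"`, `"jouyban"`.
#' @param params Numeric coefficient vector of the model's length.
#' @param T_K Temperature (K).
#' @param P_MPa Pressure (MPa).
#' @param rho Density (kg/m^3).
#' @return Numeric vector of fit-space values.  For the MST model this is
#'   the shared right-hand side `a0 + a1 rho + a2 T`; whether it is read
#'   as `ln(y2 P)` or as `T ln(y2 P)` is decided by the back-transform in
#'   [predict_y2()].
#' @export
evaluate_model <- function(model, params, T_K, P_MPa, rho) {
  def <- get_model(model)
  if (def$id == "wilson")
    stop("use predict_y2_wilson() for the modified Wilson model")
  check_params(def, params)
  if (any(T_K <= 0) || any(P_MPa <= 0) || any(rho <= 0))
    stop("T, P and rho must be positive")
  drop(model_design(model, T_K, P_MPa, rho) %*% params)
}

#' Predict the mole-fraction solubility from a density model
#'
#' Back-transforms the fit-space value of [evaluate_model()] to the solute
#' mole fraction: models fitted on `ln s` go through the mass-solubility
#' conversion, the Bartle model divides out `P/P_ref`, MST divides out `P`,
#' and the `ln y2` models exponentiate directly.
#'
#' @inheritParams evaluate_model
#' @param solute_M,solvent_M Molar masses (g/mol), used by the `ln s`
#'   models.
#' @param mst_classic Read the MST right-hand side as the classic
#'   `T ln(y2 P)` (default) rather than the plain `ln(y2 P)`.
#' @param bartle_form `"conventional"` reads the Bartle left-hand side as
#'   `ln(y2 P / P_ref)` with `P_ref = 0.1` MPa (the default);
#'   `"literal"` reads it as `ln(y2 P / rho_ref)` exactly as typeset in
#'   some sources, with `rho_ref = 700`.
#' @return Mole-fraction predictions (positive).
#' @export
predict_y2 <- function(model, params, T_K, P_MPa, rho, solute_M, solvent_M,
                       mst_classic = TRUE,
                       bartle_form = c("conventional", "literal")) {
  bartle_form <- match.arg(bartle_form)
  v <- evaluate_model(model, params, T_K, P_MPa, rho)
  switch(model,
    chrastil = ,
    kj = y2_from_s(exp(v), rho, solute_M, solvent_M),
    bartle = if (bartle_form == "conventional") exp(v) * BARTLE_P_REF / P_MPa
             else exp(v) * BARTLE_RHO_REF / P_MPa,
    mst = if (mst_classic) exp(v / T_K) / P_MPa else exp(v) / P_MPa,
    sodeifian = ,
    jouyban = exp(v))
}
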