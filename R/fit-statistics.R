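#' Average absolute relative deviation (AARD%)
#'
#' The fit-quality statistic used to score every model:
#' `AARD% = 100/(N - Z) * sum(|y_calc - y_exp| / y_exp)`, where `Z` is the
#' model's adjustable-parameter count.  With `Z = 0` this is 100 times the
#' mean absolute relative error.
#'
#' @param y_exp Experimental values (positive).
#' @param y_calc Calculated values.
#' @param z Number of adjustable parameters subtracted from the record
#'   count in the denominator (default 0).
#' @return AARD in percent (non-negative).
#' @export
aard <- function(y_exp, y_calc, z = 0) {
  if (length(y_exp) != length(y_calc))
    stop("y_exp and y_calc must have equal length")
  if (any(y_exp <= 0)) stop("experimental values must be positive")
  n <- length(y_exp)
  if (n <= z) stop("need more records than adjustable parameters")
  100 / (n - z) * sum(abs(y_calc - y_exp) / y_exp)
}

#' Correlation coefficient of calculated vs experimental values
#'
#' Squared Pearson correlation on the linear mole-fraction scale.  Being a
#' correlation it is invariant to a uniform rescaling of the calculated
#' values; bias-sensitive agreement is assessed separately by
#' [self_consistency()].
#'
#' @param y_exp,y_calc Numeric vectors of equal length (>= 2).
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(y_exp, y_calc) {
  if (length(y_exp) != length(y_calc) || length(y_exp) < 2)
    stop("need two equal-length vectors of at least 2 values")
  if (stats::sd(y_exp) == 0 || stats::sd(y_calc) == 0)
    stop("correlation undefined for a constant vector")
  stats::cor(y_exp, y_calc)^2
}

#' Adjusted correlation coefficient
#'
#' `R_adj = sqrt(|R^2 - Q (1 - R^2) / (N - Q - 1)|)` with `N` records and
#' `Q` independent variables.
#'
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param n Number of records.
#' @param q Number of independent variables.
#' @return Adjusted correlation coefficient.
#' @export
r_adjusted <- function(r2, n, q) {
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]")
  if (n <= q + 1) stop("need n > q + 1 records")
  sqrt(abs(r2 - q * (1 - r2) / (n - q - 1)))
}

#' Enthalpies from the fitted temperature coefficients
#'
#' The Chrastil temperature coefficient satisfies `a2 = dH_total / R`, so
#' the total heat of the solute-solvent mixing process is `|a2| * R`; the
#' analogous Bartle coefficient yields the vaporization enthalpy; and by
#' Hess's law the solvation enthalpy is their difference.  Magnitudes are
#' reported with the positive-endothermic convention (the fitted `a2` is
#' negative because solubility rises with temperature at fixed density).
#'
#' @param a2 Fitted temperature coefficient (K).
#' @return Enthalpy in kJ/mol.
#' @export
enthalpy_total_from_chrastil <- function(a2) {
  if (!is.finite(a2)) stop("a2 must be finite")
  abs(a2) * R_GAS / 1000
}

#' @rdname enthalpy_total_from_chrastil
#' @export
enthalpy_vap_from_bartle <- function(a2) {
  if (!is.finite(a2)) stop("a2 must be finite")
  abs(a2) * R_GAS / 1000
}

#' @rdname enthalpy_total_from_chrastil
#' @param dH_total Total mixing enthalpy (kJ/mol).
#' @param dH_vap Vaporization enthalpy (kJ/mol).
#' @export
enthalpy_solvation <- function(dH_total, dH_vap) {
  if (!is.finite(dH_total) || !is.finite(dH_vap))
    stop("enthalpies must be finite")
  dH_total - dH_vap
}

#' Enthalpy summary from a collection of fits
#'
#' Extracts the total mixing enthalpy from the Chrastil fit and the
#' vaporization enthalpy from the Bartle fit in a [fit_all_models()]
#' result, and forms the solvation enthalpy by Hess's law.
#'
#' @param fits A `"solubility_fitlist"` containing at least the
#'   `"chrastil"` and `"bartle"` fits.
#' @return List of class `"enthalpy_summary"` with `dH_total`, `dH_vap`
#'   and `dH_sol` (kJ/mol) and the raw fitted `a2` coefficients.
#' @export
enthalpies <- function(fits) {
  ids <- vapply(fits, function(f) f$model, "")
  if (!all(c("chrastil", "bartle") %in% ids))
    stop("enthalpies() needs both the chrastil and bartle fits")
  a2_c <- stats::coef(fits[[which(ids == "chrastil")]])[["a2"]]
  a2_b <- stats::coef(fits[[which(ids == "bartle")]])[["a2"]]
  dH_total <- enthalpy_total_from_chrastil(a2_c)
  dH_vap <- enthalpy_vap_from_bartle(a2_b)
  structure(list(dH_total = dH_total, dH_vap = dH_vap,
                 dH_sol = enthalpy_solvation(dH_total, dH_vap),
                 a2_chrastil = a2_c, a2_bartle = a2_b),
            class = "enthalpy_summary")
}

#' @export
print.enthalpy_summary <- function(x, ...) {
  cat("Enthalpies of the solute-solvent system (kJ/mol)\n")
  cat(sprintf("  total mixing (Chrastil a2):  %8.2f\n", x$dH_total))
  cat(sprintf("  vaporization (Bartle a2):    %8.2f\n", x$dH_vap))
  cat(sprintf("  solvation (Hess's law):      %8.2f\n", x$dH_sol))
  invisible(x)
}
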