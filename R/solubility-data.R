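#' @keywords internal
"_PACKAGE"

## Universal gas constant, J mol^-1 K^-1
R_GAS <- 8.314462

#' Solute physical properties
#'
#' Bundle of the solid solute's physical and critical constants used by the
#' expanded-liquid model and for documentation of the system.  Temperatures
#' are in K, pressures in bar, the molar mass in g/mol and the solid molar
#' volume in cm^3/mol.
#'
#' @param name Solute name.
#' @param molar_mass Molar mass (g/mol).
#' @param melting_T Melting temperature (K).
#' @param boiling_T Normal boiling temperature (K).
#' @param critical_T Critical temperature (K).
#' @param critical_P Critical pressure (bar).
#' @param acentric_factor Pitzer acentric factor (dimensionless).
#' @param molar_volume Solid molar volume (cm^3/mol).
#' @param sublimation_P Optional named numeric vector of sublimation
#'   pressures (bar) keyed by temperature (K).
#' @return An object of class `"solute_properties"`.
#' @export
solute_properties <- function(name, molar_mass, melting_T, boiling_T,
                              critical_T, critical_P, acentric_factor,
                              molar_volume, sublimation_P = NULL) {
  num <- c(molar_mass = molar_mass, melting_T = melting_T,
           boiling_T = boiling_T, critical_T = critical_T,
           critical_P = critical_P, acentric_factor = acentric_factor,
           molar_volume = molar_volume)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all solute properties must be positive and finite")
  if (!(melting_T < boiling_T && boiling_T < critical_T))
    stop("solute temperatures must satisfy melting_T < boiling_T < critical_T")
  structure(list(name = name, molar_mass = molar_mass, melting_T = melting_T,
                 boiling_T = boiling_T, critical_T = critical_T,
                 critical_P = critical_P, acentric_factor = acentric_factor,
                 molar_volume = molar_volume, sublimation_P = sublimation_P),
            class = "solute_properties")
}

#' Solvent physical properties
#'
#' The supercritical solvent's constants.  The molar critical density is
#' derived from the mass critical density and checked for consistency if
#' supplied explicitly.
#'
#' @param name Solvent name.
#' @param molar_mass Molar mass (g/mol).
#' @param critical_T Critical temperature (K).
#' @param critical_P Critical pressure (bar).
#' @param critical_mass_density Critical density (kg/m^3).
#' @param critical_molar_density Optional critical molar density (mol/m^3);
#'   computed from the mass density when omitted.
#' @return An object of class `"solvent_properties"`.
#' @export
solvent_properties <- function(name, molar_mass, critical_T, critical_P,
                               critical_mass_density,
                               critical_molar_density = NULL) {
  num <- c(molar_mass, critical_T, critical_P, critical_mass_density)
  if (any(!is.finite(num)) || any(num <= 0))
    stop("all solvent properties must be positive and finite")
  derived <- critical_mass_density / molar_mass * 1000
  if (is.null(critical_molar_density)) {
    critical_molar_density <- derived
  } else if (abs(critical_molar_density - derived) / derived > 1e-3) {
    stop("critical_molar_density inconsistent with critical_mass_density/molar_mass")
  }
  structure(list(name = name, molar_mass = molar_mass,
                 critical_T = critical_T, critical_P = critical_P,
                 critical_mass_density = critical_mass_density,
                 critical_molar_density = critical_molar_density),
            class = "solvent_properties")
}

#' Bundled aripiprazole and carbon dioxide properties
#'
#' Constants for the aripiprazole / CO2 binary system shipped with the
#' package (melting point from DSC, remaining solute constants from
#' group-contribution estimates).
#'
#' @return `apz_properties()` a [solute_properties()] object;
#'   `co2_properties()` a [solvent_properties()] object.
#' @export
apz_properties <- function() {
  y <- yaml::read_yaml(system.file("extdata", "aripiprazole_properties.yaml",
                                   package = "scsolub", mustWork = TRUE))
  subl <- unlist(y$sublimation_P)
  solute_properties(name = y$name, molar_mass = y$molar_mass,
                    melting_T = y$melting_T, boiling_T = y$boiling_T,
                    critical_T = y$critical_T, critical_P = y$critical_P,
                    acentric_factor = y$acentric_factor,
                    molar_volume = y$molar_volume, sublimation_P = subl)
}

#' @rdname apz_properties
#' @export
co2_properties <- function() {
  y <- yaml::read_yaml(system.file("extdata", "co2_properties.yaml",
                                   package = "scsolub", mustWork = TRUE))
  solvent_properties(name = y$name, molar_mass = y$molar_mass,
                     critical_T = y$critical_T, critical_P = y$critical_P,
                     critical_mass_density = y$critical_mass_density,
                     critical_molar_density = y$critical_molar_density)
}

#' Mole fraction from a dynamic sampling measurement
#'
#' Converts a spectrophotometric concentration measured in the collection
#' vial into the solute mole fraction in the saturated fluid phase:
#' `n_solute = C_s * V_vial / M_solute`, `n_solvent = V_loop * rho / M_solvent`,
#' `y2 = n_solute / (n_solute + n_solvent)`.
#'
#' @param C_s Solute concentration in the vial (g/L).
#' @param V_vial Vial (sampling) volume (L).
#' @param V_loop Injection-loop volume (L).
#' @param rho Fluid density at sampling conditions (kg/m^3); numerically
#'   equal to g/L so the mole ratio is unit-consistent.
#' @param solute_M,solvent_M Molar masses (g/mol).
#' @return Mole fraction of the solute, in `[0, 1)`.
#' @export
mole_fraction_from_sampling <- function(C_s, V_vial, V_loop, rho,
                                        solute_M, solvent_M) {
  if (any(c(V_vial, V_loop, rho, solute_M, solvent_M) <= 0) || C_s < 0)
    stop("sampling inputs must be positive (C_s may be zero)")
  n_solute <- C_s * V_vial / solute_M
  n_solvent <- V_loop * rho / solvent_M
  n_solute / (n_solute + n_solvent)
}

#' Convert between mole fraction and mass solubility
#'
#' `s_from_y2()` evaluates the equilibrium mass solubility
#' `S = rho * M_solute * y2 / (M_solvent * (1 - y2))` in g/L;
#' `y2_from_s()` is its exact algebraic inverse.
#'
#' @param rho Fluid density (kg/m^3).
#' @param y2 Solute mole fraction, in `[0, 1)`.
#' @param S Mass solubility (g/L), non-negative.
#' @param solute_M,solvent_M Molar masses (g/mol).
#' @return `s_from_y2()`: solubility in g/L; `y2_from_s()`: mole fraction.
#' @export
s_from_y2 <- function(rho, y2, solute_M, solvent_M) {
  if (any(rho <= 0)) stop("rho must be positive")
  if (any(y2 < 0 | y2 >= 1)) stop("y2 must lie in [0, 1)")
  rho * solute_M * y2 / (solvent_M * (1 - y2))
}

#' @rdname s_from_y2
#' @export
y2_from_s <- function(S, rho, solute_M, solvent_M) {
  if (any(S < 0)) stop("S must be non-negative")
  if (any(rho <= 0)) stop("rho must be positive")
  S * solvent_M / (rho * solute_M + S * solvent_M)
}

#' Expanded uncertainty of a solubility measurement
#'
#' Combines the relative standard uncertainties of the mole fraction (via
#' the standard deviation of the mean), temperature and pressure in
#' quadrature, each weighted by a sensitivity power, and multiplies by the
#' coverage factor:
#' `U = k * y * sqrt(sum((P_i * u(x_i)/x_i)^2))`.
#'
#' @param sd_y Standard deviation of the mean mole fraction.
#' @param y Mole fraction.
#' @param u_T Standard uncertainty of temperature (K).
#' @param T_K Temperature (K).
#' @param u_P Standard uncertainty of pressure (bar).
#' @param P_bar Pressure (bar).
#' @param coverage_k Coverage factor (default 2, ~95% confidence).
#' @param powers Sensitivity powers for (y, T, P); default all 1.
#' @return Expanded uncertainty on the mole-fraction scale.
#' @export
expanded_uncertainty <- function(sd_y, y, u_T, T_K, u_P, P_bar,
                                 coverage_k = 2, powers = c(1, 1, 1)) {
  if (coverage_k <= 0) stop("coverage_k must be positive")
  if (any(c(sd_y, u_T, u_P) < 0)) stop("uncertainties must be non-negative")
  x <- c(y, T_K, P_bar)
  if (any(x == 0)) stop("input estimates must be non-zero")
  if (length(powers) != 3) stop("powers must have one entry per input (y, T, P)")
  rel <- powers * c(sd_y, u_T, u_P) / x
  coverage_k * y * sqrt(sum(rel^2))
}

## Collect validation issues for a record table; character(0) when valid.
validate_records <- function(df, solute, solvent, check_s = TRUE,
                             s_tol = 0.01) {
  issues <- character(0)
  req <- c("T_K", "P_MPa", "rho_kg_m3", "y2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  for (col in intersect(c(req, "sd_y2", "U_y2", "S_gL"), names(df))) {
    if (!is.numeric(df[[col]]))
      issues <- c(issues, sprintf("column %s is not numeric", col))
  }
  if (length(issues)) return(issues)
  bad <- which(!is.finite(df$T_K) | df$T_K <= 0)
  if (length(bad)) issues <- c(issues,
    sprintf("row %d: temperature must be positive", bad))
  bad <- which(!is.finite(df$P_MPa) | df$P_MPa <= 0)
  if (length(bad)) issues <- c(issues,
    sprintf("row %d: pressure must be positive", bad))
  bad <- which(!is.finite(df$rho_kg_m3) | df$rho_kg_m3 <= 0)
  if (length(bad)) issues <- c(issues,
    sprintf("row %d: density must be positive", bad))
  bad <- which(!is.finite(df$y2) | df$y2 <= 0 | df$y2 >= 1)
  if (length(bad)) issues <- c(issues,
    sprintf("row %d: y2 must lie strictly between 0 and 1", bad))
  dup <- duplicated(df[c("T_K", "P_MPa")])
  if (any(dup)) issues <- c(issues,
    sprintf("row %d: duplicate (T, P) condition", which(dup)))
  if (check_s && "S_gL" %in% names(df) && !length(issues)) {
    s_calc <- s_from_y2(df$rho_kg_m3, df$y2,
                        solute$molar_mass, solvent$molar_mass)
    rel <- abs(s_calc - df$S_gL) / s_calc
    bad <- which(rel > s_tol)
    if (length(bad)) issues <- c(issues,
      sprintf("row %d: S column disagrees with rho/y2 conversion by %.2f%%",
              bad, 100 * rel[bad]))
  }
  issues
}

#' Construct a validated solubility dataset
#'
#' Bundles a table of equilibrium solubility records with the solute and
#' solvent constants.  Records require columns `T_K`, `P_MPa`, `rho_kg_m3`
#' and `y2`; optional columns are `sd_y2`, `U_y2` and `S_gL`.  Validation
#' enforces positivity, `0 < y2 < 1`, no duplicated (T, P) conditions and —
#' when an `S_gL` column is present — agreement of the printed mass
#' solubility with the mole-fraction conversion to within `s_tol` relative.
#'
#' @param records Data frame of solubility records.
#' @param solute A [solute_properties()] object.
#' @param solvent A [solvent_properties()] object.
#' @param check_s Verify the `S_gL` column against the conversion from
#'   `(rho, y2)` when present.
#' @param s_tol Relative tolerance for that check (default 1%).
#' @return An object of class `"solubility_data"`.
#' @export
solubility_data <- function(records, solute = apz_properties(),
                            solvent = co2_properties(), check_s = TRUE,
                            s_tol = 0.01) {
  stopifnot(is.data.frame(records))
  records <- as.data.frame(records)
  issues <- validate_records(records, solute, solvent, check_s, s_tol)
  if (length(issues))
    stop("invalid solubility records:\n  ", paste(issues, collapse = "\n  "))
  num_cols <- intersect(c("T_K", "P_MPa", "rho_kg_m3", "y2", "sd_y2",
                          "U_y2", "S_gL"), names(records))
  records[num_cols] <- lapply(records[num_cols], as.numeric)
  rownames(records) <- NULL
  structure(list(records = records, solute = solute, solvent = solvent),
            class = "solubility_data")
}

#' Read a solubility dataset from CSV
#'
#' Expects a comma-separated file with a header row and columns `T_K`,
#' `P_MPa`, `rho_kg_m3`, `y2` (optional: `sd_y2`, `U_y2`, `S_gL`).
#'
#' @param path Path to the CSV file.
#' @inheritParams solubility_data
#' @return A [solubility_data()] object.
#' @export
read_solubility_data <- function(path, solute = apz_properties(),
                                 solvent = co2_properties(), check_s = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("unreadable CSV (expected a header row with ",
                        "T_K, P_MPa, rho_kg_m3, y2): ",
                        conditionMessage(e), call. = FALSE))
  req <- c("T_K", "P_MPa", "rho_kg_m3", "y2")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  solubility_data(df, solute, solvent, check_s = check_s)
}

#' The bundled aripiprazole solubility dataset
#'
#' The 28 equilibrium solubility records of aripiprazole in supercritical
#' CO2 (4 temperatures, 308-338 K, by 7 pressures, 12-30 MPa), with CO2
#' densities, mole fractions, their uncertainties and the mass solubility.
#'
#' @return A [solubility_data()] object with 28 records.
#' @examples
#' d <- aripiprazole_scco2()
#' summary(d)
#' @export
aripiprazole_scco2 <- function() {
  read_solubility_data(
    system.file("extdata", "aripiprazole_table2.csv",
                package = "scsolub", mustWork = TRUE))
}

#' @export
print.solubility_data <- function(x, ...) {
  cat(sprintf("Solubility dataset: %s in supercritical %s\n",
              x$solute$name, x$solvent$name))
  cat(sprintf("  %d records, %d temperatures (%g-%g K), %d pressures (%g-%g MPa)\n",
              nrow(x$records), length(unique(x$records$T_K)),
              min(x$records$T_K), max(x$records$T_K),
              length(unique(x$records$P_MPa)),
              min(x$records$P_MPa), max(x$records$P_MPa)))
  cat(sprintf("  y2 range: %.3e - %.3e\n",
              min(x$records$y2), max(x$records$y2)))
  invisible(x)
}

#' @export
summary.solubility_data <- function(object, ...) {
  r <- object$records
  out <- list(
    solute = object$solute$name, solvent = object$solvent$name,
    n_records = nrow(r),
    n_temperatures = length(unique(r$T_K)),
    n_pressures = length(unique(r$P_MPa)),
    T_range_K = range(r$T_K), P_range_MPa = range(r$P_MPa),
    rho_range_kg_m3 = range(r$rho_kg_m3), y2_range = range(r$y2),
    has_S = "S_gL" %in% names(r), has_sd = "sd_y2" %in% names(r))
  class(out) <- "summary.solubility_data"
  out
}

#' @export
print.summary.solubility_data <- function(x, ...) {
  cat(sprintf("%s in supercritical %s: %d records\n",
              x$solute, x$solvent, x$n_records))
  cat(sprintf("  T: %g-%g K (%d levels);  P: %g-%g MPa (%d levels)\n",
              x$T_range_K[1], x$T_range_K[2], x$n_temperatures,
              x$P_range_MPa[1], x$P_range_MPa[2], x$n_pressures))
  cat(sprintf("  rho: %g-%g kg/m3;  y2: %.3e-%.3e\n",
              x$rho_range_kg_m3[1], x$rho_range_kg_m3[2],
              x$y2_range[1], x$y2_range[2]))
  invisible(x)
}

#' @export
as.data.frame.solubility_data <- function(x, ...) x$records

#' @export
nobs.solubility_data <- function(object, ...) nrow(object$records)
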