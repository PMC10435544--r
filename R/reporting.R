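#' Validate a solubility dataset and summarize the result
#'
#' Non-throwing validation front end: loads (or takes) a dataset, runs
#' every record invariant including the mass-solubility consistency check,
#' and returns a structured report instead of an error.
#'
#' @param x Path to a CSV file, a data frame of records, or a
#'   [solubility_data()] object.
#' @param solute,solvent System constants used for validation.
#' @return A list of class `"data_check"`: `valid`, `n_records`,
#'   `n_temperatures`, `n_pressures`, `ranges`, `issues` (character vector
#'   of every violated invariant), and `s_checked` (whether the `S_gL`
#'   consistency check ran).
#' @export
check_data <- function(x, solute = apz_properties(),
                       solvent = co2_properties()) {
  issues <- character(0)
  df <- NULL
  if (inherits(x, "solubility_data")) {
    df <- x$records
    solute <- x$solute
    solvent <- x$solvent
  } else if (is.data.frame(x)) {
    df <- as.data.frame(x)
  } else if (is.character(x) && length(x) == 1) {
    if (!file.exists(x)) {
      issues <- c(issues, paste("file not found:", x))
    } else {
      df <- tryCatch(utils::read.csv(x, stringsAsFactors = FALSE),
                     error = function(e)
                       issues <<- c(issues, paste("unreadable CSV:",
                                                  conditionMessage(e))))
    }
  } else stop("x must be a path, a data frame or a solubility_data object")

  if (is.data.frame(df))
    issues <- c(issues, validate_records(df, solute, solvent,
                                         check_s = TRUE))
  s_checked <- is.data.frame(df) && "S_gL" %in% names(df)
  ok <- length(issues) == 0 && is.data.frame(df)
  structure(list(
    valid = ok,
    n_records = if (is.data.frame(df)) nrow(df) else 0L,
    n_temperatures = if (ok) length(unique(df$T_K)) else NA_integer_,
    n_pressures = if (ok) length(unique(df$P_MPa)) else NA_integer_,
    ranges = if (ok) list(T_K = range(df$T_K), P_MPa = range(df$P_MPa),
                          y2 = range(df$y2)) else NULL,
    issues = issues, s_checked = s_checked),
    class = "data_check")
}

#' @export
print.data_check <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("Dataset valid: %d records, %d temperatures, %d pressures\n",
                x$n_records, x$n_temperatures, x$n_pressures))
    if (!x$s_checked)
      cat("  (no S_gL column: mass-solubility consistency check skipped)\n")
  } else {
    cat("Dataset INVALID:\n")
    cat(paste0("  - ", x$issues, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Dataset summary as JSON
#'
#' Serializes the record counts, condition ranges and validation report of
#' a dataset to a JSON string (or file).
#'
#' @param x Anything [check_data()] accepts.
#' @param path Optional output file; when `NULL` the JSON is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
dataset_summary_json <- function(x, path = NULL) {
  chk <- check_data(x)
  out <- jsonlite::toJSON(unclass(chk), auto_unbox = TRUE, digits = NA,
                          pretty = TRUE, null = "null")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

## Serializable summary of one fit (everything the reports need).
fit_record <- function(f) {
  rec <- list(model = f$model, label = f$label,
              params = as.list(f$coefficients),
              aard_pct = f$aard_pct, r2 = f$r2, r_adj = f$r_adj,
              z = f$z, q = f$q, seed = f$seed,
              objective_evaluations = f$objective_evaluations,
              residuals = f$residuals)
  if (!is.null(f$fixed_constants))
    rec$fixed_constants <- list(
      fusion_enthalpy = f$fixed_constants$fusion_enthalpy,
      melting_T = f$fixed_constants$melting_T,
      solvent_critical_T = f$fixed_constants$solvent_critical_T,
      solvent_critical_molar_density =
        f$fixed_constants$solvent_critical_molar_density)
  rec
}

#' Serialize and restore fit results
#'
#' `fits_to_json()` writes one record per fitted model (coefficients,
#' AARD%, R^2, R_adj, residuals, seed) to a JSON file at full numeric
#' precision; `fits_from_json()` reads it back.
#'
#' @param fits A `"solubility_fitlist"` or list of `"solubility_fit"`s.
#' @param path Output (input) JSON path.
#' @return `fits_to_json()`: the path, invisibly; `fits_from_json()`: a
#'   named list of fit records.
#' @export
fits_to_json <- function(fits, path) {
  recs <- lapply(fits, fit_record)
  names(recs) <- vapply(fits, function(f) f$model, "")
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname fits_to_json
#' @export
fits_from_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Write the full analysis report set
#'
#' Fits drive four artifacts in `dir`: `fits.json` (per-model parameters
#' and fit quality), `enthalpy.json` (total/vaporization/solvation
#' enthalpies from the Chrastil and Bartle temperature coefficients),
#' `diagnostics.json` (crossover region and per-model self-consistency),
#' and `report.md`, a readable summary whose every number is taken from
#' the JSON artifacts just written (the reporter recomputes nothing).
#'
#' @param fits A `"solubility_fitlist"` from [fit_all_models()]
#'   containing at least the Chrastil and Bartle fits.
#' @param dir Output directory (created if needed).
#' @param data The dataset the fits were produced on; defaults to the
#'   first fit's training data.
#' @return Invisibly, the paths of the four files.
#' @export
write_fit_reports <- function(fits, dir, data = NULL) {
  stopifnot(length(fits) >= 1)
  if (is.null(data)) data <- fits[[1]]$data
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("fits.json", "enthalpy.json",
                            "diagnostics.json", "report.md"))
  names(paths) <- c("fits", "enthalpy", "diagnostics", "report")

  fits_to_json(fits, paths[["fits"]])

  ent <- enthalpies(fits)
  jsonlite::write_json(list(dH_total = ent$dH_total, dH_vap = ent$dH_vap,
                            dH_sol = ent$dH_sol,
                            source_fit_ids = c("chrastil", "bartle")),
                       paths[["enthalpy"]], auto_unbox = TRUE, digits = NA)

  cx <- crossover_region(data)
  sc <- lapply(fits, function(f) {
    s <- self_consistency(f, data)
    list(identity_r2 = s$identity_r2,
         max_rel_deviation = s$max_rel_deviation,
         consistent = s$consistent)
  })
  names(sc) <- vapply(fits, function(f) f$model, "")
  jsonlite::write_json(
    list(crossover = list(bracket_low = cx$bracket_low,
                          bracket_high = cx$bracket_high,
                          trends = cx$trends),
         self_consistency = sc),
    paths[["diagnostics"]], auto_unbox = TRUE, digits = NA)

  ## report.md is rendered purely from the serialized artifacts
  fr <- fits_from_json(paths[["fits"]])
  er <- jsonlite::read_json(paths[["enthalpy"]], simplifyVector = TRUE)
  dr <- jsonlite::read_json(paths[["diagnostics"]], simplifyVector = TRUE)
  lines <- c("# Solubility correlation report", "",
             sprintf("Dataset: %d records.", nrow(data$records)), "",
             "## Model comparison", "",
             "| model | parameters | AARD% | R_adj |",
             "|---|---|---|---|")
  for (m in names(fr)) {
    p <- unlist(fr[[m]]$params)
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s |", fr[[m]]$label,
      paste(sprintf("%s=%.4g", names(p), p), collapse = ", "),
      signif(fr[[m]]$aard_pct, 4), signif(fr[[m]]$r_adj, 4)))
  }
  lines <- c(lines, "", "## Enthalpies (kJ/mol)", "",
             sprintf("- total mixing (Chrastil): %.4g", er$dH_total),
             sprintf("- vaporization (Bartle): %.4g", er$dH_vap),
             sprintf("- solvation (Hess's law): %.4g", er$dH_sol),
             "", "## Diagnostics", "",
             if (is.finite(unlist(dr$crossover$bracket_low) %||% NA))
               sprintf("- crossover bracket: (%.4g, %.4g) MPa",
                       dr$crossover$bracket_low, dr$crossover$bracket_high)
             else "- no crossover detected",
             sprintf("- self-consistency (identity-line R2): %s",
                     paste(sprintf("%s %.4g", names(dr$self_consistency),
                                   vapply(dr$self_consistency,
                                          function(s) s$identity_r2, 0)),
                           collapse = ", ")))
  writeLines(lines, paths[["report"]])
  invisible(paths)
}
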