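## Crossover-pressure and self-consistency diagnostics.
##
## Below the crossover pressure the solvent-density effect dominates and
## solubility falls as temperature rises (the density drop wins); above it
## the solute vapor-pressure effect dominates and solubility rises with
## temperature.  On a (T, P) grid the crossover shows up as the isobaric
## temperature trend flipping sign between two adjacent pressures.

#' Locate the crossover-pressure region of a dataset
#'
#' Classifies each isobar's temperature trend by the sign of the Spearman
#' correlation of y2 with T (`"decreasing"`, `"increasing"`, or `"mixed"`
#' when the isobar is not monotone), then brackets the crossover by the
#' adjacent pressure pair where the classification flips from decreasing
#' to increasing.  Mixed isobars are excluded from bracketing with a
#' warning.
#'
#' @param data A [solubility_data()] object with at least 2 temperatures
#'   and 2 pressures.
#' @return A list of class `"crossover_report"`: `trends` (data frame of
#'   pressure and classification), `bracket_low`/`bracket_high` (MPa; `NA`
#'   when no flip exists), `has_crossover`.
#' @export
crossover_region <- function(data) {
  stopifnot(inherits(data, "solubility_data"))
  r <- data$records
  if (length(unique(r$T_K)) < 2 || length(unique(r$P_MPa)) < 2)
    stop("crossover analysis needs at least 2 temperatures and 2 pressures")
  pressures <- sort(unique(r$P_MPa))
  cls <- character(length(pressures))
  for (i in seq_along(pressures)) {
    sel <- r$P_MPa == pressures[i]
    if (sum(sel) < 2) {
      cls[i] <- "mixed"
      next
    }
    rho_s <- if (stats::sd(r$y2[sel]) == 0) NA_real_
             else suppressWarnings(stats::cor(r$T_K[sel], r$y2[sel],
                                              method = "spearman"))
    cls[i] <- if (isTRUE(all.equal(rho_s, 1))) "increasing"
              else if (isTRUE(all.equal(rho_s, -1))) "decreasing"
              else "mixed"
  }
  if (any(cls == "mixed"))
    warning("non-monotone isobar(s) at P = ",
            paste(pressures[cls == "mixed"], collapse = ", "),
            " MPa excluded from crossover bracketing")
  keep <- cls != "mixed"
  p_k <- pressures[keep]
  c_k <- cls[keep]
  lo <- hi <- NA_real_
  if (length(c_k) >= 2) {
    flip <- which(c_k[-length(c_k)] == "decreasing" &
                    c_k[-1] == "increasing")
    if (length(flip)) {
      lo <- p_k[flip[1]]
      hi <- p_k[flip[1] + 1]
    }
  }
  structure(list(trends = data.frame(P_MPa = pressures,
                                     trend = cls,
                                     stringsAsFactors = FALSE),
                 bracket_low = lo, bracket_high = hi,
                 has_crossover = is.finite(lo)),
            class = "crossover_report")
}

#' @export
print.crossover_report <- function(x, ...) {
  cat("Isobaric temperature trends of y2:\n")
  print(x$trends, row.names = FALSE)
  if (x$has_crossover)
    cat(sprintf("Crossover bracket: (%g, %g) MPa\n",
                x$bracket_low, x$bracket_high))
  else cat("No crossover detected\n")
  invisible(x)
}

#' Self-consistency test of a fitted model
#'
#' Compares calculated against experimental mole fractions on the
#' 45-degree line.  The agreement statistic is the identity-line R^2,
#' `1 - sum((y_calc - y_exp)^2) / sum((y_exp - mean(y_exp))^2)` — unlike a
#' Pearson correlation this penalizes bias, which is the point of the
#' 45-degree test.  The fit is judged consistent when it exceeds the
#' threshold.
#'
#' @param fit A `"solubility_fit"` produced on `data`.
#' @param data Optional [solubility_data()]; defaults to the fit's own
#'   training data, and must match it in record count.
#' @param threshold Identity-line R^2 required for a "consistent" verdict
#'   (default 0.95).
#' @return A list of class `"self_consistency"`: `pairs` (data frame of
#'   experimental and calculated values), `identity_r2`,
#'   `max_rel_deviation`, `consistent`.
#' @export
self_consistency <- function(fit, data = NULL, threshold = 0.95) {
  stopifnot(inherits(fit, "solubility_fit"))
  if (is.null(data)) {
    data <- fit$data
    y_calc <- fit$fitted_y2
  } else {
    if (nrow(data$records) != length(fit$fitted_y2))
      stop("record count of data does not match the fit")
    y_calc <- predict(fit, newdata = data)
  }
  y_exp <- data$records$y2
  id_r2 <- 1 - sum((y_calc - y_exp)^2) / sum((y_exp - mean(y_exp))^2)
  structure(list(pairs = data.frame(y2_exp = y_exp, y2_calc = y_calc),
                 identity_r2 = id_r2,
                 max_rel_deviation = max(abs(y_calc - y_exp) / y_exp),
                 threshold = threshold,
                 consistent = id_r2 >= threshold,
                 model = fit$model),
            class = "self_consistency")
}

#' @export
print.self_consistency <- function(x, ...) {
  cat(sprintf("Self-consistency of model '%s' on %d records\n",
              x$model, nrow(x$pairs)))
  cat(sprintf("  identity-line R2: %.4f (threshold %.2f) -> %s\n",
              x$identity_r2, x$threshold,
              if (x$consistent) "consistent" else "NOT consistent"))
  cat(sprintf("  max relative deviation: %.3g\n", x$max_rel_deviation))
  invisible(x)
}
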