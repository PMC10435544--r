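## Synthetic solubility datasets with the statistical structure the
## analysis assumes: a (T, P) grid, solvent densities from a surrogate of
## the equation-of-state table, model-generated mole fractions, and
## multiplicative lognormal measurement noise (the bundled dataset's
## replicate standard deviations scale roughly with y2, at about 3-7%
## relative, which is what a lognormal error model encodes).

the_density_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      df <- utils::read.csv(system.file("extdata", "aripiprazole_table2.csv",
                                        package = "scsolub",
                                        mustWork = TRUE))
      temps <- sort(unique(df$T_K))
      pressures <- sort(unique(df$P_MPa))
      m <- matrix(NA_real_, length(temps), length(pressures),
                  dimnames = list(temps, pressures))
      for (i in seq_len(nrow(df)))
        m[as.character(df$T_K[i]), as.character(df$P_MPa[i])] <-
          df$rho_kg_m3[i]
      cache <<- list(temps = temps, pressures = pressures, rho = m)
    }
    cache
  }
})

interp1 <- function(grid, x) {
  ## fractional index of x on a sorted grid (for bilinear interpolation)
  i <- findInterval(x, grid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(grid) - 1L)
  i + (x - grid[i]) / (grid[i + 1L] - grid[i])
}

#' Surrogate CO2 density over the experimental grid
#'
#' Bilinear interpolation of the bundled 4 x 7 density table (308-338 K,
#' 12-30 MPa), exact at the grid nodes.  A stand-in for an external
#' equation-of-state density provider; any function of (T, P) can be used
#' in its place wherever a density source is accepted.
#'
#' @param T_K Temperature (K).
#' @param P_MPa Pressure (MPa).
#' @param allow_extrapolation Permit queries outside the grid hull
#'   (linear extension of the edge cells); off by default.
#' @return Density in kg/m^3, vectorized over the inputs.
#' @export
co2_density_surrogate <- function(T_K, P_MPa, allow_extrapolation = FALSE) {
  g <- the_density_grid()
  n <- max(length(T_K), length(P_MPa))
  T_K <- rep_len(T_K, n)
  P_MPa <- rep_len(P_MPa, n)
  if (!allow_extrapolation) {
    out_t <- T_K < min(g$temps) | T_K > max(g$temps)
    out_p <- P_MPa < min(g$pressures) | P_MPa > max(g$pressures)
    if (any(out_t | out_p))
      stop(sprintf(
        "density surrogate queried outside the %g-%g K / %g-%g MPa hull",
        min(g$temps), max(g$temps), min(g$pressures), max(g$pressures)))
  }
  ti <- interp1(g$temps, T_K)
  pi_ <- interp1(g$pressures, P_MPa)
  i0 <- pmin(floor(ti), length(g$temps) - 1L); u <- ti - i0
  j0 <- pmin(floor(pi_), length(g$pressures) - 1L); v <- pi_ - j0
  r <- g$rho
  (1 - u) * (1 - v) * r[cbind(i0, j0)] +
    u * (1 - v) * r[cbind(i0 + 1, j0)] +
    (1 - u) * v * r[cbind(i0, j0 + 1)] +
    u * v * r[cbind(i0 + 1, j0 + 1)]
}

#' Generate a synthetic solubility dataset
#'
#' Draws mole fractions from a chosen correlation model on a (T, P) grid
#' with multiplicative lognormal noise: `y2 = y2_model * exp(eps)`,
#' `eps ~ N(0, noise_sigma^2)`.  Densities come from a density source
#' (function of T and P, or a vector aligned with the grid) and the mass
#' solubility column is populated consistently, so generated datasets pass
#' every [solubility_data()] invariant.
#'
#' @param model Model id used as the generating truth.
#' @param params True coefficient vector (named, for `"wilson"`).
#' @param grid Data frame with columns `T_K` and `P_MPa`; defaults to the
#'   bundled 4 temperatures x 7 pressures design.
#' @param noise_sigma Relative lognormal noise scale (>= 0; default 0.05,
#'   matching the experimental replicate scatter).
#' @param seed Optional integer seed (RNG state is restored on exit).
#' @param density Density source: a function `(T_K, P_MPa) -> kg/m^3`
#'   (default [co2_density_surrogate()]) or a numeric vector of densities.
#' @param solute,solvent System constants for the conversion columns.
#' @param control A [fit_control()] (supplies model-form flags).
#' @param constants Wilson constants when `model = "wilson"`.
#' @param nsim Number of replicate datasets.
#' @return A [solubility_data()] object, or a list of them when
#'   `nsim > 1`.
#' @export
generate_dataset <- function(model = "chrastil", params, grid = NULL,
                             noise_sigma = 0.05, seed = NULL,
                             density = co2_density_surrogate,
                             solute = apz_properties(),
                             solvent = co2_properties(),
                             control = fit_control(),
                             constants = NULL, nsim = 1) {
  if (noise_sigma < 0) stop("noise_sigma must be non-negative")
  if (is.null(grid)) {
    g <- the_density_grid()
    grid <- expand.grid(T_K = g$temps, P_MPa = g$pressures,
                        KEEP.OUT.ATTRS = FALSE)
  }
  grid <- as.data.frame(grid)
  if (!all(c("T_K", "P_MPa") %in% names(grid)))
    stop("grid must have columns T_K and P_MPa")
  if (nrow(grid) == 0) stop("grid must be non-empty")
  rho <- if (is.function(density)) density(grid$T_K, grid$P_MPa)
         else rep_len(as.numeric(density), nrow(grid))

  if (model == "wilson") {
    if (is.null(constants)) constants <- wilson_constants()
    dhf <- if ("dhf" %in% names(params)) params[["dhf"]]
           else constants$fusion_enthalpy
    mu <- wilson_predict_safe(as.list(params), grid$T_K, rho, constants,
                              dhf)
  } else {
    mu <- predict_y2(model, unname(params), grid$T_K, grid$P_MPa, rho,
                     solute$molar_mass, solvent$molar_mass,
                     mst_classic = control$mst_classic,
                     bartle_form = control$bartle_form)
  }
  bad <- which(!is.finite(mu) | mu <= 0)
  if (length(bad))
    stop(sprintf("model prediction non-finite at grid point (T = %g K, P = %g MPa)",
                 grid$T_K[bad[1]], grid$P_MPa[bad[1]]))

  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv())
    if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  one <- function() {
    y2 <- mu * exp(stats::rnorm(length(mu), 0, noise_sigma))
    rec <- data.frame(T_K = grid$T_K, P_MPa = grid$P_MPa, rho_kg_m3 = rho,
                      y2 = y2, sd_y2 = noise_sigma * y2,
                      S_gL = s_from_y2(rho, y2, solute$molar_mass,
                                       solvent$molar_mass))
    solubility_data(rec, solute, solvent)
  }
  if (nsim == 1) one() else lapply(seq_len(nsim), function(i) one())
}

#' Parameter-recovery study by simulation
#'
#' Repeatedly generates synthetic datasets from known true coefficients
#' ([generate_dataset()]) and refits the same model, reporting the
#' per-coefficient relative bias and root-mean-square error of the
#' estimates, plus the distribution of refit AARD%.
#'
#' @inheritParams generate_dataset
#' @param n_rep Number of generate-and-refit replicates.
#' @param control Fitting control passed to [fit_solubility()].
#' @return A list of class `"recovery_report"`: `estimates` (replicate x
#'   coefficient matrix), `bias_rel`, `rmse`, `aard_pct`, and a
#'   `sufficient` flag (FALSE when `n_rep < 2`).
#' @export
simulate_recover <- function(model = "chrastil", params, n_rep = 20,
                             noise_sigma = 0.05, seed = 1,
                             grid = NULL, control = fit_control(),
                             solute = apz_properties(),
                             solvent = co2_properties()) {
  datasets <- generate_dataset(model = model, params = params, grid = grid,
                               noise_sigma = noise_sigma, seed = seed,
                               solute = solute, solvent = solvent,
                               control = control, nsim = n_rep)
  if (n_rep == 1) datasets <- list(datasets)
  est <- matrix(NA_real_, n_rep, length(params))
  aards <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    f <- fit_solubility(datasets[[i]], model, control)
    est[i, ] <- f$coefficients[seq_along(params)]
    aards[i] <- f$aard_pct
  }
  colnames(est) <- names(params) %||%
    get_model(model)$coef_names[seq_along(params)]
  mean_est <- colMeans(est)
  truth <- as.numeric(params)
  structure(list(model = model, truth = truth, estimates = est,
                 bias_rel = (mean_est - truth) / truth,
                 rmse = sqrt(colMeans(sweep(est, 2, truth)^2)),
                 aard_pct = aards, n_rep = n_rep,
                 noise_sigma = noise_sigma,
                 sufficient = n_rep >= 2),
            class = "recovery_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery for model '%s': %d replicates, noise sigma %g\n",
              x$model, x$n_rep, x$noise_sigma))
  if (!x$sufficient)
    cat("  NOTE: fewer than 2 replicates -- bias/RMSE estimates unreliable\n")
  df <- data.frame(truth = x$truth,
                   mean_estimate = colMeans(x$estimates),
                   bias_rel = x$bias_rel, rmse = x$rmse)
  print(signif(df, digits))
  cat(sprintf("  refit AARD%%: mean %.3g, range [%.3g, %.3g]\n",
              mean(x$aard_pct), min(x$aard_pct), max(x$aard_pct)))
  invisible(x)
}
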