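#' Control options for solubility-model fitting
#'
#' Parameters are estimated by simulated annealing (best of `n_restarts`
#' Latin-hypercube-initialized runs of a geometric cooling schedule)
#' followed by a Nelder-Mead simplex polish.  The objective minimized is
#' exactly the AARD% statistic ([aard()]) on mole fractions, including the
#' `N - Z` denominator; since `Z` is fixed per model this coincides with
#' minimizing the mean absolute relative error.
#'
#' @param seed Integer seed; identical (seed, options, dataset) give a
#'   bit-identical fit.
#' @param n_restarts Number of independent annealing restarts (>= 1).
#' @param sa_t0 Initial annealing temperature (objective units, i.e. AARD
#'   percentage points).
#' @param sa_cool Geometric cooling factor in (0, 1).
#' @param sa_iter Proposals per temperature level.
#' @param sa_tmin Stopping temperature.
#' @param polish Run a derivative-free simplex polish from the best
#'   annealed point.
#' @param polish_maxit Iteration cap for the polish.
#' @param sa_step Proposal scale.  For the density models proposals are
#'   drawn in the fit-space prediction metric (the coefficient directions
#'   are strongly collinear, so raw coordinate steps stall); `sa_step` is
#'   then in log-solubility units.  For the Wilson model it multiplies the
#'   per-coordinate box width.
#' @param sa_spread Spread (same metric) of the restart starting points
#'   around the fit-space least-squares anchor for the density models.
#' @param mst_classic Use the classic `T ln(y2 P)` MST left-hand side
#'   (the default; the plain `ln(y2 P)` reading is available by setting
#'   this to `FALSE`).
#' @param bartle_form Bartle back-transformation; see [predict_y2()].
#' @param wilson_fit_dhf Fit the fusion enthalpy as an additional bounded
#'   free parameter instead of fixing it at the [wilson_constants()] value.
#' @param dhf_bounds Bounds (J/mol) for the fitted fusion enthalpy.
#' @param penalty Large finite objective value substituted when a
#'   parameter vector yields non-finite or non-positive predictions.
#' @return A list of class `"fit_control"`.
#' @export
fit_control <- function(seed = 1L, n_restarts = 40L, sa_t0 = 10,
                        sa_cool = 0.95, sa_iter = 50L, sa_tmin = 1e-4,
                        polish = TRUE, polish_maxit = 2000L,
                        sa_step = 0.5, sa_spread = 3,
                        mst_classic = TRUE,
                        bartle_form = c("conventional", "literal"),
                        wilson_fit_dhf = FALSE,
                        dhf_bounds = c(20e3, 70e3), penalty = 1e6) {
  bartle_form <- match.arg(bartle_form)
  stopifnot(n_restarts >= 1, sa_cool > 0, sa_cool < 1, sa_t0 > sa_tmin,
            sa_tmin > 0, sa_iter >= 1, penalty > 0, sa_step > 0,
            sa_spread >= 0, length(dhf_bounds) == 2, dhf_bounds[1] > 0,
            dhf_bounds[2] > dhf_bounds[1])
  structure(list(seed = as.integer(seed), n_restarts = as.integer(n_restarts),
                 sa_t0 = sa_t0, sa_cool = sa_cool,
                 sa_iter = as.integer(sa_iter), sa_tmin = sa_tmin,
                 polish = polish, polish_maxit = as.integer(polish_maxit),
                 sa_step = sa_step, sa_spread = sa_spread,
                 mst_classic = mst_classic, bartle_form = bartle_form,
                 wilson_fit_dhf = wilson_fit_dhf, dhf_bounds = dhf_bounds,
                 penalty = penalty),
            class = "fit_control")
}

## Build the AARD objective for one model on one dataset.  Returns a list
## with the objective closure, an evaluation counter environment, and the
## vectorized predictor used for reporting.
make_objective <- function(model, data, control,
                           constants = wilson_constants()) {
  def <- get_model(model)
  r <- data$records
  y_exp <- r$y2
  n <- length(y_exp)
  denom <- n - def$z
  if (denom <= 0) stop("need more records than adjustable parameters")
  counter <- new.env(parent = emptyenv())
  counter$evals <- 0L
  counter$penalized <- 0L
  penalty <- control$penalty

  if (def$id == "wilson") {
    fixed_dhf <- constants$fusion_enthalpy
    k_free <- if (control$wilson_fit_dhf) 5L else 4L
    pred <- function(par) {
      p <- list(lam12 = par[1], lam21 = par[2], alpha = par[3],
                beta = par[4])
      dhf <- if (control$wilson_fit_dhf) par[5] else fixed_dhf
      wilson_predict_safe(p, r$T_K, r$rho_kg_m3, constants, dhf)
    }
  } else {
    X <- model_design(model, r$T_K, r$P_MPa, r$rho_kg_m3)
    Ms <- data$solute$molar_mass; Mc <- data$solvent$molar_mass
    rho <- r$rho_kg_m3; pres <- r$P_MPa; tk <- r$T_K
    bt <- switch(def$id,
      chrastil = ,
      kj = function(v) { s <- exp(v); s * Mc / (rho * Ms + s * Mc) },
      bartle = if (control$bartle_form == "conventional")
                 function(v) exp(v) * BARTLE_P_REF / pres
               else function(v) exp(v) * BARTLE_RHO_REF / pres,
      mst = if (control$mst_classic) function(v) exp(v / tk) / pres
            else function(v) exp(v) / pres,
      sodeifian = ,
      jouyban = function(v) exp(v))
    k_free <- def$n_coef
    pred <- function(par) bt(drop(X %*% par))
  }

  obj <- function(par) {
    counter$evals <- counter$evals + 1L
    y_calc <- pred(par)
    if (any(!is.finite(y_calc)) || any(y_calc <= 0)) {
      counter$penalized <- counter$penalized + 1L
      return(penalty)
    }
    100 / denom * sum(abs(y_calc - y_exp) / y_exp)
  }
  list(obj = obj, pred = pred, counter = counter, k_free = k_free,
       def = def, y_exp = y_exp)
}

#' AARD objective for a model/parameter/dataset triple
#'
#' Evaluates the fitting objective: the AARD% of [predict_y2()] (or the
#' Wilson predictor) against the experimental mole fractions, with the
#' model's parameter count `Z` in the denominator.  Parameter vectors
#' producing non-finite or non-positive predictions receive a large finite
#' penalty value rather than an error, so the optimizer can traverse them.
#'
#' @param model Model id (see [solubility_models()]).
#' @param params Coefficient vector (for `"wilson"`: lam12, lam21, alpha,
#'   beta, and optionally the fusion enthalpy when `wilson_fit_dhf` is
#'   set in `control`).
#' @param data A [solubility_data()] object.
#' @param control A [fit_control()] object.
#' @param constants Wilson constants (ignored by density models).
#' @return AARD in percent, or `control$penalty` for invalid predictions.
#' @export
objective_aard <- function(model, params, data, control = fit_control(),
                           constants = wilson_constants()) {
  ob <- make_objective(model, data, control, constants)
  if (length(params) != ob$k_free)
    stop(sprintf("model %s expects %d free parameters, got %d",
                 model, ob$k_free, length(params)))
  ob$obj(as.numeric(params))
}

## Default search box.  Density models are linear in their coefficients in
## fit space, so the box is centred on the fit-space least-squares solution
## with half-width 3|theta| + 1 per coordinate.  The Wilson model has no
## linear fit space and uses static physically-motivated bounds.
default_bounds <- function(model, data, control) {
  def <- get_model(model)
  if (def$id == "wilson") {
    lower <- c(lam12 = -30, lam21 = -30, alpha = -5e-5, beta = 1e-6)
    upper <- c(lam12 = 30, lam21 = 60, alpha = 5e-5, beta = 2e-4)
    if (control$wilson_fit_dhf) {
      lower <- c(lower, dhf = control$dhf_bounds[1])
      upper <- c(upper, dhf = control$dhf_bounds[2])
    }
    return(list(lower = lower, upper = upper))
  }
  r <- data$records
  X <- model_design(model, r$T_K, r$P_MPa, r$rho_kg_m3)
  y <- model_target(model, data, mst_classic = control$mst_classic,
                    bartle_form = control$bartle_form)
  theta <- qr.solve(X, y)
  half <- 3 * abs(theta) + 1
  names(theta) <- def$coef_names
  list(lower = theta - half, upper = theta + half)
}

## One simulated-annealing run: geometric cooling, Gaussian proposals with
## a step size that shrinks with temperature, clamped into the box.  When a
## proposal matrix `precond` is supplied, steps are `precond %*% z` with
## isotropic z, so the walk moves in the fit-space prediction metric
## instead of the (collinear) raw coefficient axes.
sa_anneal <- function(obj, start, lower, upper, control, precond = NULL) {
  x <- start
  fx <- obj(x)
  best_x <- x
  best_f <- fx
  temp <- control$sa_t0
  k <- length(x)
  step0 <- (upper - lower) / 10
  while (temp > control$sa_tmin) {
    rel <- sqrt(temp / control$sa_t0)
    for (i in seq_len(control$sa_iter)) {
      prop <- if (is.null(precond))
        x + stats::rnorm(k, 0, step0 * rel)
      else
        x + drop(precond %*% stats::rnorm(k, 0, control$sa_step * rel))
      prop <- pmin(pmax(prop, lower), upper)
      fp <- obj(prop)
      if (fp <= fx || stats::runif(1) < exp((fx - fp) / temp)) {
        x <- prop
        fx <- fp
      }
      if (fx < best_f) {
        best_x <- x
        best_f <- fx
      }
    }
    temp <- temp * control$sa_cool
  }
  list(par = best_x, value = best_f)
}

#' Fit a solubility correlation model
#'
#' Estimates the parameters of one of the density-based correlations or
#' the modified Wilson expanded-liquid model on a solubility dataset by
#' minimizing the AARD% on mole fractions ([objective_aard()]) with
#' simulated annealing plus a simplex polish (see [fit_control()]).
#'
#' @param data A [solubility_data()] object.
#' @param model Model id; one of the rows of [solubility_models()].
#' @param control A [fit_control()] object.
#' @param bounds Optional list with numeric `lower` and `upper` vectors
#'   overriding the default search box.
#' @param constants Wilson-model constants ([wilson_constants()]); ignored
#'   by the density models.
#' @return An object of class `"solubility_fit"` with components `model`,
#'   `coefficients`, `aard_pct`, `r2`, `r_adj`, `residuals` (relative, per
#'   record), `fitted_y2`, `seed`, `objective_evaluations` and the data.
#' @examples
#' d <- aripiprazole_scco2()
#' f <- fit_solubility(d, "chrastil", fit_control(seed = 1, n_restarts = 4))
#' summary(f)
#' @export
fit_solubility <- function(data, model = "chrastil",
                           control = fit_control(), bounds = NULL,
                           constants = wilson_constants()) {
  stopifnot(inherits(data, "solubility_data"))
  def <- get_model(model)
  ob <- make_objective(model, data, control, constants)
  if (is.null(bounds)) bounds <- default_bounds(model, data, control)
  lower <- as.numeric(bounds$lower)
  upper <- as.numeric(bounds$upper)
  if (length(lower) != ob$k_free || length(upper) != ob$k_free)
    stop("bounds length does not match the model's free-parameter count")
  if (any(upper <= lower)) stop("upper bounds must exceed lower bounds")

  ## fixed-seed, restorable RNG
  had_seed <- exists(".Random.seed", envir = globalenv())
  if (had_seed) old_seed <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old_seed, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(control$seed)

  k <- ob$k_free
  precond <- NULL
  anchor <- NULL
  if (def$id != "wilson") {
    ## fit-space least-squares anchor and prediction-metric preconditioner,
    ## scaled by the anchor's fit-space residual spread so that step sizes
    ## track the distance to the optimum in every fit space
    r <- data$records
    X <- model_design(model, r$T_K, r$P_MPa, r$rho_kg_m3)
    y <- model_target(model, data, mst_classic = control$mst_classic,
                      bartle_form = control$bartle_form)
    anchor <- qr.solve(X, y)
    s_resid <- stats::sd(y - drop(X %*% anchor))
    if (!is.finite(s_resid) || s_resid == 0) s_resid <- 1
    sv <- svd(X)
    precond <- sv$v %*% diag(s_resid / sv$d, k)
  } else {
    if (control$wilson_fit_dhf) {
      ## warm start: solve the 4-parameter problem (fusion enthalpy fixed)
      ## first, so the 5-parameter optimum can never be worse
      ctrl4 <- control
      ctrl4$wilson_fit_dhf <- FALSE
      fit4 <- fit_solubility(data, "wilson", ctrl4,
                             bounds = list(lower = lower[1:4],
                                           upper = upper[1:4]),
                             constants = constants)
      anchor <- unname(c(fit4$coefficients, constants$fusion_enthalpy))
    } else {
      anchor <- (lower + upper) / 2
    }
    ## precondition by the Jacobian of the log prediction at the anchor:
    ## the Wilson parameters act on the solubility on very different
    ## scales (dimensionless energies vs m^3/mol volumes) and along
    ## strongly coupled directions
    h <- pmax(abs(anchor) * 1e-4, c(1e-4, 1e-4, 1e-9, 1e-9,
                                    1e-2)[seq_len(k)])
    f0 <- log(ob$pred(anchor))
    if (all(is.finite(f0))) {
      J <- matrix(0, length(f0), k)
      ok <- TRUE
      for (j in seq_len(k)) {
        e <- anchor
        e[j] <- e[j] + h[j]
        fj <- log(ob$pred(e))
        if (any(!is.finite(fj))) { ok <- FALSE; break }
        J[, j] <- (fj - f0) / h[j]
      }
      if (ok) {
        sv <- svd(J)
        if (all(sv$d > 0)) precond <- sv$v %*% diag(1 / sv$d, k)
      }
    }
  }
  obj_clamped <- function(p) ob$obj(pmin(pmax(p, lower), upper))
  ## starts come from a fixed-size Latin-hypercube pool so that runs with
  ## more restarts extend (rather than reshuffle) runs with fewer: the
  ## best-of-restarts objective is then non-increasing in n_restarts
  lhs_draws <- lhs::randomLHS(max(200L, control$n_restarts), k)
  best <- NULL
  for (i in seq_len(control$n_restarts)) {
    start <- if (!is.null(precond)) {
      if (i == 1) anchor
      else anchor + drop(precond %*%
                           (control$sa_spread * (2 * lhs_draws[i, ] - 1)))
    } else if (i == 1) {
      anchor
    } else {
      lower + lhs_draws[i, ] * (upper - lower)
    }
    start <- pmin(pmax(start, lower), upper)
    res <- sa_anneal(ob$obj, start, lower, upper, control, precond)
    if (control$polish && res$value < control$penalty) {
      ## short simplex descent per restart: each restart lands in a local
      ## minimum, and the best of those is polished fully below.  The
      ## simplex sees the objective through a clamp so it cannot leave
      ## the search box.
      pol <- stats::optim(res$par, obj_clamped, method = "Nelder-Mead",
                          control = list(maxit = 200 * k, reltol = 1e-9))
      par_cl <- pmin(pmax(pol$par, lower), upper)
      if (pol$value <= res$value) res <- list(par = par_cl,
                                              value = pol$value)
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (best$value >= control$penalty)
    stop(sprintf(paste0("fit of model %s failed: all %d restarts produced",
                        " non-finite predictions (%d penalized evaluations)"),
                 model, control$n_restarts, ob$counter$penalized))
  sa_value <- best$value
  par <- best$par
  value <- sa_value
  if (control$polish) {
    pol <- stats::optim(par, obj_clamped, method = "Nelder-Mead",
                        control = list(maxit = control$polish_maxit,
                                       reltol = 1e-12))
    if (pol$value <= value) {
      par <- pmin(pmax(pol$par, lower), upper)
      value <- pol$value
    }
  }

  y_calc <- ob$pred(par)
  y_exp <- ob$y_exp
  r2 <- r_squared(y_exp, y_calc)
  radj <- r_adjusted(r2, length(y_exp), def$q)
  cf <- as.numeric(par)
  names(cf) <- if (def$id == "wilson" && control$wilson_fit_dhf)
    c(def$coef_names, "dhf") else def$coef_names
  structure(list(
    model = def$id, label = def$label, coefficients = cf,
    aard_pct = value, sa_aard_pct = sa_value, r2 = r2, r_adj = radj,
    z = def$z, q = def$q,
    residuals = (y_calc - y_exp) / y_exp, fitted_y2 = y_calc,
    data = data, control = control, bounds = list(lower = lower,
                                                  upper = upper),
    seed = control$seed,
    objective_evaluations = ob$counter$evals,
    penalized_evaluations = ob$counter$penalized,
    fixed_constants = if (def$id == "wilson") constants else NULL),
    class = "solubility_fit")
}

#' Fit every registered model to a dataset
#'
#' Runs [fit_solubility()] for the six density-based correlations and the
#' modified Wilson model (by default) and returns the fits ordered by
#' ascending AARD%.  Individual fit failures are reported as warnings and
#' the remaining fits returned.
#'
#' @inheritParams fit_solubility
#' @param models Character vector of model ids to fit.
#' @return A list of class `"solubility_fitlist"`, ordered by AARD%.
#' @export
fit_all_models <- function(data,
                           models = c("chrastil", "bartle", "kj", "mst",
                                      "sodeifian", "jouyban", "wilson"),
                           control = fit_control(),
                           constants = wilson_constants()) {
  fits <- list()
  failures <- character(0)
  for (m in models) {
    res <- tryCatch(fit_solubility(data, m, control, constants = constants),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("%s: %s", m, conditionMessage(res)))
      warning("fit of model ", m, " failed: ", conditionMessage(res),
              call. = FALSE)
    } else {
      fits[[m]] <- res
    }
  }
  ord <- order(vapply(fits, function(f) f$aard_pct, 0))
  fits <- fits[ord]
  structure(fits, class = "solubility_fitlist", failures = failures)
}

#' @export
print.solubility_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s solubility correlation (model '%s')\n", x$label, x$model))
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("AARD%%: %.*g   R2: %.*g   R_adj: %.*g   (n = %d, Z = %d)\n",
              digits, x$aard_pct, digits, x$r2, digits, x$r_adj,
              length(x$residuals), x$z))
  invisible(x)
}

#' @export
summary.solubility_fit <- function(object, ...) {
  out <- list(model = object$model, label = object$label,
              coefficients = object$coefficients,
              aard_pct = object$aard_pct, r2 = object$r2,
              r_adj = object$r_adj, n = length(object$residuals),
              z = object$z, q = object$q, seed = object$seed,
              objective_evaluations = object$objective_evaluations,
              resid_range = range(object$residuals),
              max_abs_rel = max(abs(object$residuals)))
  class(out) <- "summary.solubility_fit"
  out
}

#' @export
print.summary.solubility_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s correlation fitted on %d records (seed %d, %d objective evaluations)\n",
              x$label, x$n, x$seed, x$objective_evaluations))
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits))
  cat(sprintf("AARD%%: %.*g (Z = %d)   R2: %.*g   R_adj: %.*g (Q = %d)\n",
              digits, x$aard_pct, x$z, digits, x$r2, digits, x$r_adj, x$q))
  cat(sprintf("Relative residuals in [%.3g, %.3g]; max |rel| %.3g\n",
              x$resid_range[1], x$resid_range[2], x$max_abs_rel))
  invisible(x)
}

#' @export
coef.solubility_fit <- function(object, ...) object$coefficients

#' @export
fitted.solubility_fit <- function(object, ...) object$fitted_y2

#' @export
nobs.solubility_fit <- function(object, ...) length(object$residuals)

#' Residuals of a solubility fit
#'
#' @param object A `"solubility_fit"`.
#' @param type `"relative"` (default): `(y_calc - y_exp)/y_exp`;
#'   `"response"`: `y_calc - y_exp`; `"log"`: `log(y_calc/y_exp)`.
#' @param ... Unused.
#' @return Numeric vector, one value per record.
#' @export
residuals.solubility_fit <- function(object,
                                     type = c("relative", "response",
                                              "log"), ...) {
  type <- match.arg(type)
  y_exp <- object$data$records$y2
  y_calc <- object$fitted_y2
  switch(type,
         relative = (y_calc - y_exp) / y_exp,
         response = y_calc - y_exp,
         log = log(y_calc / y_exp))
}

#' Predict mole-fraction solubility from a fitted model
#'
#' @param object A `"solubility_fit"`.
#' @param newdata A [solubility_data()] object or a data frame with
#'   columns `T_K`, `P_MPa` and `rho_kg_m3`; defaults to the training
#'   data.
#' @param ... Unused.
#' @return Predicted mole fractions.
#' @export
predict.solubility_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted_y2)
  df <- if (inherits(newdata, "solubility_data")) newdata$records
        else as.data.frame(newdata)
  req <- if (object$model == "wilson") c("T_K", "rho_kg_m3")
         else c("T_K", "P_MPa", "rho_kg_m3")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("newdata lacks column(s): ", paste(missing_cols, collapse = ", "))
  ctrl <- object$control
  if (object$model == "wilson") {
    cf <- object$coefficients
    dhf <- if ("dhf" %in% names(cf)) cf[["dhf"]]
           else object$fixed_constants$fusion_enthalpy
    wilson_predict_safe(as.list(cf[c("lam12", "lam21", "alpha", "beta")]),
                        df$T_K, df$rho_kg_m3, object$fixed_constants, dhf)
  } else {
    predict_y2(object$model, unname(object$coefficients), df$T_K, df$P_MPa,
               df$rho_kg_m3, object$data$solute$molar_mass,
               object$data$solvent$molar_mass,
               mst_classic = ctrl$mst_classic,
               bartle_form = ctrl$bartle_form)
  }
}

#' Plot a fitted solubility model
#'
#' `which = 1`: calculated vs experimental mole fractions with the
#' 45-degree identity line (the self-consistency view); `which = 2`:
#' solubility isotherms vs pressure, experimental points and model lines.
#'
#' @param x A `"solubility_fit"`.
#' @param which Which plot(s) to draw.
#' @param ... Passed to the underlying plotting calls.
#' @return Invisibly, `x`.
#' @export
plot.solubility_fit <- function(x, which = 1, ...) {
  r <- x$data$records
  if (1 %in% which) {
    lim <- range(c(r$y2, x$fitted_y2))
    graphics::plot(r$y2, x$fitted_y2, xlim = lim, ylim = lim,
                   xlab = "experimental y2", ylab = "calculated y2",
                   main = sprintf("%s: self-consistency", x$label), ...)
    graphics::abline(0, 1, lty = 2)
  }
  if (2 %in% which) {
    temps <- sort(unique(r$T_K))
    cols <- seq_along(temps)
    graphics::plot(r$P_MPa, r$y2, col = cols[match(r$T_K, temps)],
                   xlab = "P (MPa)", ylab = "y2",
                   main = sprintf("%s: isotherms", x$label), ...)
    for (i in seq_along(temps)) {
      sel <- r$T_K == temps[i]
      o <- order(r$P_MPa[sel])
      graphics::lines(r$P_MPa[sel][o], x$fitted_y2[sel][o], col = cols[i])
    }
    graphics::legend("topleft", legend = sprintf("%g K", temps),
                     col = cols, lty = 1, bty = "n")
  }
  invisible(x)
}

#' @export
print.solubility_fitlist <- function(x, digits = 4, ...) {
  cat("Solubility model comparison (ordered by AARD%)\n")
  df <- data.frame(
    model = vapply(x, function(f) f$model, ""),
    AARD_pct = vapply(x, function(f) f$aard_pct, 0),
    R2 = vapply(x, function(f) f$r2, 0),
    R_adj = vapply(x, function(f) f$r_adj, 0))
  df$AARD_pct <- signif(df$AARD_pct, digits)
  df$R2 <- signif(df$R2, digits)
  df$R_adj <- signif(df$R_adj, digits)
  print(df, row.names = FALSE)
  fails <- attr(x, "failures")
  if (length(fails))
    cat("Failed fits:\n ", paste(fails, collapse = "\n  "), "\n")
  invisible(x)
}

#' Simulate datasets from a fitted model
#'
#' Draws synthetic replicates of the training design: predictions at the
#' fitted coefficients perturbed by multiplicative lognormal noise whose
#' scale is the standard deviation of the fit's log residuals (or a
#' user-supplied `sigma`).
#'
#' @param object A `"solubility_fit"`.
#' @param nsim Number of replicate datasets.
#' @param seed Optional integer seed.
#' @param sigma Optional lognormal noise scale overriding the residual
#'   estimate.
#' @param ... Unused.
#' @return A list of `nsim` [solubility_data()] objects.
#' @export
simulate.solubility_fit <- function(object, nsim = 1, seed = NULL,
                                    sigma = NULL, ...) {
  if (is.null(sigma)) sigma <- stats::sd(residuals(object, type = "log"))
  r <- object$data$records
  grid <- r[c("T_K", "P_MPa")]
  out <- generate_dataset(model = object$model,
                          params = object$coefficients,
                          grid = grid, noise_sigma = sigma, seed = seed,
                          density = r$rho_kg_m3,
                          solute = object$data$solute,
                          solvent = object$data$solvent,
                          control = object$control,
                          constants = object$fixed_constants,
                          nsim = nsim)
  out
}
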