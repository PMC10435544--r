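## Shared fixtures for the test suite.  Everything is built in code; the
## only file fixture is the bundled solubility table.

## Reference coefficients used as a convenient generating truth for the
## Chrastil correlation (association number, intercept, temperature
## coefficient in K).
CHRASTIL_TRUTH <- c(a0 = 4.8, a1 = -24, a2 = -3608.9)

## Molar masses of the bundled binary system (g/mol).
M_APZ <- 448.39
M_CO2 <- 44.01

## A fast annealing schedule for tests that exercise the fitting path but
## do not need publication-quality optima.
light_control <- function(seed = 1L, n_restarts = 4L, ...) {
  fit_control(seed = seed, n_restarts = n_restarts, sa_t0 = 1,
              sa_cool = 0.9, sa_iter = 25L, sa_tmin = 1e-3, ...)
}

## Small hand-built dataset: same density on every isobar across
## temperatures, mole fractions monotone in T everywhere (no crossover).
flat_rho_dataset <- function() {
  grid <- expand.grid(T_K = c(310, 320, 330), P_MPa = c(10, 20))
  rho <- ifelse(grid$P_MPa == 10, 600, 800)
  y2 <- 1e-6 * (1 + 0.02 * (grid$T_K - 310)) * (rho / 600)
  solubility_data(data.frame(T_K = grid$T_K, P_MPa = grid$P_MPa,
                             rho_kg_m3 = rho, y2 = y2))
}
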