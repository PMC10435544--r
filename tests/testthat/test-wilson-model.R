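test_that("ideal solid solubility has its closed-form limits", {
  cst <- wilson_constants(melting_T = 415.11, fusion_enthalpy = 23450)
  expect_equal(ideal_solubility(415.11, cst), 1)
  ## vanishing fusion enthalpy: no penalty for melting, x_ideal -> 1
  cst0 <- wilson_constants(melting_T = 415.11, fusion_enthalpy = 1e-9)
  expect_equal(ideal_solubility(c(300, 350, 400), cst0), rep(1, 3),
               tolerance = 1e-12)
  ## direct evaluation at 308 K with the Walden-rule enthalpy
  expect_equal(ideal_solubility(308, cst), 0.094, tolerance = 5e-3)
  ## increasing in temperature, bounded by 1
  tt <- seq(300, 415, by = 5)
  xi <- ideal_solubility(tt, cst)
  expect_true(all(diff(xi) > 0) && all(xi <= 1))
  expect_error(ideal_solubility(500, cst), "melting")
})

test_that("Wilson interaction terms follow the reduced-density geometry", {
  cst <- wilson_constants()
  ## reciprocal structure when both interaction energies vanish
  p0 <- c(lam12 = 0, lam21 = 0, alpha = 0, beta = 5e-5)
  lam <- wilson_lambdas(p0, rho = 768.42, T_K = 308, cst)
  expect_equal(lam$L12 * lam$L21, 1, tolerance = 1e-12)
  ## alpha = 0 makes the molar volume density-independent
  expect_equal(wilson_lambdas(p0, 400, 308, cst)$v2,
               wilson_lambdas(p0, 900, 308, cst)$v2)
  expect_error(wilson_lambdas(c(lam12 = 0, lam21 = 0, alpha = -1e-4,
                                beta = 1e-5), 900, 308, cst),
               "positive")
})

test_that("the tabulated Wilson parameters evaluate as the step-by-step oracle", {
  ## independent hand evaluation of the whole chain at 308 K, 768.42 kg/m3
  p <- c(lam12 = -2.78033, lam21 = 16.6667, alpha = -7.87e-6,
         beta = 4.52e-5)
  cst <- wilson_constants(melting_T = 415.11, fusion_enthalpy = 23450)
  rho_r <- 768.42 / 467.6
  t_r <- 308 / 304.18
  v2 <- -7.87e-6 * rho_r + 4.52e-5
  expect_equal(rho_r, 1.643, tolerance = 1e-3)
  expect_equal(t_r, 1.0126, tolerance = 1e-4)
  expect_equal(v2, 3.23e-5, tolerance = 1e-2)
  g <- v2 * 10625 * rho_r
  L12_ref <- g * exp(2.78033 / t_r)
  L21_ref <- exp(-16.6667 / t_r) / g
  lam <- wilson_lambdas(p, 768.42, 308, cst)
  expect_equal(lam$L12, L12_ref, tolerance = 1e-12)
  expect_equal(lam$L21, L21_ref, tolerance = 1e-12)
  gamma_ref <- exp(1 - L12_ref - log(L21_ref))
  expect_equal(gamma_infinity(lam$L12, lam$L21), gamma_ref,
               tolerance = 1e-12)
  expect_equal(predict_y2_wilson(p, 308, 768.42, cst),
               ideal_solubility(308, cst) / gamma_ref, tolerance = 1e-12)
})

test_that("activity coefficient closed forms and domain errors hold", {
  expect_equal(gamma_infinity(1, 1), 1)
  expect_equal(gamma_infinity(1, exp(1)), exp(-1))
  expect_error(gamma_infinity(-1, 1), "positive")
  expect_error(gamma_infinity(1, 0), "positive")
})

test_that("unit activity coefficient reduces the model to ideal solubility", {
  cst <- wilson_constants()
  ## choose alpha = 0 and beta so that v2 rho_cl rho_r = 1: with zero
  ## interaction energies both Lambdas are 1 and gamma_inf = 1
  rho <- 700
  rho_r <- rho / cst$solvent_critical_mass_density
  beta <- 1 / (cst$solvent_critical_molar_density * rho_r)
  p <- c(lam12 = 0, lam21 = 0, alpha = 0, beta = beta)
  expect_equal(predict_y2_wilson(p, 330, rho, cst),
               ideal_solubility(330, cst), tolerance = 1e-12)
  expect_equal(predict_y2_wilson(p, cst$melting_T,
                                 cst$solvent_critical_mass_density * rho_r,
                                 cst), 1, tolerance = 1e-12)
})

test_that("Wilson predictions are finite and continuous over the data range", {
  d <- aripiprazole_scco2()
  p <- c(lam12 = -2.78033, lam21 = 16.6667, alpha = -7.87e-6,
         beta = 4.52e-5)
  cst <- wilson_constants(melting_T = 415.11, fusion_enthalpy = 23450)
  y <- predict_y2_wilson(p, d$records$T_K, d$records$rho_kg_m3, cst)
  expect_true(all(is.finite(y) & y > 0))
  ## small perturbations in T and rho move the prediction smoothly
  base <- predict_y2_wilson(p, 320, 700, cst)
  eps <- predict_y2_wilson(p, 320 + 1e-5, 700 + 1e-4, cst)
  expect_equal(base, eps, tolerance = 1e-4)
})
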