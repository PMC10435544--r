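test_that("the fitting objective penalizes invalid parameter regions", {
  d <- aripiprazole_scco2()
  ctrl <- light_control()
  ## a perfect Wilson-volume violation: v2 < 0 everywhere
  bad <- c(lam12 = 0, lam21 = 0, alpha = -1e-4, beta = 1e-6)
  expect_identical(objective_aard("wilson", bad, d, ctrl), ctrl$penalty)
  ## a valid chrastil vector scores its AARD
  v <- objective_aard("chrastil", CHRASTIL_TRUTH, d, ctrl)
  expect_true(is.finite(v) && v > 0 && v < 100)
  expect_error(objective_aard("chrastil", c(1, 2), d, ctrl),
               "free parameters")
})

test_that("noise-free synthetic data is recovered to optimizer precision", {
  synth <- generate_dataset("chrastil", CHRASTIL_TRUTH, noise_sigma = 0,
                            seed = 5)
  f <- fit_solubility(synth, "chrastil", light_control())
  expect_lt(f$aard_pct, 0.01)
  expect_equal(unname(coef(f)), unname(CHRASTIL_TRUTH), tolerance = 1e-3)
  expect_gt(f$r_adj, 0.9999)
})

test_that("fits are bit-identical under a fixed seed", {
  d <- aripiprazole_scco2()
  f1 <- fit_solubility(d, "kj", light_control(seed = 3))
  f2 <- fit_solubility(d, "kj", light_control(seed = 3))
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$aard_pct, f2$aard_pct)
  expect_identical(f1$residuals, f2$residuals)
  ## the fit restores the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(fit_solubility(d, "kj", light_control()))
  expect_identical(runif(3), before)
})

test_that("more restarts never worsen the best objective", {
  d <- aripiprazole_scco2()
  f2 <- fit_solubility(d, "mst", light_control(seed = 2, n_restarts = 2))
  f6 <- fit_solubility(d, "mst", light_control(seed = 2, n_restarts = 6))
  expect_lte(f6$aard_pct, f2$aard_pct)
})

test_that("the simplex polish only improves on the annealed objective", {
  d <- aripiprazole_scco2()
  for (m in c("chrastil", "jouyban")) {
    f <- fit_solubility(d, m, light_control())
    expect_lte(f$aard_pct, f$sa_aard_pct)
  }
})

test_that("fit_all_models ranks models by AARD and survives failures", {
  synth <- generate_dataset("chrastil", CHRASTIL_TRUTH, noise_sigma = 0,
                            seed = 5)
  fits <- fit_all_models(synth, models = c("bartle", "chrastil", "kj"),
                         control = light_control())
  av <- vapply(fits, function(f) f$aard_pct, 0)
  expect_identical(av, sort(av))
  ## the generating model wins on its own noise-free data
  expect_identical(fits[[1]]$model, "chrastil")
  expect_lt(fits[[1]]$aard_pct, 0.01)
})

test_that("invalid bounds and hopeless boxes raise clear errors", {
  d <- aripiprazole_scco2()
  expect_error(fit_solubility(d, "chrastil", light_control(),
                              bounds = list(lower = c(0, 0), upper = c(1, 1))),
               "length")
  expect_error(fit_solubility(d, "chrastil", light_control(),
                              bounds = list(lower = c(1, 1, 1),
                                            upper = c(0, 2, 2))),
               "exceed")
  ## a box in which the Wilson volume is negative everywhere
  expect_error(
    fit_solubility(d, "wilson", light_control(),
                   bounds = list(lower = c(-1, -1, -1e-4, -2e-4),
                                 upper = c(1, 1, -5e-5, -1e-4))),
    "restarts")
})

test_that("fit methods expose predictions, residuals and simulations", {
  d <- aripiprazole_scco2()
  f <- fit_solubility(d, "chrastil", light_control())
  expect_identical(predict(f), fitted(f))
  expect_identical(nobs(f), 28L)
  nd <- data.frame(T_K = 318, P_MPa = 15, rho_kg_m3 = 743.17)
  expect_equal(predict(f, nd),
               predict_y2("chrastil", unname(coef(f)), 318, 15, 743.17,
                          M_APZ, M_CO2), tolerance = 1e-14)
  expect_error(predict(f, data.frame(T_K = 318)), "lacks")

  rel <- residuals(f)
  y <- d$records$y2
  expect_equal(rel, (fitted(f) - y) / y)
  expect_equal(residuals(f, "response"), fitted(f) - y)
  expect_equal(residuals(f, "log"), log(fitted(f) / y))

  sims <- simulate(f, nsim = 2, seed = 7)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "solubility_data")
  sims2 <- simulate(f, nsim = 2, seed = 7)
  expect_identical(sims[[1]]$records, sims2[[1]]$records)

  ## printing is stable and informative
  expect_output(print(f), "Chrastil")
  expect_output(print(summary(f)), "AARD")
})
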