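test_that("model registry exposes the documented parameter counts", {
  reg <- solubility_models()
  counts <- setNames(reg$z, reg$id)
  expect_identical(counts[c("chrastil", "bartle", "kj", "mst")],
                   c(chrastil = 3L, bartle = 3L, kj = 3L, mst = 3L))
  expect_identical(counts[c("sodeifian", "jouyban")],
                   c(sodeifian = 6L, jouyban = 6L))
  expect_error(evaluate_model("nope", c(1, 2, 3), 308, 12, 768),
               "unknown model")
  expect_error(evaluate_model("chrastil", c(1, 2), 308, 12, 768),
               "expects 3")
})

test_that("the Chrastil chain reproduces a hand-evaluated worked example", {
  ## ln s = a0 ln(rho) + a1 + a2/T evaluated with independent arithmetic
  ln_s <- 4.8 * log(768.42) - 24 - 3608.9 / 308
  expect_equal(ln_s, -3.824, tolerance = 2e-4)
  expect_equal(evaluate_model("chrastil", CHRASTIL_TRUTH, 308, 12, 768.42),
               ln_s, tolerance = 1e-14)
  ## back through the mass-solubility conversion: s ~ 0.0219 g/L,
  ## y2 ~ 2.8e-6, within ~8% of the measured 3.03e-6
  s <- exp(ln_s)
  expect_equal(s, 0.0219, tolerance = 5e-3)
  y2 <- predict_y2("chrastil", CHRASTIL_TRUTH, 308, 12, 768.42,
                   M_APZ, M_CO2)
  expect_equal(y2, s * M_CO2 / (768.42 * M_APZ + s * M_CO2),
               tolerance = 1e-14)
  expect_equal(y2, 2.8e-6, tolerance = 0.01)
})

test_that("degenerate parameter vectors collapse to their closed forms", {
  for (m in c("chrastil", "bartle", "kj", "mst")) {
    expect_identical(evaluate_model(m, c(0, 0, 0), 310, 15, 700), 0)
  }
  expect_identical(evaluate_model("sodeifian", rep(0, 5), 310, 15, 700), 0)
  expect_identical(evaluate_model("jouyban", rep(0, 6), 310, 15, 700), 0)
  ## every log term vanishes at rho = 1, T = 1
  p <- c(a0 = 1.5, a1 = 7, a2 = -2, a3 = 0.25, a4 = 9)
  expect_equal(evaluate_model("sodeifian", p, 1, 15, 1),
               p[["a0"]] + p[["a3"]])
})

test_that("a one-point Bartle interpolation recovers the record exactly", {
  y <- 4.67e-6; pres <- 18; temp <- 308; rho <- 848.87
  a0 <- log(y * pres / 0.1)
  expect_equal(predict_y2("bartle", c(a0, 0, 0), temp, pres, rho,
                          M_APZ, M_CO2), y, tolerance = 1e-12)
  ## the literal typeset reading divides by rho_ref instead of P_ref
  a0_lit <- log(y * pres / 700)
  expect_equal(predict_y2("bartle", c(a0_lit, 0, 0), temp, pres, rho,
                          M_APZ, M_CO2, bartle_form = "literal"),
               y, tolerance = 1e-12)
})

test_that("back-transformations agree with independently coded forms", {
  ## an independently written transform chain per fit space, checked on
  ## random parameter/condition draws
  set.seed(101)
  reg <- solubility_models()
  for (i in 1:200) {
    temp <- runif(1, 305, 340); pres <- runif(1, 10, 32)
    rho <- runif(1, 350, 950)
    for (m in setdiff(reg$id, "wilson")) {
      k <- reg$n_coef[reg$id == m]
      par <- runif(k, -1, 1) * c(5, 0.01, 1, 1e-3, 0.1, 1)[seq_len(k)]
      v <- evaluate_model(m, par, temp, pres, rho)
      ref <- switch(m,
        chrastil = ,
        kj = exp(v) * M_CO2 / (rho * M_APZ + exp(v) * M_CO2),
        bartle = exp(v) * 0.1 / pres,
        mst = exp(v / temp) / pres,
        sodeifian = ,
        jouyban = exp(v))
      expect_equal(predict_y2(m, par, temp, pres, rho, M_APZ, M_CO2),
                   ref, tolerance = 1e-13)
    }
    ## the plain MST reading divides out P without the 1/T scaling
    par3 <- runif(3, -1, 1)
    expect_equal(predict_y2("mst", par3, temp, pres, rho, M_APZ, M_CO2,
                            mst_classic = FALSE),
                 exp(evaluate_model("mst", par3, temp, pres, rho)) / pres,
                 tolerance = 1e-13)
  }
})

test_that("model evaluation is pure and monotone where theory says so", {
  p <- CHRASTIL_TRUTH
  a <- evaluate_model("chrastil", p, 318, 15, 743.17)
  b <- evaluate_model("chrastil", p, 318, 15, 743.17)
  expect_identical(a, b)
  ## positive association number: solubility rises with density at fixed T
  rr <- seq(400, 900, by = 25)
  y_chr <- predict_y2("chrastil", c(4.8, -24, -3608.9), 318, 15, rr,
                      M_APZ, M_CO2)
  expect_true(all(diff(y_chr) > 0))
  y_kj <- predict_y2("kj", c(3.4, 0.006, -3674), 318, 15, rr,
                     M_APZ, M_CO2)
  expect_true(all(diff(y_kj) > 0))
})
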