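test_that("sampling mole fraction follows the vial/loop mole balance", {
  ## independent arithmetic oracle, evaluated step by step
  C_s <- 0.01; V_vial <- 0.005; V_loop <- 600e-6; rho <- 768.42
  n_solute <- C_s * V_vial / M_APZ
  n_co2 <- V_loop * rho / M_CO2
  expect_equal(
    mole_fraction_from_sampling(C_s, V_vial, V_loop, rho, M_APZ, M_CO2),
    n_solute / (n_solute + n_co2), tolerance = 1e-14)

  ## zero solute is a valid boundary for the op (datasets reject it later)
  expect_identical(
    mole_fraction_from_sampling(0, V_vial, V_loop, rho, M_APZ, M_CO2), 0)

  ## constructed symmetry: equal mole numbers give y2 = 1/2
  expect_equal(
    mole_fraction_from_sampling(C_s = M_APZ, V_vial = 1, V_loop = 1,
                                rho = M_CO2, M_APZ, M_CO2), 0.5)

  expect_error(mole_fraction_from_sampling(0.01, -1, V_loop, rho,
                                           M_APZ, M_CO2), "positive")
})

test_that("mass solubility conversion reproduces tabulated spot values", {
  ## S x 10 printed as 0.237 at 308 K / 12 MPa and 0.855 at 338 K / 30 MPa
  expect_equal(s_from_y2(768.42, 3.03e-6, M_APZ, M_CO2), 0.0237,
               tolerance = 0.0002 / 0.0237)
  expect_equal(s_from_y2(809.58, 1.036e-5, M_APZ, M_CO2), 0.0855,
               tolerance = 0.0002 / 0.0855)
  expect_identical(s_from_y2(768.42, 0, M_APZ, M_CO2), 0)
  expect_error(s_from_y2(768.42, 1, M_APZ, M_CO2), "y2")
  expect_error(s_from_y2(-1, 0.5, M_APZ, M_CO2), "rho")
})

test_that("mole-fraction/mass conversions are exact inverses and monotone", {
  set.seed(11)
  y <- runif(200, 1e-9, 0.0999)
  rho <- runif(200, 300, 1000)
  s <- s_from_y2(rho, y, M_APZ, M_CO2)
  expect_equal(y2_from_s(s, rho, M_APZ, M_CO2), y, tolerance = 1e-12)
  expect_equal(y2_from_s(0, 500, M_APZ, M_CO2), 0)
  ## inverse of the tabulated spot value
  expect_equal(y2_from_s(0.0237, 768.42, M_APZ, M_CO2), 3.03e-6,
               tolerance = 1e-3)
  ## strictly increasing in y2 and in rho
  yy <- sort(runif(50, 1e-8, 0.09))
  expect_true(all(diff(s_from_y2(700, yy, M_APZ, M_CO2)) > 0))
  rr <- sort(runif(50, 300, 1000))
  expect_true(all(diff(s_from_y2(rr, 1e-5, M_APZ, M_CO2)) > 0))
  expect_error(y2_from_s(-0.1, 700, M_APZ, M_CO2), "non-negative")
})

test_that("expanded uncertainty combines relative uncertainties in quadrature", {
  ## direct formula evaluation, compared to the tabulated 0.306e-6 value
  sd_y <- 0.015e-5; y <- 0.303e-5
  u_rel <- sqrt((sd_y / y)^2 + (0.1 / 308)^2 + (1 / 120)^2)
  expect_equal(expanded_uncertainty(sd_y, y, 0.1, 308, 1, 120, 2),
               2 * y * u_rel, tolerance = 1e-14)
  expect_equal(expanded_uncertainty(sd_y, y, 0.1, 308, 1, 120, 2),
               0.306e-6, tolerance = 0.05)

  expect_identical(expanded_uncertainty(0, y, 0, 308, 0, 120, 2), 0)
  ## linear in the coverage factor
  u1 <- expanded_uncertainty(sd_y, y, 0.1, 308, 1, 120, coverage_k = 1)
  expect_equal(expanded_uncertainty(sd_y, y, 0.1, 308, 1, 120,
                                    coverage_k = 2), 2 * u1)
  expect_error(expanded_uncertainty(sd_y, 0, 0.1, 308, 1, 120), "non-zero")
})

test_that("the bundled dataset loads with the published structure", {
  d <- aripiprazole_scco2()
  r <- d$records
  expect_s3_class(d, "solubility_data")
  expect_identical(nrow(r), 28L)
  expect_identical(length(unique(r$T_K)), 4L)
  expect_identical(length(unique(r$P_MPa)), 7L)

  ## extreme mole fractions and where they occur
  expect_equal(min(r$y2), 1.83e-6)
  expect_equal(max(r$y2), 1.036e-5)
  expect_equal(unlist(r[which.min(r$y2), c("T_K", "P_MPa")]),
               c(T_K = 338, P_MPa = 12))
  expect_equal(unlist(r[which.max(r$y2), c("T_K", "P_MPa")]),
               c(T_K = 338, P_MPa = 30))

  ## the printed mass-solubility column agrees with the conversion
  s_calc <- s_from_y2(r$rho_kg_m3, r$y2, M_APZ, M_CO2)
  expect_lt(max(abs(s_calc - r$S_gL) / s_calc), 0.01)
  expect_true(all(abs(10 * s_calc - 10 * r$S_gL) <= 0.002))
})

test_that("dataset validation reports distinct, row-level errors", {
  good <- data.frame(T_K = c(308, 318), P_MPa = c(12, 12),
                     rho_kg_m3 = c(768, 660), y2 = c(3e-6, 2.6e-6))
  expect_s3_class(solubility_data(good), "solubility_data")

  bad_y <- good; bad_y$y2[2] <- 1.5
  expect_error(solubility_data(bad_y), "row 2.*between 0 and 1")

  dup <- good; dup$T_K[2] <- 308
  expect_error(solubility_data(dup), "duplicate")

  tmp <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(good[c("T_K", "P_MPa", "y2")], tmp, row.names = FALSE)
  expect_error(read_solubility_data(tmp), "rho_kg_m3")

  writeLines("", tmp)
  expect_error(read_solubility_data(tmp), "T_K")

  ## an inconsistent S column is caught with the offending row named
  bad_s <- good
  bad_s$S_gL <- s_from_y2(bad_s$rho_kg_m3, bad_s$y2, M_APZ, M_CO2)
  bad_s$S_gL[1] <- bad_s$S_gL[1] * 1.2
  expect_error(solubility_data(bad_s), "row 1.*S column")
})

test_that("physical-property constructors enforce their invariants", {
  expect_error(solute_properties("x", 100, melting_T = 500, boiling_T = 400,
                                 critical_T = 900, critical_P = 10,
                                 acentric_factor = 0.3, molar_volume = 100),
               "melting_T < boiling_T")
  expect_error(solvent_properties("c", 44.01, 304.18, 73.8, 467.6,
                                  critical_molar_density = 99999),
               "inconsistent")
  co2 <- co2_properties()
  expect_equal(co2$critical_molar_density,
               co2$critical_mass_density / co2$molar_mass * 1000,
               tolerance = 1e-3)
  apz <- apz_properties()
  expect_true(apz$melting_T < apz$boiling_T &&
                apz$boiling_T < apz$critical_T)
})
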