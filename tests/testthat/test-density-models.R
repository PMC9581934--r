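test_that("density-model predictors evaluate their closed forms", {
  ## Chrastil: unit association number and zero constants give y2 = 1/2
  expect_equal(chrastil_predict(c(kappa = 1, A1 = 0, B1 = 0), 310, 850), 0.5)
  ## strictly increasing in density when kappa > 1
  rho <- seq(400, 900, by = 50)
  y <- chrastil_predict(c(kappa = 4, A1 = -20, B1 = -3700), 318, rho)
  expect_true(all(diff(y) > 0))
  ## published parameters at the 308 K / 12 MPa state (log-domain arithmetic:
  ## ln g = 3.0042 ln 769 - 20.368 - 3677.8/308)
  g <- exp(3.0042 * log(769) - 20.368 - 3677.8 / 308)
  expect_equal(chrastil_predict(c(kappa = 4.0042, A1 = -20.368, B1 = -3677.8),
                                308, 769),
               g / (1 + g), tolerance = 1e-12)
  expect_equal(g / (1 + g), 4.36e-6, tolerance = 0.01)

  ## modified Chrastil: kappa' = 1 is density-independent
  p <- c(kappa_prime = 1, A2 = -12, B2 = 0)
  expect_equal(modified_chrastil_predict(p, 318, 500),
               modified_chrastil_predict(p, 318, 900))
  ## rescaling the standard fugacity is absorbed entirely by A2
  p1 <- list(kappa_prime = 4.0048, A2 = -35.727, B2 = -2709, f_std = 1)
  p10 <- list(kappa_prime = 4.0048, A2 = -35.727 + (4.0048 - 1) * log(10),
              B2 = -2709, f_std = 10)
  expect_equal(modified_chrastil_predict(p1, 308, 769),
               modified_chrastil_predict(p10, 308, 769), tolerance = 1e-10)

  ## MT: left-hand side at the first fixture record vs the published line
  lhs <- mt_lhs(308, 12, 0.483e-5)
  expect_equal(lhs, 308 * log(0.483e-5 * 12), tolerance = 1e-12)
  rhs <- -7921.4 + 2.5303 * 769 + 9.6455 * 308
  expect_equal(lhs, rhs, tolerance = 1e-3)  # relative; both ~ -3005 K
  ## B3 = C3 = 0 degenerate form
  expect_equal(mt_predict(c(A3 = -3000, B3 = 0, C3 = 0), 310, 15, 700),
               exp(-3000 / 310) / 15)

  ## Bartle: published parameters reproduce the measured 308 K / 12 MPa point
  pb <- c(A4 = 11.249, B4 = -5918.3, C4 = 7.4427e-3)
  expect_equal(bartle_predict(pb, 308, 12, 769), 0.483e-5, tolerance = 0.01)
  ## at the reference density with B4 = 0 the exponential collapses
  expect_equal(bartle_predict(c(A4 = 2, B4 = 0, C4 = 5e-3), 310, 10, 700),
               0.1 / 10 * exp(2))
  expect_true(all(diff(bartle_predict(pb, 318, 15, rho)) > 0))
})

test_that("MT self-consistency: isotherms collapse onto one line in density", {
  d <- crizotinib_dataset()
  fit <- cached_density_fit("mt")
  collapsed <- mt_lhs(d$temperature_K, d$pressure_MPa, d$y2) -
    fit$params[["C3"]] * d$temperature_K
  line <- fit$params[["A3"]] + fit$params[["B3"]] * d$co2_density_kg_m3
  spread <- sd(collapsed - line) / diff(range(collapsed))
  expect_lt(spread, 0.05)
})

test_that("fitting the crizotinib data reproduces the published parameter sets", {
  fc <- cached_density_fit("chrastil")
  expect_equal(fc$params[["kappa"]], 4.0042, tolerance = 1e-3)
  expect_equal(fc$params[["A1"]], -20.368, tolerance = 1e-3)
  expect_equal(fc$params[["B1"]], -3677.8, tolerance = 1e-3)
  expect_equal(fc$aard_percent, 6.97, tolerance = 0.01)
  expect_gt(fc$r2, fc$r2_adj)

  fm <- cached_density_fit("mchrastil")
  expect_equal(fm$params[["kappa_prime"]], 4.0048, tolerance = 1e-3)
  expect_equal(fm$params[["B2"]], -2709, tolerance = 1e-3)

  fmt <- cached_density_fit("mt")
  expect_equal(fmt$params[["A3"]], -7921.4, tolerance = 1e-4)
  expect_equal(fmt$params[["B3"]], 2.5303, tolerance = 1e-3)
  expect_equal(fmt$params[["C3"]], 9.6455, tolerance = 1e-3)

  fb <- cached_density_fit("bartle")
  expect_equal(fb$params[["A4"]], 11.249, tolerance = 1e-3)
  expect_equal(fb$params[["B4"]], -5918.3, tolerance = 1e-3)
  expect_equal(fb$params[["C4"]], 7.4427e-3, tolerance = 1e-2)

  ## all four predictors stay inside (0, 1) over the fixture conditions
  for (f in list(fc, fm, fmt, fb)) {
    expect_true(all(f$predicted > 0 & f$predicted < 1))
  }
})

test_that("the fit is robust to restarts and rejects underdetermined data", {
  d <- crizotinib_dataset()
  fit <- cached_density_fit("chrastil")
  ## random perturbed restarts never improve the objective materially
  set.seed(11)
  for (i in 1:20) {
    init <- fit$params * runif(3, 0.9, 1.1)
    refit <- fit_density_model("chrastil", d, init = init)
    expect_gte(refit$of_value, fit$of_value * (1 - 1e-6))
  }
  expect_error(fit_density_model("chrastil", d[1:2, ]), "at least")
  expect_error(fit_density_model("nonsense", d))
})

test_that("noise-free synthetic data returns the generating parameters", {
  truth <- c(kappa = 4, A1 = -20, B1 = -3700)
  spec <- generator_spec(truth = function(T, P, rho)
    chrastil_predict(truth, T, rho), noise_cv = 0, seed = 3)
  d <- generate_dataset(spec)
  fit <- fit_density_model("chrastil", d)
  expect_equal(unname(fit$params), unname(truth), tolerance = 1e-4)
  expect_lt(fit$aard_percent, 1e-4)
})

test_that("dissolution enthalpies follow from the 1/T coefficients", {
  fc <- cached_density_fit("chrastil")
  fm <- cached_density_fit("mchrastil")
  fb <- cached_density_fit("bartle")
  h <- dissolution_enthalpies(fc, fb)
  expect_equal(h$total, -fc$params[["B1"]] * 8.314 / 1000, tolerance = 1e-12)
  expect_equal(h$solvation, h$total - h$sublimation, tolerance = 1e-12)
  h2 <- dissolution_enthalpies(fm, fb)
  expect_equal(h2$total, -fm$params[["B2"]] * 8.314 / 1000, tolerance = 1e-12)
  ## a zero coefficient gives zero enthalpy
  fz <- fc; fz$params[["B1"]] <- 0
  expect_equal(dissolution_enthalpies(fz, fb)$total, 0)
  expect_error(dissolution_enthalpies(fb, fb), "Chrastil")
  expect_error(dissolution_enthalpies(fc, fc), "Bartle")
})
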