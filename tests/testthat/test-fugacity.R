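test_that("analytic fugacity coefficients match the volume-integral oracle", {
  ## the central correctness property of the analytic expressions: agreement
  ## with direct quadrature of the thermodynamic definition over a grid
  ## spanning the study's (T, P) range, for every variant
  Ts <- c(308, 318, 328, 338)
  Ps <- c(12e6, 18e6, 27e6)
  y <- 1e-5
  for (variant in c("RK", "PR", "SRK3", "SRK4")) {
    pure <- pure_pair(variant)
    inter <- default_interaction(variant)
    for (T in Ts) for (P in Ps) {
      fa <- fugacity_coeff(variant, c(1 - y, y), T, P, pure, inter)
      fn <- fugacity_coeff_numeric(variant, c(1 - y, y), T, P, pure, inter)
      expect_gt(fa, 0)
      expect_lt(abs(fa - fn) / fn, 1e-5)
    }
  }
})

test_that("the pure-solvent limit recovers the textbook pure fugacity coefficient", {
  ## textbook pure-component forms: for the SRK/RK shape
  ## ln(phi) = Z - 1 - ln(Z - B*) - (A*/B*) ln(1 + B*/Z), and the PR analogue
  ## with the 1 +/- sqrt(2) denominator split
  R <- 8.314
  for (variant in c("RK", "SRK3", "SRK4", "PR")) {
    pure <- pure_pair(variant)
    inter <- default_interaction(variant)
    T <- 318; P <- 15e6
    p1 <- pure[[1]]
    E <- switch(variant,
                RK = p1$a / sqrt(T),
                PR = ,
                SRK3 = p1$a + p1$c * R * T - 2 * sqrt(p1$a * p1$c * R * T),
                SRK4 = p1$a + p1$c * R * T - p1$d * R * sqrt(T))
    st <- solve_Z(variant, p1, T, P)
    Z <- st$Z; v <- st$v
    As <- E * P / (R * T)^2; Bs <- p1$b * P / (R * T)
    ln_phi_ref <- if (variant == "PR") {
      s2 <- sqrt(2)
      Z - 1 - log(Z - Bs) - As / (2 * s2 * Bs) *
        log((Z + (1 + s2) * Bs) / (Z + (1 - s2) * Bs))
    } else {
      Z - 1 - log(Z - Bs) - As / Bs * log(1 + Bs / Z)
    }
    phi <- fugacity_coeff(variant, c(1, 0), T, P, pure, inter, i = 1)
    expect_equal(log(phi), ln_phi_ref, tolerance = 1e-8)
  }
})

test_that("fugacity coefficients approach unity in the ideal-gas limit", {
  for (variant in c("RK", "PR", "SRK3", "SRK4")) {
    pure <- pure_pair(variant)
    inter <- default_interaction(variant)
    phi <- fugacity_coeff(variant, c(1 - 1e-5, 1e-5), 318, 1e-2, pure, inter)
    expect_equal(phi, 1, tolerance = 1e-4)
    phin <- fugacity_coeff_numeric(variant, c(1 - 1e-5, 1e-5), 318, 1e-2,
                                   pure, inter)
    expect_equal(phin, 1, tolerance = 1e-4)
  }
})

test_that("the four-constant SRK form nests the three-constant one", {
  ## an SRK3 decomposition (a(Tc), m) is reproduced exactly by SRK4-style
  ## constants with m' = m, n' = m (1 + m); at the pure vertices the
  ## fugacity coefficients must then coincide
  R <- 8.314
  srk4_from_srk3 <- function(props) {
    w <- props$omega
    m <- 0.48 + 1.574 * w - 0.176 * w^2
    n <- m * (1 + m)
    aTc <- 0.42748 * R^2 * props$Tc^2 / props$Pc
    structure(list(a = aTc * (1 + m + n),
                   b = 0.08664 * R * props$Tc / props$Pc,
                   c = aTc * (n - m) / (R * props$Tc),
                   d = 2 * n * aTc / (R * sqrt(props$Tc)),
                   variant = "SRK4", name = props$name),
              class = "pure_km_constants")
  }
  p3 <- pure_pair("SRK3")
  p4 <- list(srk4_from_srk3(co2_properties()),
             srk4_from_srk3(crizotinib_properties()))
  i3 <- km_interaction("SRK3", 0.1, -0.1, 0.2)
  i4 <- km_interaction("SRK4", 0.1, -0.1, 0.2, 0.2)
  for (x in list(c(1, 0), c(0, 1))) {
    i_comp <- if (x[1] == 1) 1L else 2L
    phi3 <- fugacity_coeff("SRK3", x, 318, 18e6, p3, i3, i = i_comp)
    phi4 <- fugacity_coeff("SRK4", x, 318, 18e6, p4, i4, i = i_comp)
    expect_equal(phi4, phi3, tolerance = 1e-8)
  }
})

test_that("the solubility solve reduces to the Poynting closed form when phi = 1", {
  model <- eos_solubility_model("SRK3", km_interaction("SRK3", 0, 0, 0),
                                crizotinib_properties(), co2_properties())
  ## phi = 1 and the printed solid molar volume: one analytic evaluation
  y <- solve_solubility(model, 308, 12e6, phi_fixed = 1)
  kernel <- (1072 / 12e6) * exp((12e6 - 1072) * 32.12e-6 / (8.314 * 308))
  expect_equal(y, kernel, tolerance = 1e-9)
  expect_equal(y, 1.04e-4, tolerance = 0.01)

  ## with zero solid volume the Poynting factor disappears entirely
  props0 <- component_properties("x", 485.25, 14.102e6, 0.4394,
                                 v_solid = 1e-300,
                                 p_sub = c("308" = 1072))
  m0 <- eos_solubility_model("SRK3", km_interaction("SRK3", 0, 0, 0),
                             props0, co2_properties())
  expect_equal(solve_solubility(m0, 308, 12e6, phi_fixed = 1), 1072 / 12e6,
               tolerance = 1e-12)

  ## pressure below the sublimation pressure is rejected
  expect_error(solve_solubility(model, 308, 500), "exceed")
})

test_that("the converged solubility satisfies the fixed-point relation", {
  model <- eos_solubility_model("SRK3", km_interaction("SRK3", 0.1, -0.1, 0.2),
                                crizotinib_properties(), co2_properties())
  for (P in c(12e6, 21e6)) {
    y <- solve_solubility(model, 318, P)
    expect_gt(y, 0); expect_lt(y, 1)
    phi <- fugacity_coeff("SRK3", c(1 - y, y), 318, P,
                          model$pure, model$interaction)
    P_s <- 1628
    rhs <- P_s / P * exp((P - P_s) * 32.12e-6 / (8.314 * 318)) / phi
    expect_equal(y, rhs, tolerance = 1e-8)
  }
  ## solubility vanishes with the sublimation pressure
  small <- component_properties("x", 485.25, 14.102e6, 0.4394,
                                v_solid = 32.12e-6,
                                p_sub = c("318" = 1e-6))
  msmall <- eos_solubility_model("SRK3", km_interaction("SRK3", 0.1, -0.1, 0.2),
                                 small, co2_properties())
  expect_lt(solve_solubility(msmall, 318, 12e6), 1e-11)
})

test_that("interaction fitting recovers known parameters from noise-free data", {
  truth <- km_interaction("SRK3", 0.12, -0.08, 0.25)
  model <- eos_solubility_model("SRK3", truth, crizotinib_properties(),
                                co2_properties())
  d0 <- crizotinib_dataset()
  y_true <- predict_solubility(model, d0)
  d <- solubility_dataset(
    data.frame(temperature_K = d0$temperature_K,
               pressure_MPa = d0$pressure_MPa,
               co2_density_kg_m3 = d0$co2_density_kg_m3, y2 = y_true),
    solute = "synthetic")
  fit <- fit_interaction("SRK3", d, n_starts = 2, seed = 5,
                         extra_starts = rbind(c(0.1, -0.1, 0.2)),
                         reltol = 1e-10, maxit = 2000)
  expect_lt(fit$aard_percent, 0.5)
  ## descent property: starting from the solution never worsens it
  refit <- fit_interaction("SRK3", d, n_starts = 0,
                           extra_starts = rbind(unname(fit$params)),
                           reltol = 1e-10, maxit = 2000)
  expect_lte(refit$of_value, fit$of_value * (1 + 1e-9))
})
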