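## Synthetic solubility datasets with known ground truth, for
## parameter-recovery and robustness studies, plus the crossover-pressure
## locator.

#' Specification for a synthetic solubility dataset
#'
#' Describes a (temperature x pressure) measurement grid, the solvent
#' density at each grid point, a ground-truth solubility model and a
#' multiplicative noise level. Defaults emulate the crizotinib study: the
#' 4 x 6 grid (308-338 K, 12-27 MPa) with the published CO2 densities.
#'
#' @param temperatures isotherm temperatures, K.
#' @param pressures pressures, MPa.
#' @param density_fun function `(T, P) -> kg m^-3`; the default looks up the
#'   crizotinib-study density grid.
#' @param truth a fitted model (anything with a `predict` method over a
#'   dataset-shaped data.frame) or a function `(T, P, rho) -> y2`.
#' @param noise_cv coefficient of variation of the multiplicative Gaussian
#'   noise (>= 0).
#' @param seed integer seed.
#' @export
generator_spec <- function(temperatures = c(308, 318, 328, 338),
                           pressures = c(12, 15, 18, 21, 24, 27),
                           density_fun = NULL,
                           truth, noise_cv = 0.02, seed = 1L) {
  stopifnot(length(temperatures) >= 1, length(pressures) >= 1, noise_cv >= 0)
  if (is.null(density_fun)) {
    fixture <- crizotinib_dataset()
    density_fun <- function(T, P) {
      rho <- mapply(function(Ti, Pi) {
        iso <- fixture[abs(fixture$temperature_K - Ti) < 1e-9, ]
        if (!nrow(iso)) stop("no fixture isotherm at T = ", Ti, " K")
        approx(iso$pressure_MPa, iso$co2_density_kg_m3, xout = Pi,
               rule = 2)$y
      }, T, P)
      as.numeric(rho)
    }
  }
  structure(list(temperatures = temperatures, pressures = pressures,
                 density_fun = density_fun, truth = truth,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "generator_spec")
}

## evaluate the ground-truth model on grid vectors
.truth_predict <- function(truth, T, P, rho) {
  if (is.function(truth)) return(truth(T, P, rho))
  predict(truth, data.frame(temperature_K = T, pressure_MPa = P,
                            co2_density_kg_m3 = rho))
}

#' Generate a synthetic solubility dataset
#'
#' Evaluates the ground-truth model on the full grid and perturbs each point
#' with independent multiplicative Gaussian noise,
#' `y2 = truth * (1 + eps)`, `eps ~ N(0, noise_cv)`; non-positive draws are
#' redrawn. Deterministic under the spec's seed.
#'
#' @param spec a [generator_spec()].
#' @return a [solubility_dataset()] tagged as synthetic.
#' @export
generate_dataset <- function(spec) {
  grid <- expand.grid(pressure_MPa = spec$pressures,
                      temperature_K = spec$temperatures)
  T <- grid$temperature_K; P <- grid$pressure_MPa
  rho <- spec$density_fun(T, P)
  y_true <- .truth_predict(spec$truth, T, P, rho)
  if (any(!is.finite(y_true)) || any(y_true <= 0))
    stop("truth model returned non-finite or non-positive solubility")
  set.seed(spec$seed)
  y <- y_true * (1 + rnorm(length(y_true), 0, spec$noise_cv))
  for (tries in 1:100) {
    bad <- y <= 0
    if (!any(bad)) break
    y[bad] <- y_true[bad] * (1 + rnorm(sum(bad), 0, spec$noise_cv))
  }
  if (any(y <= 0)) stop("could not draw positive noisy solubilities")
  solubility_dataset(
    data.frame(temperature_K = T, pressure_MPa = P,
               co2_density_kg_m3 = rho, y2 = y),
    solute = "synthetic solute", solvent = "CO2")
}

#' Crossover pressure between two fitted isotherms
#'
#' The crossover pressure is where the solubility isotherms at two
#' temperatures intersect: below it the solvent-density effect dominates
#' (solubility falls with temperature), above it the vapor-pressure effect
#' dominates. Located by bisection on the difference of model-predicted
#' solubilities along the two isotherms, with the solvent density at each
#' pressure obtained by per-isotherm linear interpolation of the dataset's
#' density columns.
#'
#' @param fit a fitted model with a `predict` method (typically a
#'   [fit_density_model()] result).
#' @param dataset the dataset supplying the density-vs-pressure tables;
#'   defaults to the dataset stored in the fit.
#' @param T_low,T_high the two isotherm temperatures, K (must exist in the
#'   dataset).
#' @return crossover pressure, MPa.
#' @export
crossover_pressure <- function(fit, dataset = fit$dataset,
                               T_low = min(dataset$temperature_K),
                               T_high = max(dataset$temperature_K)) {
  iso <- function(Ti) {
    d <- dataset[abs(dataset$temperature_K - Ti) < 1e-9, ]
    if (nrow(d) < 2) stop("no isotherm at T = ", Ti, " K")
    approxfun(d$pressure_MPa, d$co2_density_kg_m3)
  }
  rho_lo <- iso(T_low); rho_hi <- iso(T_high)
  d_lo <- dataset[abs(dataset$temperature_K - T_low) < 1e-9, ]
  d_hi <- dataset[abs(dataset$temperature_K - T_high) < 1e-9, ]
  P_min <- max(min(d_lo$pressure_MPa), min(d_hi$pressure_MPa))
  P_max <- min(max(d_lo$pressure_MPa), max(d_hi$pressure_MPa))
  gap <- function(P) {
    y_lo <- .truth_predict(fit, T_low, P, rho_lo(P))
    y_hi <- .truth_predict(fit, T_high, P, rho_hi(P))
    y_lo - y_hi
  }
  g_min <- gap(P_min); g_max <- gap(P_max)
  if (!is.finite(g_min) || !is.finite(g_max) || g_min * g_max > 0)
    stop("no crossover: the isotherms do not intersect in [",
         P_min, ", ", P_max, "] MPa")
  uniroot(gap, c(P_min, P_max), tol = 1e-8)$root
}
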