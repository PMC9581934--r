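## Density-based (semi-empirical) solubility models: Chrastil, modified
## Chrastil, Mendez-Santiago-Teja (MT) and Bartle, their regression against
## a solubility dataset, and the dissolution enthalpies derived from the
## fitted 1/T coefficients.

.density_variants <- c("chrastil", "mchrastil", "mt", "bartle")

#' Chrastil model prediction
#'
#' The Chrastil association model writes the solvato-complex concentration as
#' `c2 = rho1^kappa * exp(A1 + B1/T)`; in mole-fraction form
#' `y2 = g/(1+g)` with `g = rho1^(kappa-1) * exp(A1 + B1/T)`. `kappa` is the
#' association number (solvent molecules per complex). Evaluated in the log
#' domain.
#'
#' @param params named vector or list with `kappa`, `A1`, `B1` (B1 in K).
#' @param T temperature, K.
#' @param rho1 solvent density, kg m^-3.
#' @return mole fraction y2.
#' @export
chrastil_predict <- function(params, T, rho1) {
  stopifnot(all(T > 0), all(rho1 > 0))
  p <- as.list(params)
  ln_g <- (p$kappa - 1) * log(rho1) + p$A1 + p$B1 / T
  if (any(!is.finite(ln_g))) stop("non-finite Chrastil exponent")
  1 / (1 + exp(-ln_g))
}

#' Modified (dimensionally corrected) Chrastil prediction
#'
#' `y2 = (R T rho1 / (M_ScF f0))^(kappa' - 1) * exp(A2 + B2/T)`. The
#' dimensionless group is evaluated with R = 8.314 J mol^-1 K^-1, density in
#' kg m^-3, the solvent molar mass in g/mol and standard fugacity `f0 = 1`;
#' rescaling `f0` only shifts `A2` and leaves predictions unchanged.
#'
#' @param params named vector/list with `kappa_prime`, `A2`, `B2` and
#'   optionally `f_std` (default 1) and `solvent_molar_mass` (default 44.01).
#' @inheritParams chrastil_predict
#' @export
modified_chrastil_predict <- function(params, T, rho1) {
  stopifnot(all(T > 0), all(rho1 > 0))
  p <- as.list(params)
  f0 <- if (is.null(p$f_std)) 1 else p$f_std
  M <- if (is.null(p$solvent_molar_mass)) 44.01 else p$solvent_molar_mass
  if (f0 <= 0) stop("f_std must be positive")
  ln_y <- (p$kappa_prime - 1) * log(.R_GAS * T * rho1 / (M * f0)) +
    p$A2 + p$B2 / T
  if (any(!is.finite(ln_y))) stop("non-finite exponent")
  exp(ln_y)
}

#' Mendez-Santiago-Teja (MT) model
#'
#' Self-consistency model `T ln(y2 P) = A3 + B3 rho1 + C3 T` with P in MPa.
#' `mt_predict` inverts it for y2; `mt_lhs` evaluates the left-hand side
#' (in K), the quantity that collapses all isotherms onto a single line in
#' `rho1` when the data are self-consistent.
#'
#' @param params named vector/list with `A3` (K), `B3` (K m^3/kg), `C3`.
#' @param P pressure, MPa.
#' @inheritParams chrastil_predict
#' @export
mt_predict <- function(params, T, P, rho1) {
  stopifnot(all(T > 0), all(P > 0), all(rho1 > 0))
  p <- as.list(params)
  (1 / P) * exp((p$A3 + p$B3 * rho1) / T + p$C3)
}

#' @rdname mt_predict
#' @param y2 mole fraction in (0, 1).
#' @export
mt_lhs <- function(T, P, y2) {
  stopifnot(all(T > 0), all(P > 0), all(y2 > 0), all(y2 < 1))
  T * log(y2 * P)
}

#' Bartle model
#'
#' `ln(y2 P / P_ref) = A4 + B4/T + C4 (rho1 - rho_ref)` with the standard
#' references P_ref = 0.1 MPa and rho_ref = 700 kg m^-3. The 1/T coefficient
#' `B4` carries the sublimation enthalpy, `dH_sub = -B4 * R`.
#'
#' @param params named vector/list with `A4`, `B4` (K), `C4` (m^3/kg) and
#'   optionally `P_ref` (MPa), `rho_ref` (kg m^-3).
#' @inheritParams mt_predict
#' @export
bartle_predict <- function(params, T, P, rho1) {
  stopifnot(all(T > 0), all(P > 0), all(rho1 > 0))
  p <- as.list(params)
  P_ref <- if (is.null(p$P_ref)) 0.1 else p$P_ref
  rho_ref <- if (is.null(p$rho_ref)) 700 else p$rho_ref
  (P_ref / P) * exp(p$A4 + p$B4 / T + p$C4 * (rho1 - rho_ref))
}

## dispatch a density-model prediction from a variant tag + parameter vector
.density_predict <- function(variant, params, T, P, rho1) {
  switch(variant,
         chrastil = chrastil_predict(params, T, rho1),
         mchrastil = modified_chrastil_predict(params, T, rho1),
         mt = mt_predict(params, T, P, rho1),
         bartle = bartle_predict(params, T, P, rho1),
         stop("unknown density-model variant: ", variant))
}

## linearized least-squares initial guesses (log-transform to affine form)
.density_init <- function(variant, T, P, rho1, y2) {
  switch(variant,
         chrastil = {
           g <- y2 / (1 - y2)
           f <- lm(log(g) ~ log(rho1) + I(1 / T))
           c(kappa = unname(coef(f)[2]) + 1, A1 = unname(coef(f)[1]),
             B1 = unname(coef(f)[3]))
         },
         mchrastil = {
           grp <- log(.R_GAS * T * rho1 / 44.01)
           f <- lm(log(y2) ~ grp + I(1 / T))
           c(kappa_prime = unname(coef(f)[2]) + 1, A2 = unname(coef(f)[1]),
             B2 = unname(coef(f)[3]))
         },
         mt = {
           f <- lm(I(T * log(y2 * P)) ~ rho1 + T)
           c(A3 = unname(coef(f)[1]), B3 = unname(coef(f)[2]),
             C3 = unname(coef(f)[3]))
         },
         bartle = {
           f <- lm(log(y2 * P / 0.1) ~ I(1 / T) + I(rho1 - 700))
           c(A4 = unname(coef(f)[1]), B4 = unname(coef(f)[2]),
             C4 = unname(coef(f)[3]))
         })
}

#' Fit a density-based solubility model
#'
#' Regresses one of the four density models against a dataset by Nelder-Mead
#' from a linearized least-squares initial guess. Two regression objectives
#' on the relative residuals `(y2_exp - y2_calc)/y2_exp` are supported: their
#' sum of squares (`"squared_relative"`, relative least squares) and their
#' sum of absolute values (`"absolute_relative"`, the objective whose mean
#' times 100 is the reported AARD%). The default objective is per model:
#' squared for the two Chrastil forms, absolute for MT and Bartle — the
#' conventions under which the published crizotinib parameter sets are the
#' respective optima (see the methods vignette).
#'
#' @param variant one of `"chrastil"`, `"mchrastil"`, `"mt"`, `"bartle"`.
#' @param dataset a [solubility_dataset()].
#' @param objective `"squared_relative"`, `"absolute_relative"`, or `NULL`
#'   for the per-model default.
#' @param init optional named initial parameter vector; defaults to the
#'   linearized fit.
#' @param reltol,maxit Nelder-Mead convergence tolerance and iteration cap;
#'   the optimizer is restarted from its own solution until no further
#'   improvement (at most `restarts` times).
#' @param restarts maximum number of Nelder-Mead restarts.
#' @return a `density_model_fit` with elements `variant`, `params`,
#'   `predicted`, `observed`, `residuals` (relative), `aard_percent`, `r2`,
#'   `r2_adj`, `n_params`, `objective`, `of_value`.
#' @export
fit_density_model <- function(variant = .density_variants, dataset,
                              objective = NULL, init = NULL,
                              reltol = 1e-12, maxit = 5000, restarts = 4) {
  variant <- match.arg(variant)
  if (is.null(objective))
    objective <- if (variant %in% c("chrastil", "mchrastil"))
      "squared_relative" else "absolute_relative"
  objective <- match.arg(objective, c("squared_relative", "absolute_relative"))
  T <- dataset$temperature_K; P <- dataset$pressure_MPa
  rho1 <- dataset$co2_density_kg_m3; y2 <- dataset$y2
  n_par <- 3L
  if (nrow(dataset) < n_par + 1)
    stop("need at least ", n_par + 1, " records to fit a ", n_par,
         "-parameter model")
  if (is.null(init)) init <- .density_init(variant, T, P, rho1, y2)
  ofun <- function(p) {
    yc <- tryCatch(.density_predict(variant, setNames(p, names(init)),
                                    T, P, rho1),
                   error = function(e) NULL)
    if (is.null(yc) || any(!is.finite(yc)) || any(yc <= 0)) return(1e10)
    r <- (y2 - yc) / y2
    if (objective == "squared_relative") sum(r^2) else sum(abs(r))
  }
  o <- optim(init, ofun, method = "Nelder-Mead",
             control = list(reltol = reltol, maxit = maxit))
  for (i in seq_len(restarts)) {
    o2 <- optim(o$par, ofun, method = "Nelder-Mead",
                control = list(reltol = reltol, maxit = maxit))
    if (o2$value >= o$value * (1 - 1e-12)) { o <- o2; break }
    o <- o2
  }
  if (!is.finite(o$value) || o$value >= 1e10)
    stop("density-model fit failed to converge; best objective ", o$value)
  params <- setNames(o$par, names(init))
  predicted <- .density_predict(variant, params, T, P, rho1)
  .finish_fit(variant, params, y2, predicted, dataset, objective, o$value)
}

## common bookkeeping for fitted models (used by EoS fits too)
.finish_fit <- function(variant, params, observed, predicted, dataset,
                        objective, of_value) {
  res <- (observed - predicted) / observed
  n <- length(observed); q <- length(params)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- 1 - sse / sst
  structure(list(variant = variant, params = params,
                 observed = observed, predicted = predicted,
                 residuals = res,
                 aard_percent = 100 * mean(abs(res)),
                 r2 = r2,
                 r2_adj = 1 - (1 - r2) * (n - 1) / (n - q - 1),
                 n_params = q, n_points = n,
                 dataset = dataset, objective = objective,
                 of_value = of_value),
            class = "density_model_fit")
}

#' @export
print.density_model_fit <- function(x, ...) {
  cat(sprintf("%s fit (%s objective)\n", x$variant, x$objective))
  print(signif(x$params, 6))
  cat(sprintf("AARD = %.2f%%, R2 = %.3f, R2_adj = %.3f (N = %d, Q = %d)\n",
              x$aard_percent, x$r2, x$r2_adj, x$n_points, x$n_params))
  invisible(x)
}

#' @export
predict.density_model_fit <- function(object, newdata = NULL, ...) {
  d <- if (is.null(newdata)) object$dataset else newdata
  .density_predict(object$variant, object$params, d$temperature_K,
                   d$pressure_MPa, d$co2_density_kg_m3)
}

#' Dissolution enthalpies from fitted density models
#'
#' The total dissolution enthalpy follows from the 1/T coefficient of a
#' Chrastil-type fit, `dH_total = -B * R` (B1 or B2), the sublimation
#' enthalpy from the Bartle 1/T coefficient, `dH_sub = -B4 * R`, and the
#' solvation enthalpy is their difference `dH_sol = dH_total - dH_sub`
#' (negative: solute-solvent clustering is exothermic).
#'
#' @param chrastil_fit a fitted `"chrastil"` or `"mchrastil"` model.
#' @param bartle_fit a fitted `"bartle"` model.
#' @return list with `total`, `sublimation`, `solvation`, all kJ/mol.
#' @export
dissolution_enthalpies <- function(chrastil_fit, bartle_fit) {
  if (!chrastil_fit$variant %in% c("chrastil", "mchrastil"))
    stop("first argument must be a Chrastil-type fit")
  if (bartle_fit$variant != "bartle")
    stop("second argument must be a Bartle fit")
  B <- if (chrastil_fit$variant == "chrastil")
    chrastil_fit$params[["B1"]] else chrastil_fit$params[["B2"]]
  B4 <- bartle_fit$params[["B4"]]
  total <- -B * .R_GAS / 1000
  sub <- -B4 * .R_GAS / 1000
  structure(list(total = total, sublimation = sub, solvation = total - sub),
            class = "dissolution_enthalpies")
}

#' @export
print.dissolution_enthalpies <- function(x, ...) {
  cat(sprintf("dH_total = %.3f, dH_sub = %.3f, dH_sol = %.3f kJ/mol\n",
              x$total, x$sublimation, x$solvation))
  invisible(x)
}
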