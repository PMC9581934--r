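## Solute fugacity coefficients in the supercritical phase, the implicit
## solid-solubility relation, and the regression of binary interaction
## parameters.
##
## The analytic ln(phi_i) expressions are derived from the volume-integral
## definition
##   ln(phi_i) = 1/RT * int_v^inf [ (dP/dN_i)_{T,V,Nj} - RT/v ] dv - ln Z
## applied to the pressure-explicit KM forms. For every variant the result
## is
##   ln(phi_i) = (bhat_i/b)(Z - 1) - ln[Z(1 - b/v)] + attraction term,
## where bhat_i = 2 sum_j x_j b_ij - b and the attraction term involves
## Ehat_i = (1/N) d(N^2 E)/dN_i. A numeric quadrature of the same integral
## is provided as an independent oracle.

## ---- vectorized binary state: Z, v and ln(phi) of component i ----------
## y is the mole fraction of component 2 (the solute); all of y, T, P may be
## vectors of equal length. Returns NULL on any invalid state (used as a
## penalty signal during fitting).
.km_state_vec <- function(variant, p1, p2, inter, y, T, P, i = 2L) {
  R <- .R_GAS
  pr <- tryCatch(.km_pairs(variant, p1, p2, inter), error = function(e) NULL)
  if (is.null(pr)) return(NULL)
  x1 <- 1 - y; x2 <- y
  quad <- function(q11, q12, q22)
    x1^2 * q11 + 2 * x1 * x2 * q12 + x2^2 * q22
  b <- quad(pr$b11, pr$b12, pr$b22)
  cc <- quad(pr$c11, pr$c12, pr$c22)
  dd <- quad(pr$d11, pr$d12, pr$d22)
  if (any(b <= 0)) return(NULL)
  if (variant == "RK") {
    g11 <- .cbrt(pr$a11^2 * pr$b11); g22 <- .cbrt(pr$a22^2 * pr$b22)
    g12 <- .cbrt(pr$a12^2 * pr$b12)
    s_ab <- quad(g11, g12, g22)
    if (any(s_ab < 0)) return(NULL)
    a <- s_ab^1.5 / sqrt(b)
  } else {
    a <- quad(pr$a11, pr$a12, pr$a22)
  }
  E <- .km_E(variant, a, cc, dd, T)
  if (is.null(E) || any(!is.finite(E))) return(NULL)
  st <- .solve_Z_vec(variant, E, b, T, P)
  if (is.null(st)) return(NULL)
  Z <- st$Z; v <- st$v
  ## partial-molar combinations for component i
  xi_other <- if (i == 2L) x1 else x2
  xi_self <- if (i == 2L) x2 else x1
  pick <- function(qii, q12, qjj)
    if (i == 2L) list(self = qjj, cross = q12) else list(self = qii, cross = q12)
  bb <- pick(pr$b11, pr$b12, pr$b22)
  bhat <- 2 * (xi_other * bb$cross + xi_self * bb$self) - b
  if (variant == "RK") {
    gg <- pick(g11, g12, g22)
    t_i <- xi_other * gg$cross + xi_self * gg$self
    u_i <- xi_other * bb$cross + xi_self * bb$self
    rat <- s_ab / b
    ahat <- 3 * t_i * sqrt(rat) - rat^1.5 * u_i
    Ehat <- ahat / sqrt(T)
  } else {
    aa <- pick(pr$a11, pr$a12, pr$a22)
    ccp <- pick(pr$c11, pr$c12, pr$c22)
    ahat <- 2 * (xi_other * aa$cross + xi_self * aa$self)
    chat <- 2 * (xi_other * ccp$cross + xi_self * ccp$self)
    if (variant == "SRK4") {
      ddp <- pick(pr$d11, pr$d12, pr$d22)
      dhat <- 2 * (xi_other * ddp$cross + xi_self * ddp$self)
      Ehat <- ahat + chat * R * T - dhat * R * sqrt(T)
    } else if (all(cc == 0)) {
      Ehat <- ahat
    } else {
      Ehat <- ahat * (1 - sqrt(R * T * cc / a)) +
        chat * (R * T - sqrt(R * T * a / cc))
    }
  }
  if (variant == "PR") {
    s2 <- sqrt(2)
    L <- log((v + (1 + s2) * b) / (v + (1 - s2) * b))
    lnphi <- bhat / b * (Z - 1) - log(Z * (1 - b / v)) +
      (E * bhat / b - Ehat) / (2 * s2 * b * R * T) * L
  } else {
    L <- log(1 + b / v)
    lnphi <- bhat / b * (Z - 1) - log(Z * (1 - b / v)) +
      (E * bhat / (b^2 * R * T) - Ehat / (b * R * T)) * L
  }
  if (any(!is.finite(lnphi))) return(NULL)
  list(Z = Z, v = v, b = b, lnphi = lnphi, phi = exp(lnphi))
}

#' Analytic fugacity coefficient of a component in a binary mixture
#'
#' Evaluates the closed-form `ln(phi_i)` for the chosen EoS variant with
#' Kwak-Mansoori mixing, derived from the thermodynamic volume integral.
#' Use [fugacity_coeff_numeric()] as an independent check.
#'
#' @param variant EoS variant tag.
#' @param x binary composition vector (component 1 = solvent).
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @param pure list of two [pure_constants()] records.
#' @param inter a [km_interaction()].
#' @param i index of the component whose fugacity coefficient is returned
#'   (default 2, the solute).
#' @return the fugacity coefficient (positive scalar).
#' @export
fugacity_coeff <- function(variant = .eos_variants, x, T, P, pure, inter,
                           i = 2L) {
  variant <- match.arg(variant)
  if (length(x) != 2 || abs(sum(x) - 1) > 1e-12 || any(x < 0))
    stop("x must be a binary composition summing to 1")
  st <- .km_state_vec(variant, pure[[1]], pure[[2]], inter, x[2], T, P,
                      i = as.integer(i))
  if (is.null(st))
    stop("invalid state: no fluid root or negative logarithm argument")
  st$phi
}

#' Numeric fugacity coefficient (volume-integral oracle)
#'
#' Evaluates `ln(phi_i)` directly from its definition: `dP/dN_i` by central
#' finite differences on mole numbers (relative step 1e-6) and the volume
#' integral by adaptive quadrature after the substitution u = 1/V (which
#' maps the infinite tail to a finite interval). Intended for tests and
#' cross-validation of [fugacity_coeff()], not for production fitting.
#'
#' @inheritParams fugacity_coeff
#' @export
fugacity_coeff_numeric <- function(variant = .eos_variants, x, T, P, pure,
                                   inter, i = 2L) {
  variant <- match.arg(variant)
  R <- .R_GAS
  st <- .km_state_vec(variant, pure[[1]], pure[[2]], inter, x[2], T, P,
                      i = as.integer(i))
  if (is.null(st)) stop("invalid state for the numeric oracle")
  ## total pressure as a function of mole vector and total volume
  P_of <- function(n, Vt) {
    N <- sum(n)
    mix <- km_mix(variant, n / N, pure, inter)
    E <- .km_E(variant, mix$a, mix$c, mix$d, T)
    B <- N * mix$b
    if (variant == "PR")
      N * R * T / (Vt - B) - N^2 * E / (Vt^2 + 2 * B * Vt - B^2)
    else
      N * R * T / (Vt - B) - N^2 * E / (Vt * (Vt + B))
  }
  n0 <- x  # N = 1 mol basis
  h <- 1e-6
  dPdNi <- function(Vt) {
    vapply(Vt, function(Vv) {
      np <- n0; np[i] <- np[i] + h
      nm <- n0; nm[i] <- nm[i] - h
      (P_of(np, Vv) - P_of(nm, Vv)) / (2 * h)
    }, numeric(1))
  }
  integrand_u <- function(u)
    vapply(u, function(uu) (dPdNi(1 / uu) - R * T * uu) / uu^2, numeric(1))
  I <- tryCatch(
    integrate(integrand_u, 0, 1 / st$v, rel.tol = 1e-10,
              abs.tol = 1e-8 * R * T)$value,
    error = function(e) stop("quadrature failed: ", conditionMessage(e)))
  exp(I / (R * T) - log(st$Z))
}

#' Settings for the solid-solubility fixed-point solve
#'
#' @param rel_tolerance relative convergence tolerance on y2.
#' @param max_iterations iteration cap.
#' @param damping damping factor in (0, 1]; 1 is undamped successive
#'   substitution.
#' @param initial_y2 starting value; `NULL` uses the ideal value
#'   `P_sub/P`.
#' @export
solubility_solve_settings <- function(rel_tolerance = 1e-10,
                                      max_iterations = 200L,
                                      damping = 0.5, initial_y2 = NULL) {
  stopifnot(rel_tolerance > 0, max_iterations >= 1,
            damping > 0, damping <= 1)
  structure(list(rel_tolerance = rel_tolerance,
                 max_iterations = as.integer(max_iterations),
                 damping = damping, initial_y2 = initial_y2),
            class = "solubility_solve_settings")
}

#' An EoS solubility model: variant + interaction + components
#'
#' @param variant EoS variant tag.
#' @param interaction a [km_interaction()] for the solvent-solute pair.
#' @param solute,solvent [component_properties()] records; the solute needs
#'   a sublimation-pressure table and a solid molar volume.
#' @export
eos_solubility_model <- function(variant = .eos_variants, interaction,
                                 solute, solvent) {
  variant <- match.arg(variant)
  if (interaction$variant != variant)
    stop("interaction parameter set was built for ", interaction$variant)
  if (is.null(solute$p_sub) || !is.finite(solute$v_solid))
    stop("solute needs a sublimation-pressure table and solid molar volume")
  structure(list(variant = variant, interaction = interaction,
                 solute = solute, solvent = solvent,
                 pure = list(pure_constants(variant, solvent),
                             pure_constants(variant, solute))),
            class = "eos_solubility_model")
}

## vectorized damped successive substitution over records; phi_override
## replaces the EoS fugacity coefficient (used for closed-form checks).
## Returns y vector, or NULL if any state is invalid.
.solve_solubility_vec <- function(variant, p1, p2, inter, T, P, P_sub, v_S,
                                  settings, phi_override = NULL,
                                  trace = FALSE) {
  R <- .R_GAS
  kernel <- P_sub / P * exp((P - P_sub) * v_S / (R * T))
  y <- if (is.null(settings$initial_y2)) P_sub / P
       else rep(settings$initial_y2, length(P))
  lam <- settings$damping
  hist <- if (trace) list() else NULL
  for (it in seq_len(settings$max_iterations)) {
    phi <- if (is.null(phi_override)) {
      st <- .km_state_vec(variant, p1, p2, inter, y, T, P, i = 2L)
      if (is.null(st)) return(NULL)
      st$phi
    } else phi_override
    y_new <- kernel / phi
    if (any(!is.finite(y_new)) || any(y_new <= 0)) return(NULL)
    y_new <- pmin(y_new, 0.5)
    y_next <- (1 - lam) * y + lam * y_new
    if (trace) hist[[it]] <- y_next
    delta <- max(abs(y_next - y) / pmax(y_next, 1e-300))
    y <- y_next
    if (delta < settings$rel_tolerance)
      return(structure(y, iterations = it, trace = hist))
  }
  attr(y, "iterations") <- settings$max_iterations
  attr(y, "converged") <- FALSE
  attr(y, "trace") <- hist
  y
}

#' Solve the solid-solubility relation for y2
#'
#' The equilibrium mole fraction of a solid solute in the supercritical
#' phase satisfies
#' `y2 = (P_sub/P) * exp((P - P_sub) v_S / (R T)) / phi2(y2)`,
#' where the saturation-phase fugacity coefficient is taken as unity, the
#' exponential is the Poynting compression factor, and `phi2` is the solute
#' fugacity coefficient in the fluid from the chosen EoS. Solved by damped
#' successive substitution.
#'
#' @param model an [eos_solubility_model()].
#' @param T temperature, K (the sublimation pressure is looked up or
#'   interpolated here).
#' @param P pressure, Pa; must exceed the sublimation pressure.
#' @param settings a [solubility_solve_settings()].
#' @param phi_fixed optional fixed value replacing the EoS fugacity
#'   coefficient (e.g. 1 for the ideal/Poynting-only solubility).
#' @return equilibrium mole fraction y2 in (0, 1).
#' @export
solve_solubility <- function(model, T, P,
                             settings = solubility_solve_settings(),
                             phi_fixed = NULL) {
  P_sub <- sublimation_pressure(model$solute, T)
  if (any(P <= P_sub)) stop("system pressure must exceed the sublimation pressure")
  y <- .solve_solubility_vec(model$variant, model$pure[[1]], model$pure[[2]],
                             model$interaction, T, P, P_sub,
                             model$solute$v_solid, settings,
                             phi_override = phi_fixed, trace = TRUE)
  if (is.null(y))
    stop("solubility solve hit an invalid EoS state")
  if (isFALSE(attr(y, "converged"))) {
    tr <- attr(y, "trace")
    last <- vapply(tr[max(1, length(tr) - 5):length(tr)], function(z) z[1],
                   numeric(1))
    osc <- length(last) >= 3 && any(diff(sign(diff(last))) != 0)
    stop("solubility iteration did not converge in ",
         settings$max_iterations, " iterations",
         if (osc) " (oscillation detected: reduce the damping factor)",
         "; last iterates: ", paste(signif(last, 6), collapse = ", "))
  }
  as.numeric(y)
}

#' Fit binary interaction parameters against a solubility dataset
#'
#' Multi-start Nelder-Mead over the variant's interaction parameters
#' (uniform random starts in `[-start_box, start_box]^Q` from the given
#' seed, plus the origin), minimizing the sum of absolute relative
#' deviations between measured and EoS-predicted mole fractions. A trial
#' point whose solubility solve diverges contributes a large finite penalty
#' so the simplex can recover.
#'
#' @param variant EoS variant tag.
#' @param dataset a [solubility_dataset()].
#' @param solute,solvent [component_properties()] records.
#' @param n_starts number of random starts (plus the origin).
#' @param seed integer seed for the random starts.
#' @param start_box half-width of the uniform start box.
#' @param extra_starts optional matrix (one start per row) of additional
#'   starting parameter vectors.
#' @param settings solve settings for the inner fixed-point iteration.
#' @param reltol,maxit Nelder-Mead control for each start.
#' @return an `eos_model_fit`: the fitted [km_interaction()], per-point
#'   predictions, AARD%, R2 statistics and optimizer diagnostics.
#' @export
fit_interaction <- function(variant = .eos_variants, dataset,
                            solute = crizotinib_properties(),
                            solvent = co2_properties(),
                            n_starts = 32L, seed = 1L, start_box = 1,
                            extra_starts = NULL,
                            settings = solubility_solve_settings(1e-8),
                            reltol = 1e-9, maxit = 1500) {
  variant <- match.arg(variant)
  if (!nrow(dataset)) stop("dataset is empty")
  q <- .n_interaction(variant)
  p1 <- pure_constants(variant, solvent)
  p2 <- pure_constants(variant, solute)
  T <- dataset$temperature_K
  P <- dataset$pressure_MPa * 1e6
  y_exp <- dataset$y2
  P_sub <- sublimation_pressure(solute, T)
  v_S <- solute$v_solid
  penalty <- 1e6
  ofun <- function(p) {
    inter <- tryCatch(.par_to_inter(variant, p), error = function(e) NULL)
    if (is.null(inter)) return(penalty)
    y <- .solve_solubility_vec(variant, p1, p2, inter, T, P, P_sub, v_S,
                               settings)
    if (is.null(y) || any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
      return(penalty)
    sum(abs(y_exp - y) / y_exp)
  }
  set.seed(seed)
  starts <- rbind(rep(0, q),
                  if (n_starts > 0)
                    matrix(runif(n_starts * q, -start_box, start_box),
                           ncol = q),
                  extra_starts)
  best <- NULL; n_ok <- 0L
  for (s in seq_len(nrow(starts))) {
    o <- tryCatch({
      o1 <- optim(starts[s, ], ofun, method = "Nelder-Mead",
                  control = list(reltol = reltol, maxit = maxit))
      optim(o1$par, ofun, method = "Nelder-Mead",
            control = list(reltol = reltol, maxit = maxit))
    }, error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value) || o$value >= penalty) next
    n_ok <- n_ok + 1L
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best))
    stop("all ", nrow(starts), " starts failed to produce a valid fit for ",
         variant)
  inter <- .par_to_inter(variant, best$par)
  y_fit <- .solve_solubility_vec(variant, p1, p2, inter, T, P, P_sub, v_S,
                                 settings)
  fit <- .finish_fit(variant, setNames(best$par, names(.inter_to_par(inter))),
                     y_exp, as.numeric(y_fit), dataset,
                     "absolute_relative", best$value)
  fit$interaction <- inter
  fit$seed <- seed
  fit$n_starts_ok <- n_ok
  class(fit) <- c("eos_model_fit", class(fit))
  fit
}

#' Predict EoS solubilities over a dataset's conditions
#'
#' Runs the solid-solubility solve at every (T, P) of a dataset for a given
#' model (variant + interaction + components).
#'
#' @param model an [eos_solubility_model()].
#' @param dataset a [solubility_dataset()] (only T and P are used).
#' @param settings a [solubility_solve_settings()].
#' @return vector of predicted mole fractions.
#' @export
predict_solubility <- function(model, dataset,
                               settings = solubility_solve_settings()) {
  T <- dataset$temperature_K
  P <- dataset$pressure_MPa * 1e6
  P_sub <- sublimation_pressure(model$solute, T)
  y <- .solve_solubility_vec(model$variant, model$pure[[1]], model$pure[[2]],
                             model$interaction, T, P, P_sub,
                             model$solute$v_solid, settings)
  if (is.null(y)) stop("solubility solve hit an invalid EoS state")
  as.numeric(y)
}

#' @export
predict.eos_model_fit <- function(object, newdata = NULL, ...,
                                  solute = crizotinib_properties(),
                                  solvent = co2_properties()) {
  d <- if (is.null(newdata)) object$dataset else newdata
  model <- eos_solubility_model(object$variant, object$interaction,
                                solute, solvent)
  predict_solubility(model, d)
}

#' @export
print.eos_model_fit <- function(x, ...) {
  cat(sprintf("%s EoS + Kwak-Mansoori fit\n", x$variant))
  print(signif(x$params, 6))
  cat(sprintf("AARD = %.2f%%, R2 = %.3f (N = %d, Q = %d, seed = %s)\n",
              x$aard_percent, x$r2, x$n_points, x$n_params,
              as.character(x$seed)))
  invisible(x)
}
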