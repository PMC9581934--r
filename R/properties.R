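## Pure-component property records and the embedded crizotinib/CO2 study
## constants.

#' Pure-component critical and physical properties
#'
#' @param name component name.
#' @param Tc critical temperature, K.
#' @param Pc critical pressure, Pa.
#' @param omega acentric factor (dimensionless).
#' @param v_solid solid molar volume, m^3/mol (solids only).
#' @param p_sub named numeric vector of sublimation pressures in Pa, with
#'   names giving the temperature in K (solids only).
#' @return a `component_properties` object.
#' @export
component_properties <- function(name, Tc, Pc, omega, v_solid = NA_real_,
                                 p_sub = NULL) {
  if (!is.finite(Tc) || Tc <= 0 || !is.finite(Pc) || Pc <= 0)
    stop("Tc and Pc must be finite and positive")
  if (!is.finite(omega)) stop("omega must be finite")
  if (!is.null(p_sub)) {
    if (is.null(names(p_sub)) || any(!is.finite(as.numeric(names(p_sub)))))
      stop("p_sub must be named by temperature in K")
    p_sub <- p_sub[order(as.numeric(names(p_sub)))]
  }
  structure(list(name = name, Tc = Tc, Pc = Pc, omega = omega,
                 v_solid = v_solid, p_sub = p_sub),
            class = "component_properties")
}

#' @export
print.component_properties <- function(x, ...) {
  cat(sprintf("%s: Tc = %.2f K, Pc = %.4g MPa, omega = %.4f\n",
              x$name, x$Tc, x$Pc / 1e6, x$omega))
  if (is.finite(x$v_solid))
    cat(sprintf("  solid molar volume: %.4g m^3/mol\n", x$v_solid))
  if (!is.null(x$p_sub)) {
    cat("  sublimation pressure (Pa):",
        paste(sprintf("%s K: %g", names(x$p_sub), x$p_sub), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Property constants of crizotinib and of CO2
#'
#' Group-contribution estimates for crizotinib (Tc = 485.25 K,
#' Pc = 14.102 MPa, omega = 0.4394, solid molar volume 32.12e-6 m^3/mol,
#' sublimation pressures at the four study temperatures) and the standard
#' critical constants of CO2 (Tc = 304.18 K, Pc = 7.38 MPa, omega = 0.225).
#' The critical-pressure column of the source table is labelled in Pa but
#' holds 14.102 for the drug and 73.80 for CO2; the only physically coherent
#' reading, used here, is MPa for the drug and bar for CO2.
#'
#' @return a [component_properties()] record.
#' @export
crizotinib_properties <- function() {
  component_properties(
    name = "crizotinib", Tc = 485.25, Pc = 14.102e6, omega = 0.4394,
    v_solid = 32.12e-6,
    p_sub = c("308" = 1072, "318" = 1628, "328" = 2398, "338" = 3433))
}

#' @rdname crizotinib_properties
#' @export
co2_properties <- function() {
  component_properties(name = "CO2", Tc = 304.18, Pc = 7.38e6, omega = 0.225)
}

#' Sublimation pressure at a given temperature
#'
#' Returns the tabulated sublimation pressure when `T` matches a tabulated
#' temperature; otherwise interpolates (or extrapolates) log-linearly in 1/T,
#' the Clausius-Clapeyron form.
#'
#' @param props a [component_properties()] with a `p_sub` table.
#' @param T temperature, K.
#' @return sublimation pressure, Pa.
#' @export
sublimation_pressure <- function(props, T) {
  if (is.null(props$p_sub)) stop("no sublimation-pressure table for ",
                                 props$name)
  tab_T <- as.numeric(names(props$p_sub))
  tab_P <- as.numeric(props$p_sub)
  vapply(T, function(Ti) {
    hit <- which(abs(tab_T - Ti) < 1e-9)
    if (length(hit)) return(tab_P[hit[1]])
    if (length(tab_T) < 2)
      stop("need at least two tabulated points to interpolate")
    fit <- lm(log(tab_P) ~ I(1 / tab_T))
    exp(sum(coef(fit) * c(1, 1 / Ti)))
  }, numeric(1))
}

#' Read or write component properties as JSON
#'
#' Field names mirror [component_properties()]; `p_sub` is stored as an
#' object keyed by temperature.
#'
#' @param path file path.
#' @return `read_component_json` returns a [component_properties()].
#' @export
read_component_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  p_sub <- if (!is.null(x$p_sub)) unlist(x$p_sub) else NULL
  component_properties(name = x$name, Tc = x$Tc, Pc = x$Pc, omega = x$omega,
                       v_solid = if (is.null(x$v_solid)) NA_real_ else x$v_solid,
                       p_sub = p_sub)
}

#' @rdname read_component_json
#' @param props a [component_properties()].
#' @export
write_component_json <- function(props, path) {
  x <- unclass(props)
  if (!is.null(x$p_sub)) x$p_sub <- as.list(x$p_sub)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' The crizotinib/scCO2 solubility measurements
#'
#' The 24 published equilibrium solubility records of crystalline crizotinib
#' in supercritical CO2: four isotherms (308, 318, 328, 338 K) at six
#' pressures (12 to 27 MPa), with the NIST CO2 density at each state, the
#' measured mole fraction, its replicate standard deviation, the equilibrium
#' solubility in g/L and the expanded uncertainty (coverage factor 2).
#'
#' @return a [solubility_dataset()] of 24 records.
#' @export
crizotinib_dataset <- function() {
  df <- data.frame(
    temperature_K = rep(c(308, 318, 328, 338), each = 6),
    pressure_MPa = rep(c(12, 15, 18, 21, 24, 27), times = 4),
    co2_density_kg_m3 = c(769, 817, 849, 875, 896, 914,
                          661, 744, 791, 824, 851, 872,
                          509, 656, 725, 769, 802, 829,
                          388, 557, 652, 710, 751, 783),
    y2 = 1e-5 * c(0.483, 0.515, 0.556, 0.686, 0.730, 0.791,
                  0.315, 0.566, 0.650, 0.799, 0.899, 0.958,
                  0.260, 0.629, 0.749, 0.918, 0.995, 1.057,
                  0.156, 0.675, 0.870, 0.993, 1.083, 1.219),
    sd_y2 = 1e-5 * c(0.005, 0.009, 0.003, 0.014, 0.015, 0.021,
                     0.011, 0.015, 0.011, 0.016, 0.020, 0.041,
                     0.010, 0.015, 0.012, 0.019, 0.021, 0.032,
                     0.005, 0.022, 0.032, 0.035, 0.012, 0.054),
    S_g_L = c(0.038, 0.043, 0.048, 0.061, 0.067, 0.074,
              0.021, 0.043, 0.053, 0.067, 0.078, 0.085,
              0.013, 0.042, 0.056, 0.072, 0.082, 0.089,
              0.006, 0.038, 0.058, 0.072, 0.083, 0.098),
    U = 1e-5 * c(0.025, 0.029, 0.025, 0.043, 0.042, 0.056,
                 0.026, 0.039, 0.038, 0.046, 0.055, 0.090,
                 0.022, 0.042, 0.043, 0.056, 0.061, 0.079,
                 0.011, 0.051, 0.074, 0.088, 0.053, 0.123))
  solubility_dataset(df, solute = "crizotinib", solvent = "CO2")
}
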