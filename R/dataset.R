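## Solubility datasets: validated tables of (T, P, rho1, y2) with optional
## replicate standard deviation, equilibrium solubility S and expanded
## uncertainty columns, plus the unit conversions that relate a sampled
## drug concentration to a mole fraction.

#' Construct a solubility dataset
#'
#' A solubility dataset is an ordered table of isothermal saturation
#' measurements of a solid solute in supercritical CO2. Each record holds the
#' temperature (K), pressure (MPa), the solvent density at that state
#' (kg m^-3, taken from an external correlation such as the NIST database,
#' never computed here), and the measured equilibrium mole fraction `y2`.
#' Optional columns carry the replicate standard deviation of `y2`, the
#' equilibrium solubility `S` in g/L and the expanded uncertainty `U`.
#'
#' Records are sorted by (temperature, pressure) and duplicate (T, P) pairs
#' are rejected. When both `y2` and `S_g_L` are present the pair must be
#' consistent with the density-ratio relation `S = rho1 * Ms/MCO2 *
#' y2/(1-y2)` to within 1 percent relative (printed tables are rounded).
#'
#' @param records a data.frame with columns `temperature_K`, `pressure_MPa`,
#'   `co2_density_kg_m3`, `y2` and optionally `sd_y2`, `S_g_L`, `U`.
#' @param solute,solvent component names (character scalars).
#' @param geometry a [sampling_geometry()] used only for the y2/S consistency
#'   check; defaults to the crizotinib study geometry.
#' @return an object of class `solubility_dataset` (a data.frame).
#' @export
solubility_dataset <- function(records, solute = "solute", solvent = "CO2",
                               geometry = crizotinib_geometry()) {
  required <- c("temperature_K", "pressure_MPa", "co2_density_kg_m3", "y2")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  optional <- c("sd_y2", "S_g_L", "U")
  for (col in optional) if (!col %in% names(records)) records[[col]] <- NA_real_
  records <- records[c(required, optional)]
  for (col in names(records)) {
    if (!is.numeric(records[[col]]))
      stop("non-numeric values in column '", col, "'")
  }
  bad <- which(records$temperature_K <= 0 | records$pressure_MPa <= 0 |
               records$co2_density_kg_m3 <= 0)
  if (length(bad))
    stop("non-positive temperature/pressure/density in row(s) ",
         paste(bad, collapse = ", "))
  bad <- which(records$y2 <= 0 | records$y2 >= 1)
  if (length(bad))
    stop("mole fraction outside (0, 1) in row(s) ", paste(bad, collapse = ", "))
  key <- paste(records$temperature_K, records$pressure_MPa)
  if (anyDuplicated(key))
    stop("duplicate (temperature, pressure) pair in row(s) ",
         paste(which(duplicated(key)), collapse = ", "))
  ord <- order(records$temperature_K, records$pressure_MPa)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  has_S <- !is.na(records$S_g_L)
  if (any(has_S)) {
    implied <- S_from_y2(records$y2[has_S], records$co2_density_kg_m3[has_S],
                         geometry)
    rel <- abs(records$S_g_L[has_S] - implied) / implied
    ## printed S values are rounded to 3 decimals; allow 1% plus half an ulp
    tol <- 0.01 + 0.0005 / pmax(records$S_g_L[has_S], 1e-12)
    if (any(rel > tol, na.rm = TRUE))
      stop("y2 and S_g_L inconsistent with the density-ratio relation in row(s) ",
           paste(which(has_S)[rel > tol], collapse = ", "))
  }
  structure(records, class = c("solubility_dataset", "data.frame"),
            solute = solute, solvent = solvent)
}

#' @export
print.solubility_dataset <- function(x, ...) {
  cat("Solubility dataset:", attr(x, "solute"), "in", attr(x, "solvent"),
      sprintf("(%d records, %d isotherm(s))\n", nrow(x),
              length(unique(x$temperature_K))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' Sampling-loop geometry of the solubility apparatus
#'
#' Holds the physical constants that convert a measured drug concentration in
#' the collection vial into a mole fraction: the sampling-loop volume `V1`,
#' the total collection volume `Vs` (both m^3), and the molar masses of
#' solute and solvent (g/mol).
#'
#' @param loop_volume_m3 volume of saturated fluid sampled, m^3.
#' @param vial_volume_m3 total volume of the analysed solution, m^3.
#' @param solute_molar_mass,solvent_molar_mass molar masses, g/mol.
#' @return a `sampling_geometry` object.
#' @export
sampling_geometry <- function(loop_volume_m3, vial_volume_m3,
                              solute_molar_mass, solvent_molar_mass) {
  vals <- c(loop_volume_m3, vial_volume_m3, solute_molar_mass,
            solvent_molar_mass)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry fields must be strictly positive")
  structure(list(loop_volume_m3 = loop_volume_m3,
                 vial_volume_m3 = vial_volume_m3,
                 solute_molar_mass = solute_molar_mass,
                 solvent_molar_mass = solvent_molar_mass),
            class = "sampling_geometry")
}

#' Geometry of the crizotinib solubility measurements
#'
#' 600 uL sampling loop, 5 mL collection volume, crizotinib (450.3 g/mol)
#' in CO2 (44.01 g/mol).
#' @return a [sampling_geometry()].
#' @export
crizotinib_geometry <- function() {
  sampling_geometry(loop_volume_m3 = 600e-9, vial_volume_m3 = 5e-6,
                    solute_molar_mass = 450.3, solvent_molar_mass = 44.01)
}

#' Mole fraction from the sampled drug concentration
#'
#' Converts the drug concentration measured in the collection vial
#' (`C_s`, g/L) into the equilibrium mole fraction
#' `y2 = n_drug / (n_drug + n_CO2)` with `n_drug = C_s Vs / Ms` and
#' `n_CO2 = V1 rho / M_CO2`.
#'
#' @param conc_g_per_L drug concentration in the vial, g/L (non-negative).
#' @param co2_density solvent density in the loop, kg m^-3 (equals g/L).
#' @param geom a [sampling_geometry()].
#' @return dimensionless mole fraction.
#' @export
mole_fraction_from_concentration <- function(conc_g_per_L, co2_density,
                                             geom = crizotinib_geometry()) {
  if (any(conc_g_per_L < 0)) stop("concentration must be non-negative")
  if (any(co2_density <= 0)) stop("density must be strictly positive")
  vs_L <- geom$vial_volume_m3 * 1e3
  v1_L <- geom$loop_volume_m3 * 1e3
  n_drug <- conc_g_per_L * vs_L / geom$solute_molar_mass
  n_co2 <- v1_L * co2_density / geom$solvent_molar_mass
  n_drug / (n_drug + n_co2)
}

#' Equilibrium solubility from the sampled concentration
#'
#' `S = C_s Vs / V1`, the solubility expressed per litre of supercritical
#' fluid sampled.
#'
#' @inheritParams mole_fraction_from_concentration
#' @return solubility in g/L.
#' @export
equilibrium_solubility <- function(conc_g_per_L, geom = crizotinib_geometry()) {
  if (any(conc_g_per_L < 0)) stop("concentration must be non-negative")
  conc_g_per_L * geom$vial_volume_m3 / geom$loop_volume_m3
}

#' Convert between mole fraction and equilibrium solubility
#'
#' `S = (rho Ms / MCO2) y2 / (1 - y2)`; the two functions are mutual
#' inverses.
#'
#' @param y2 mole fraction in `[0, 1)`.
#' @param S solubility, g/L (non-negative).
#' @param co2_density solvent density, kg m^-3.
#' @param geom a [sampling_geometry()] (only the molar masses are used).
#' @return `S_from_y2`: g/L; `y2_from_S`: dimensionless.
#' @export
S_from_y2 <- function(y2, co2_density, geom = crizotinib_geometry()) {
  if (any(y2 < 0) || any(y2 >= 1)) stop("y2 must lie in [0, 1)")
  if (any(co2_density <= 0)) stop("density must be strictly positive")
  co2_density * geom$solute_molar_mass / geom$solvent_molar_mass *
    y2 / (1 - y2)
}

#' @rdname S_from_y2
#' @export
y2_from_S <- function(S, co2_density, geom = crizotinib_geometry()) {
  if (any(S < 0)) stop("S must be non-negative")
  if (any(co2_density <= 0)) stop("density must be strictly positive")
  r <- S * geom$solvent_molar_mass /
    (co2_density * geom$solute_molar_mass)
  r / (1 + r)
}

#' Read or write a solubility dataset as CSV
#'
#' The CSV schema is one column per printed table column:
#' `temperature_K, pressure_MPa, co2_density_kg_m3, y2, sd_y2, S_g_L, U`
#' (the last three optional). Validation errors name the offending row.
#'
#' @param path file path.
#' @param solute,solvent component names stored on the returned dataset.
#' @return `read_solubility_csv` returns a [solubility_dataset()];
#'   `write_solubility_csv` returns `path` invisibly.
#' @export
read_solubility_csv <- function(path, solute = "solute", solvent = "CO2") {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path)
  solubility_dataset(df, solute = solute, solvent = solvent)
}

#' @rdname read_solubility_csv
#' @param dataset a [solubility_dataset()].
#' @export
write_solubility_csv <- function(dataset, path) {
  write.csv(as.data.frame(dataset), path, row.names = FALSE)
  invisible(path)
}
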