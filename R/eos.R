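## Cubic equations of state under the Kwak-Mansoori (KM) decomposition:
## every variant is reduced to temperature-independent constants (a, b and,
## depending on the variant, c and d) that mix with quadratic composition
## sums; the temperature dependence re-enters only through the effective
## attraction E(T) assembled from those constants.
##
## Variants: RK   - Redlich-Kwong, E = a/sqrt(T)                (a, b)
##           PR   - Peng-Robinson, E = a + cRT - 2 sqrt(acRT)   (a, b, c)
##           SRK3 - Soave-Redlich-Kwong, same E form            (a, b, c)
##           SRK4 - SRK with the 1993 two-constant alpha,
##                  E = a + cRT - dR sqrt(T)                    (a, b, c, d)

.eos_variants <- c("RK", "PR", "SRK3", "SRK4")

## signed cube root (c can be negative for some acentric factors)
.cbrt <- function(x) sign(x) * abs(x)^(1 / 3)

#' Temperature-independent pure-component EoS constants
#'
#' Decomposes a cubic EoS into Kwak-Mansoori constants from the critical
#' properties. For RK, `a = 0.42748 R^2 Tc^2.5 / Pc` (the T^1.5 form) and
#' `b = 0.08664 R Tc / Pc`. For PR and SRK the Soave alpha polynomial in
#' `m(omega)` is expanded about Tc so that `a = a(Tc)(1+m)^2` and
#' `c = a(Tc) m^2 / (R Tc)` are constants; the four-parameter SRK uses the
#' heavy-compound alpha with `m = 0.484 + 1.515 w - 0.044 w^2`,
#' `n = 2.756 m - 0.7`, giving `a = a(Tc)(1+m+n)`,
#' `c = a(Tc)(n-m)/(R Tc)` and `d = 2 n a(Tc)/(R sqrt(Tc))`.
#'
#' @param variant one of `"RK"`, `"PR"`, `"SRK3"`, `"SRK4"`.
#' @param props a [component_properties()] record (Tc in K, Pc in Pa).
#' @return a `pure_km_constants` list with elements `a`, `b`, `c`, `d`
#'   (unused constants are zero) and the variant tag.
#' @export
pure_constants <- function(variant = .eos_variants, props) {
  variant <- match.arg(variant)
  Tc <- props$Tc; Pc <- props$Pc; w <- props$omega
  R <- .R_GAS
  out <- switch(variant,
    RK = list(a = 0.42748 * R^2 * Tc^2.5 / Pc,
              b = 0.08664 * R * Tc / Pc, c = 0, d = 0),
    PR = {
      aTc <- 0.45724 * R^2 * Tc^2 / Pc
      m <- 0.37464 + 1.5422 * w - 0.26992 * w^2
      list(a = aTc * (1 + m)^2, b = 0.07780 * R * Tc / Pc,
           c = aTc * m^2 / (R * Tc), d = 0)
    },
    SRK3 = {
      aTc <- 0.42748 * R^2 * Tc^2 / Pc
      m <- 0.48 + 1.574 * w - 0.176 * w^2
      list(a = aTc * (1 + m)^2, b = 0.08664 * R * Tc / Pc,
           c = aTc * m^2 / (R * Tc), d = 0)
    },
    SRK4 = {
      aTc <- 0.42748 * R^2 * Tc^2 / Pc
      m <- 0.484 + 1.515 * w - 0.044 * w^2
      n <- 2.756 * m - 0.7
      list(a = aTc * (1 + m + n), b = 0.08664 * R * Tc / Pc,
           c = aTc * (n - m) / (R * Tc), d = 2 * n * aTc / (R * sqrt(Tc)))
    })
  structure(c(out, list(variant = variant, name = props$name)),
            class = "pure_km_constants")
}

## number of binary interaction parameters per variant
.n_interaction <- function(variant) {
  switch(variant, RK = 2L, PR = 3L, SRK3 = 3L, SRK4 = 4L)
}

#' Binary interaction parameter set
#'
#' One dimensionless interaction parameter per mixed constant: `k_ij` for
#' the attraction cross term, `l_ij` for the covolume, `m_ij` for `c`
#' (PR/SRK3/SRK4) and `n_ij` for `d` (SRK4). All are temperature-independent.
#'
#' @param variant EoS variant tag.
#' @param k_ij,l_ij,m_ij,n_ij dimensionless interaction parameters.
#' @export
km_interaction <- function(variant = .eos_variants, k_ij, l_ij,
                           m_ij = NULL, n_ij = NULL) {
  variant <- match.arg(variant)
  q <- .n_interaction(variant)
  vals <- c(k_ij, l_ij, m_ij, n_ij)
  if (length(vals) != q)
    stop(variant, " takes exactly ", q, " interaction parameters")
  if (any(!is.finite(vals))) stop("interaction parameters must be finite")
  structure(list(variant = variant, k_ij = k_ij, l_ij = l_ij,
                 m_ij = if (q >= 3) m_ij else NULL,
                 n_ij = if (q >= 4) n_ij else NULL),
            class = "km_interaction")
}

## as a plain parameter vector (fitting order k, l, m, n)
.inter_to_par <- function(inter) {
  unlist(inter[c("k_ij", "l_ij", "m_ij", "n_ij")], use.names = TRUE)
}
.par_to_inter <- function(variant, p) {
  q <- .n_interaction(variant)
  km_interaction(variant, k_ij = p[1], l_ij = p[2],
                 m_ij = if (q >= 3) p[3] else NULL,
                 n_ij = if (q >= 4) p[4] else NULL)
}

## pairwise combined constants for a binary (components 1, 2)
.km_pairs <- function(variant, p1, p2, inter) {
  a_prod <- p1$a * p2$a
  if (a_prod < 0) stop("negative product a11*a22 under the square root")
  comb3 <- function(u, v) ((.cbrt(u) + .cbrt(v)) / 2)^3
  list(
    a11 = p1$a, a22 = p2$a, a12 = (1 - inter$k_ij) * sqrt(a_prod),
    b11 = p1$b, b22 = p2$b, b12 = (1 - inter$l_ij) * comb3(p1$b, p2$b),
    c11 = p1$c, c22 = p2$c,
    c12 = if (variant == "RK") 0 else (1 - inter$m_ij) * comb3(p1$c, p2$c),
    d11 = p1$d, d22 = p2$d,
    d12 = if (variant == "SRK4") (1 - inter$n_ij) * comb3(p1$d, p2$d) else 0)
}

#' Mixture constants from the Kwak-Mansoori rules
#'
#' Quadratic composition sums of the pairwise constants. Cross terms:
#' `a_ij = (1 - k_ij) sqrt(a_ii a_jj)` and cube-root-mean covolumes
#' `b_ij = (1 - l_ij) ((b_ii^(1/3) + b_jj^(1/3))/2)^3` (and analogously for
#' `c`, `d`). For RK the attraction uses the 2/3-1/3 power rule
#' `a = (sum_ij x_i x_j a_ij^(2/3) b_ij^(1/3))^(3/2) / b^(1/2)`, which
#' reduces to the pure `a` at the composition vertices.
#'
#' @param variant EoS variant tag.
#' @param x binary composition vector (sums to 1, entries >= 0).
#' @param pure list of two [pure_constants()] records.
#' @param inter a [km_interaction()].
#' @return a `mixture_constants` list with `a`, `b`, `c`, `d`.
#' @export
km_mix <- function(variant = .eos_variants, x, pure, inter) {
  variant <- match.arg(variant)
  if (length(x) != 2 || length(pure) != 2)
    stop("binary mixtures only: x and pure must have length 2")
  if (abs(sum(x) - 1) > 1e-12) stop("composition must sum to 1")
  if (any(x < 0)) stop("composition entries must be non-negative")
  pr <- .km_pairs(variant, pure[[1]], pure[[2]], inter)
  quad <- function(q11, q12, q22)
    x[1]^2 * q11 + 2 * x[1] * x[2] * q12 + x[2]^2 * q22
  b <- quad(pr$b11, pr$b12, pr$b22)
  cc <- quad(pr$c11, pr$c12, pr$c22)
  dd <- quad(pr$d11, pr$d12, pr$d22)
  if (variant == "RK") {
    g <- function(a, bb) .cbrt(a^2 * bb)
    s_ab <- quad(g(pr$a11, pr$b11), g(pr$a12, pr$b12), g(pr$a22, pr$b22))
    if (s_ab < 0 || b <= 0)
      stop("invalid RK mixing sums (negative attraction or covolume)")
    a <- s_ab^1.5 / sqrt(b)
  } else {
    a <- quad(pr$a11, pr$a12, pr$a22)
  }
  structure(list(a = a, b = b, c = cc, d = dd, variant = variant),
            class = "mixture_constants")
}

## effective attraction E(T) [Pa m^6 mol^-2] from mixture-level constants
.km_E <- function(variant, a, cc, dd, T) {
  R <- .R_GAS
  switch(variant,
         RK = a / sqrt(T),
         PR = ,
         SRK3 = {
           prod_ac <- a * cc * R * T
           if (any(prod_ac < 0)) return(NULL)
           a + cc * R * T - 2 * sqrt(prod_ac)
         },
         SRK4 = a + cc * R * T - dd * R * sqrt(T))
}

## largest real root of z^3 + p2 z^2 + p1 z + p0 (vectorized Cardano with
## Newton polish); NA where the coefficients are not finite
.cubic_max_root <- function(p2, p1, p0) {
  a <- p1 - p2^2 / 3
  b <- 2 * p2^3 / 27 - p2 * p1 / 3 + p0
  disc <- (b / 2)^2 + (a / 3)^3
  t <- rep(NA_real_, length(disc))
  one <- which(disc > 0)
  if (length(one)) {
    s <- sqrt(disc[one])
    t[one] <- .cbrt(-b[one] / 2 + s) + .cbrt(-b[one] / 2 - s)
  }
  three <- which(disc <= 0)
  if (length(three)) {
    an <- a[three]; bn <- b[three]
    mag <- 2 * sqrt(-an / 3)
    arg <- pmin(pmax(3 * bn / (an * mag), -1), 1)
    t[three] <- mag * cos(acos(arg) / 3)
  }
  z <- t - p2 / 3
  for (i in 1:3) {
    f <- z^3 + p2 * z^2 + p1 * z + p0
    fp <- 3 * z^2 + 2 * p2 * z + p1
    step <- ifelse(is.finite(fp) & abs(fp) > 0, f / fp, 0)
    z <- z - step
  }
  z
}

## vectorized compressibility solve; returns list(Z, v) or NULL on failure
.solve_Z_vec <- function(variant, E, b, T, P) {
  R <- .R_GAS
  As <- E * P / (R * T)^2
  Bs <- b * P / (R * T)
  if (any(!is.finite(As)) || any(!is.finite(Bs)) || any(Bs <= 0)) return(NULL)
  Z <- if (variant == "PR")
    .cubic_max_root(-(1 - Bs), As - 3 * Bs^2 - 2 * Bs,
                    -(As * Bs - Bs^2 - Bs^3))
  else
    .cubic_max_root(rep(-1, length(As)), As - Bs - Bs^2, -As * Bs)
  if (any(!is.finite(Z)) || any(Z <= Bs)) return(NULL)
  list(Z = Z, v = Z * R * T / P)
}

#' Solve a cubic EoS for the compressibility factor
#'
#' Rearranges the variant's pressure-explicit form to a cubic in Z, extracts
#' the real roots analytically (Cardano, then Newton polish) and returns the
#' largest real root with molar volume `v > b` — the single supercritical
#' fluid phase considered here.
#'
#' @param variant EoS variant tag.
#' @param mix mixture (or pure) constants: a list with `a`, `b`, `c`, `d`.
#' @param T temperature, K.
#' @param P pressure, Pa.
#' @return list with `Z`, molar volume `v` (m^3/mol), and the relative EoS
#'   residual at the returned state.
#' @export
solve_Z <- function(variant = .eos_variants, mix, T, P) {
  variant <- match.arg(variant)
  stopifnot(T > 0, P > 0)
  E <- .km_E(variant, mix$a, mix$c, mix$d, T)
  if (is.null(E)) stop("negative a*c product: no real effective attraction")
  st <- .solve_Z_vec(variant, E, mix$b, T, P)
  if (is.null(st))
    stop("no real compressibility root with v > b (unphysical constants)")
  v <- st$v
  P_calc <- .R_GAS * T / (v - mix$b) -
    if (variant == "PR") E / (v^2 + 2 * mix$b * v - mix$b^2)
    else E / (v * (v + mix$b))
  list(Z = st$Z, v = v, residual = abs(P_calc - P) / P)
}
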