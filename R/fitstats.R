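## Regression objective, AARD, information criteria and the model-comparison
## table.

#' Relative-deviation objective and AARD
#'
#' `objective_of` is the sum of absolute relative deviations
#' `sum(|y_exp - y_calc| / y_exp)`; `aard_percent` is `100/N` times that sum,
#' the average absolute relative deviation in percent.
#'
#' @param observed,predicted equal-length numeric vectors; `observed` must be
#'   strictly positive.
#' @export
objective_of <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stop("observed and predicted must have equal length")
  if (any(observed <= 0)) stop("observed values must be strictly positive")
  sum(abs(observed - predicted) / observed)
}

#' @rdname objective_of
#' @export
aard_percent <- function(observed, predicted) {
  100 * objective_of(observed, predicted) / length(observed)
}

#' Akaike information criteria from an error sum of squares
#'
#' `AIC = N log(SSE/N) + 2Q` and the small-sample correction
#' `AICc = AIC + 2Q(Q+1)/(N-Q-1)`, with N data points and Q model
#' parameters. AICc requires `N > Q + 1`.
#'
#' @param sse error sum of squares (> 0).
#' @param N number of data points.
#' @param Q number of model parameters.
#' @return list with elements `aic` and `aicc`.
#' @export
information_criteria <- function(sse, N, Q) {
  if (sse <= 0) stop("sse must be positive")
  if (N <= Q + 1) stop("AICc undefined for N <= Q + 1")
  aic <- N * log(sse / N) + 2 * Q
  list(aic = aic, aicc = aic + 2 * Q * (Q + 1) / (N - Q - 1))
}

#' Model-comparison table
#'
#' Collects SSE, RMSE, AARD%, R2, adjusted R2, AIC and AICc for a set of
#' fitted models (density-model or EoS fits sharing one dataset) and sorts
#' ascending by AICc, so the preferred model comes first. SSE is computed on
#' the raw mole-fraction residuals even though fitting minimizes relative
#' deviations; the two scales are deliberately different.
#'
#' @param fits named list of fit objects carrying `observed`, `predicted`
#'   and `n_params`.
#' @return a data.frame with one row per model.
#' @export
comparison_table <- function(fits) {
  if (is.null(names(fits)) || any(names(fits) == ""))
    names(fits) <- vapply(fits, function(f) f$variant, character(1))
  obs0 <- fits[[1]]$observed
  rows <- lapply(seq_along(fits), function(idx) {
    nm <- names(fits)[idx]
    f <- fits[[idx]]
    if (length(f$observed) != length(obs0) ||
        any(abs(f$observed - obs0) > 1e-12 * pmax(obs0, 1e-300)))
      stop("fits were not produced on the same dataset")
    n <- length(f$observed); q <- f$n_params
    sse <- sum((f$observed - f$predicted)^2)
    ic <- information_criteria(sse, n, q)
    data.frame(model = nm, sse = sse, rmse = sqrt(sse / n),
               n_points = n, n_params = q,
               aard_percent = aard_percent(f$observed, f$predicted),
               r2 = f$r2, r2_adj = f$r2_adj,
               aic = ic$aic, aicc = ic$aicc)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$aicc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Replicate statistics and expanded uncertainty
#'
#' `sample_std` is the Bessel-corrected standard deviation of replicate
#' measurements; `expanded_uncertainty` multiplies a combined standard
#' uncertainty by the coverage factor `k` (default 2, approximately 95
#' percent confidence).
#'
#' @param values numeric vector of replicates (length >= 2).
#' @export
sample_std <- function(values) {
  if (length(values) < 2) stop("need at least two replicates")
  sqrt(sum((values - mean(values))^2) / (length(values) - 1))
}

#' @rdname sample_std
#' @param u_combined combined standard uncertainty.
#' @param k coverage factor (> 0).
#' @export
expanded_uncertainty <- function(u_combined, k = 2) {
  if (k <= 0) stop("coverage factor must be positive")
  k * u_combined
}

#' Combined relative standard uncertainty
#'
#' Root-sum-square propagation `u_c/y = sqrt(sum((P_i u(x_i)/x_i)^2))` of
#' relative input uncertainties with sensitivity coefficients `P_i`.
#'
#' @param rel_u vector of relative standard uncertainties `u(x_i)/x_i`.
#' @param sensitivity sensitivity coefficients, recycled to `length(rel_u)`.
#' @export
combined_relative_uncertainty <- function(rel_u, sensitivity = 1) {
  sqrt(sum((sensitivity * rel_u)^2))
}
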