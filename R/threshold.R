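#' Normalization constants for the threshold polynomial
#'
#' The effective-threshold polynomial is evaluated in centered and scaled
#' coordinates `(x - x0) / dx0` for `x` in (mu_V, sigma_V, tau_V_N). The
#' normalization is a pure reparameterization — rescaling it and compensating
#' the coefficients leaves the predicted rate unchanged — so its role is only
#' to keep the fitted coefficients O(1). Defaults: center the voltage mean at
#' -60 mV (scale 1 mV), the voltage fluctuation at 4 mV (scale 6 mV), the
#' dimensionless autocorrelation time at 0.5 (scale 1).
#'
#' @param mu_V0,dmu_V0 Center and scale for `mu_V` (mV).
#' @param sigma_V0,dsigma_V0 Center and scale for `sigma_V` (mV).
#' @param tau_VN0,dtau_VN0 Center and scale for `tau_V_N` (dimensionless).
#' @return A named list of class `threshold_norm`.
#' @export
threshold_norm <- function(mu_V0 = -60, dmu_V0 = 1,
                           sigma_V0 = 4, dsigma_V0 = 6,
                           tau_VN0 = 0.5, dtau_VN0 = 1) {
  stopifnot(dmu_V0 != 0, dsigma_V0 != 0, dtau_VN0 != 0)
  structure(list(mu_V0 = mu_V0, dmu_V0 = dmu_V0,
                 sigma_V0 = sigma_V0, dsigma_V0 = dsigma_V0,
                 tau_VN0 = tau_VN0, dtau_VN0 = dtau_VN0),
            class = "threshold_norm")
}

# Fixed term order shared by the polynomial, the fit design matrix and the
# coefficient tables.
threshold_terms <- c("P0", "P_muV", "P_sigmaV", "P_tauV",
                     "P_muV2", "P_sigmaV2", "P_tauV2",
                     "P_muVsigmaV", "P_muVtauV", "P_sigmaVtauV")

#' Phenomenological threshold polynomial
#'
#' A second-order polynomial in the normalized subthreshold moments
#' `(mu_V, sigma_V, tau_V_N)`: a constant, three linear terms, three squares
#' and three cross terms (ten coefficients, all in mV). Fitted to simulated
#' single-neuron rates, it gives the effective voltage threshold that makes
#' the erfc rate formula reproduce the measured transfer function.
#'
#' @param coef Named numeric vector with elements `P0`, `P_muV`, `P_sigmaV`,
#'   `P_tauV`, `P_muV2`, `P_sigmaV2`, `P_tauV2`, `P_muVsigmaV`, `P_muVtauV`,
#'   `P_sigmaVtauV` (mV). Missing terms default to 0 (`P0` must be given).
#' @param norm A [threshold_norm()].
#' @return An object of class `threshold_polynomial`.
#' @export
#' @examples
#' threshold_polynomial(c(P0 = -50, P_muV = 4))
threshold_polynomial <- function(coef, norm = threshold_norm()) {
  if (is.null(names(coef)) || !("P0" %in% names(coef))) {
    abort("`coef` must be a named vector including P0")
  }
  bad <- setdiff(names(coef), threshold_terms)
  if (length(bad) > 0) abort(paste("unknown terms:", paste(bad, collapse = ", ")))
  full <- setNames(numeric(10), threshold_terms)
  full[names(coef)] <- coef
  if (!all(is.finite(full))) abort("coefficients must be finite")
  structure(list(coef = full, norm = norm), class = "threshold_polynomial")
}

# Design matrix of the ten polynomial terms at the given moments.
threshold_design <- function(moments, norm) {
  x1 <- (moments$mu_V - norm$mu_V0) / norm$dmu_V0
  x2 <- (moments$sigma_V - norm$sigma_V0) / norm$dsigma_V0
  x3 <- (moments$tau_V_N - norm$tau_VN0) / norm$dtau_VN0
  m <- cbind(1, x1, x2, x3, x1^2, x2^2, x3^2, x1 * x2, x1 * x3, x2 * x3)
  colnames(m) <- threshold_terms
  m
}

#' Evaluate the effective threshold
#'
#' @param moments A tibble from [voltage_moments()] (any number of rows).
#' @param poly A [threshold_polynomial()].
#' @return Effective threshold(s) `V_thr_eff` in mV.
#' @export
effective_threshold <- function(moments, poly) {
  stopifnot(inherits(poly, "threshold_polynomial"))
  if (!all(is.finite(moments$mu_V), is.finite(moments$sigma_V),
           is.finite(moments$tau_V_N))) {
    abort("moments must be finite")
  }
  drop(threshold_design(moments, poly$norm) %*% poly$coef)
}

#' @export
print.threshold_polynomial <- function(x, ...) {
  cat("<threshold_polynomial> (mV)\n")
  print(round(x$coef, 4))
  invisible(x)
}

#' Published reference threshold coefficients
#'
#' Coefficient tables for the six model/cell combinations, as published with
#' the original parameterization of the normalization constants. Shipped for
#' reference and comparison only: the printed normalization scales are
#' dimensionally ambiguous, so these coefficients are not interchangeable
#' with ones fitted under this package's [threshold_norm()] defaults (the
#' polynomial value, not the coefficients, is the meaningful quantity).
#'
#' @param model `"adex"`, `"hh"` or `"ml"`.
#' @param cell `"RS"` or `"FS"`.
#' @return A [threshold_polynomial()] carrying the published coefficients
#'   and, in attribute `"reference"`, the source table row.
#' @export
reference_thresholds <- function(model = c("adex", "hh", "ml"),
                                 cell = c("RS", "FS")) {
  model <- match.arg(model)
  cell <- match.arg(cell)
  path <- system.file("extdata", "threshold_coefficients_reference.tsv",
                      package = "neuromf", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  row <- tab[tab$model == model & tab$cell == cell, ]
  coef <- setNames(as.numeric(row[1, threshold_terms]), threshold_terms)
  out <- threshold_polynomial(coef)
  attr(out, "reference") <- row
  out
}
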