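erfc <- function(x) 2 * stats::pnorm(-x * sqrt(2))
erfcinv <- function(y) -stats::qnorm(y / 2) / sqrt(2)

#' Semianalytic transfer-function model
#'
#' Bundles a fitted [threshold_polynomial()] with the synaptic and
#' connectivity context (`K_e`, `K_i`, quantal conductances, reversals) and
#' the target cell's leak parameters, so that an input rate pair
#' `(nu_e, nu_i)` maps to an output rate through the subthreshold moments and
#' the erfc formula `F = alpha / (2 tau_V) * erfc((V_thr_eff - mu_V) /
#' (sqrt(2) sigma_V))`.
#'
#' The multiplicative factor `alpha` (default 1) extends the formula to very
#' high output rates (e.g. fitting a Hodgkin-Huxley cell across its approach
#' to depolarization block); in the low-rate fluctuation-driven regime it is
#' left at 1.
#'
#' @param poly A [threshold_polynomial()].
#' @param cell A `neuron_params` object (leak fields `g_L`, `c_m`, `E_L`).
#' @param synapse [synapse_params()].
#' @param K_e,K_i Input synapse counts.
#' @param alpha Rate multiplier, >= 1.
#' @return An object of class `transfer_function`.
#' @export
transfer_function <- function(poly, cell, synapse = NULL,
                              K_e = 400, K_i = 100, alpha = 1) {
  stopifnot(inherits(poly, "threshold_polynomial"), alpha >= 1)
  synapse <- synapse %||% default_synapse(model_of(cell))
  structure(list(poly = poly, cell = cell, synapse = synapse,
                 K_e = K_e, K_i = K_i, alpha = alpha),
            class = "transfer_function")
}

#' Predicted output rate of a transfer-function model
#'
#' @param nu_e,nu_i Presynaptic rates (Hz), vectorized (recycled to common
#'   length).
#' @param tf A [transfer_function()].
#' @return Predicted output rate(s), Hz. When `sigma_V = 0` (no input
#'   fluctuations) the rate is 0 below threshold and `alpha / tau_V` above.
#' @export
#' @examples
#' tf <- transfer_function(threshold_polynomial(c(P0 = -50)), adex_params())
#' predicted_rate(4, 8, tf)
predicted_rate <- function(nu_e, nu_i, tf) {
  stopifnot(inherits(tf, "transfer_function"))
  if (any(nu_e < 0) || any(nu_i < 0)) abort("rates must be >= 0")
  mom <- voltage_moments(nu_e, nu_i, tf$cell, tf$K_e, tf$K_i, tf$synapse)
  v_thr <- effective_threshold(mom, tf$poly)
  z <- ifelse(mom$sigma_V > 0,
              (v_thr - mom$mu_V) / (sqrt(2) * mom$sigma_V),
              ifelse(mom$mu_V < v_thr, Inf, -Inf))
  1000 * tf$alpha / (2 * mom$tau_V) * erfc(z)
}

#' Effective threshold implied by an observed output rate
#'
#' Inverts the erfc rate formula at given subthreshold moments: the unique
#' `V_thr_eff` for which the formula reproduces `nu_out`. This is the first
#' stage of the fitting procedure, mapping each measured (input, output) pair
#' into threshold space where the polynomial can be fitted linearly.
#'
#' @param nu_out Observed output rate(s), Hz; must lie strictly inside the
#'   attainable range `(0, alpha / tau_V)`.
#' @param moments A row (or rows) from [voltage_moments()] with
#'   `sigma_V > 0`.
#' @param alpha Rate multiplier of the erfc formula.
#' @return Effective threshold(s), mV.
#' @export
invert_rate <- function(nu_out, moments, alpha = 1) {
  y <- 2 * moments$tau_V * (nu_out / 1000) / alpha  # erfc value, in (0, 2)
  if (any(nu_out <= 0) || any(y >= 2)) {
    abort("nu_out outside the attainable range (0, alpha / tau_V)")
  }
  if (any(moments$sigma_V <= 0)) abort("invert_rate requires sigma_V > 0")
  moments$mu_V + sqrt(2) * moments$sigma_V * erfcinv(y)
}

#' @export
print.transfer_function <- function(x, ...) {
  cat("<transfer_function: ", model_of(x$cell), " ", x$cell$cell %||% "",
      ", K_e = ", x$K_e, ", K_i = ", x$K_i, ", alpha = ", x$alpha, ">\n",
      sep = "")
  print(x$poly)
  invisible(x)
}

# A plain vectorized function (nu_e, nu_i) -> Hz for the mean-field hot loop.
# Same math as predicted_rate() but without tibble construction; the two
# paths are asserted equal in the test suite.
tf_as_function <- function(tf) {
  stopifnot(inherits(tf, "transfer_function"))
  s <- tf$synapse
  g_L <- tf$cell$g_L
  c_m <- tf$cell$c_m
  E_L <- tf$cell$E_L
  K_e <- tf$K_e
  K_i <- tf$K_i
  nrm <- tf$poly$norm
  cf <- tf$poly$coef
  alpha <- tf$alpha
  function(nu_e, nu_i) {
    ne <- nu_e / 1000
    ni <- nu_i / 1000
    mu_Ge <- ne * K_e * s$tau * s$Q_e
    mu_Gi <- ni * K_i * s$tau * s$Q_i
    mu_G <- mu_Ge + mu_Gi + g_L
    tau_m <- c_m / mu_G
    mu_V <- (mu_Ge * s$E_e + mu_Gi * s$E_i + g_L * E_L) / mu_G
    U_e <- s$Q_e * (s$E_e - mu_V) / mu_G
    U_i <- s$Q_i * (s$E_i - mu_V) / mu_G
    we <- K_e * ne * (U_e * s$tau)^2
    wi <- K_i * ni * (U_i * s$tau)^2
    sigma_V <- sqrt((we + wi) / (2 * (tau_m + s$tau)))
    den <- (we + wi) / (tau_m + s$tau)
    tau_V <- ifelse(den > 0, (we + wi) / den, tau_m)
    x1 <- (mu_V - nrm$mu_V0) / nrm$dmu_V0
    x2 <- (sigma_V - nrm$sigma_V0) / nrm$dsigma_V0
    x3 <- (tau_V * g_L / c_m - nrm$tau_VN0) / nrm$dtau_VN0
    v_thr <- cf[1] + cf[2] * x1 + cf[3] * x2 + cf[4] * x3 +
      cf[5] * x1^2 + cf[6] * x2^2 + cf[7] * x3^2 +
      cf[8] * x1 * x2 + cf[9] * x1 * x3 + cf[10] * x2 * x3
    z <- ifelse(sigma_V > 0, (v_thr - mu_V) / (sqrt(2) * sigma_V),
                ifelse(mu_V < v_thr, Inf, -Inf))
    1000 * alpha / (2 * tau_V) * erfc(z)
  }
}
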