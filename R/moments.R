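#' Stationary conductance moments under Poissonian input
#'
#' Mean and standard deviation of the excitatory and inhibitory synaptic
#' conductances produced by `K_e` excitatory synapses firing at `nu_e` Hz and
#' `K_i` inhibitory synapses at `nu_i` Hz through exponential-decay synapses
#' (shot-noise statistics): `mu_G = nu K tau Q` and
#' `sigma_G = Q * sqrt(nu K tau / 2)`.
#'
#' @param nu_e,nu_i Per-synapse presynaptic rates (Hz), vectorized.
#' @param K_e,K_i Input synapse counts.
#' @param synapse [synapse_params()].
#' @return A tibble with columns `nu_e`, `nu_i`, `mu_Ge`, `sigma_Ge`,
#'   `mu_Gi`, `sigma_Gi` (nS).
#' @export
#' @examples
#' conductance_moments(4, 0, K_e = 400, K_i = 100) # mu_Ge = 12, sigma_Ge = 3
conductance_moments <- function(nu_e, nu_i, K_e = 400, K_i = 100,
                                synapse = synapse_params()) {
  if (any(nu_e < 0) || any(nu_i < 0)) abort("presynaptic rates must be >= 0")
  ne <- nu_e / 1000  # Hz -> 1/ms
  ni <- nu_i / 1000
  tibble(nu_e = nu_e, nu_i = nu_i,
         mu_Ge = ne * K_e * synapse$tau * synapse$Q_e,
         sigma_Ge = synapse$Q_e * sqrt(ne * K_e * synapse$tau / 2),
         mu_Gi = ni * K_i * synapse$tau * synapse$Q_i,
         sigma_Gi = synapse$Q_i * sqrt(ni * K_i * synapse$tau / 2))
}

#' Subthreshold membrane-voltage moments
#'
#' Maps presynaptic rates to the statistics of the subthreshold membrane
#' voltage of a passive (leak + synapses only) membrane: mean `mu_V`,
#' standard deviation `sigma_V`, autocorrelation time `tau_V` and its
#' dimensionless form `tau_V_N = tau_V * g_L / c_m`. Spike-generating and
#' adaptation currents are deliberately excluded; the fitted effective
#' threshold absorbs their mean effect.
#'
#' The total input conductance `mu_G = mu_Ge + mu_Gi + g_L` sets the
#' effective membrane time constant `tau_m_eff = c_m / mu_G`; the voltage
#' mean is the conductance-weighted combination of the reversal potentials,
#' and the fluctuation statistics follow from shot-noise filtering with
#' synaptic efficacies `U_s = Q_s (E_s - mu_V) / mu_G`.
#'
#' @param nu_e,nu_i Per-synapse presynaptic rates (Hz), vectorized.
#' @param cell A `neuron_params` object supplying `g_L`, `c_m`, `E_L` of the
#'   target cell (only the leak fields are used).
#' @param K_e,K_i Input synapse counts.
#' @param synapse [synapse_params()].
#' @return A tibble with columns `nu_e`, `nu_i`, `mu_Ge`, `sigma_Ge`,
#'   `mu_Gi`, `sigma_Gi`, `mu_G` (nS), `tau_m_eff` (ms), `mu_V` (mV),
#'   `sigma_V` (mV), `tau_V` (ms), `tau_V_N` (dimensionless).
#' @export
#' @examples
#' voltage_moments(4, 8, adex_params("RS"))
voltage_moments <- function(nu_e, nu_i, cell = adex_params("RS"),
                            K_e = 400, K_i = 100,
                            synapse = synapse_params()) {
  g <- conductance_moments(nu_e, nu_i, K_e, K_i, synapse)
  g_L <- cell$g_L
  c_m <- cell$c_m
  mu_G <- g$mu_Ge + g$mu_Gi + g_L
  tau_m <- c_m / mu_G
  mu_V <- (g$mu_Ge * synapse$E_e + g$mu_Gi * synapse$E_i + g_L * cell$E_L) / mu_G

  ne <- g$nu_e / 1000
  ni <- g$nu_i / 1000
  U_e <- synapse$Q_e * (synapse$E_e - mu_V) / mu_G
  U_i <- synapse$Q_i * (synapse$E_i - mu_V) / mu_G
  tau_s <- synapse$tau
  we <- K_e * ne * (U_e * tau_s)^2
  wi <- K_i * ni * (U_i * tau_s)^2
  sigma_V <- sqrt(we / (2 * (tau_m + tau_s)) + wi / (2 * (tau_m + tau_s)))
  num <- we + wi
  den <- we / (tau_m + tau_s) + wi / (tau_m + tau_s)
  tau_V <- ifelse(den > 0, num / den, tau_m)

  tibble(nu_e = g$nu_e, nu_i = g$nu_i,
         mu_Ge = g$mu_Ge, sigma_Ge = g$sigma_Ge,
         mu_Gi = g$mu_Gi, sigma_Gi = g$sigma_Gi,
         mu_G = mu_G, tau_m_eff = tau_m,
         mu_V = mu_V, sigma_V = sigma_V,
         tau_V = tau_V, tau_V_N = tau_V * g_L / c_m)
}
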