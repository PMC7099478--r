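#' One forward-Euler step of the AdEx model
#'
#' Advances the two-variable AdEx state by `dt` under fixed synaptic
#' conductances. If the updated voltage exceeds the numerical spike cutoff
#' `v_cut` (see [adex_params()]), the voltage is reset to `v_rest`, the
#' adaptation variable is incremented by `b`, and `spiked` is raised; the
#' caller is responsible for holding the neuron at `v_rest` for the
#' refractory time `T_refr` (see [simulate_neuron()], which tracks
#' refractory clocks).
#'
#' @param state Named list or vector with elements `v` (mV) and `w` (pA).
#' @param params [adex_params()].
#' @param g_e,g_i Instantaneous excitatory / inhibitory conductances (nS).
#' @param dt Time step (ms).
#' @param synapse [synapse_params()] providing the reversal potentials.
#' @return A list with `state` (the updated `v`, `w`) and `spiked` (logical).
#' @export
#' @examples
#' p <- adex_params("RS")
#' adex_step(list(v = -65, w = 0), p, g_e = 0, g_i = 0, dt = 0.1)
adex_step <- function(state, params, g_e, g_i, dt, synapse = synapse_params()) {
  stopifnot(dt > 0)
  v <- state$v
  w <- state$w
  if (!all(is.finite(c(v, w)))) {
    abort(paste0("integration failure: non-finite ",
                 if (!is.finite(v)) "v" else "w"))
  }
  i_syn <- g_e * (synapse$E_e - v) + g_i * (synapse$E_i - v)
  dv <- (params$g_L * (params$E_L - v) +
           params$g_L * params$Delta * exp((v - params$v_t) / params$Delta) -
           w + i_syn) / params$c_m
  dw <- (params$a * (v - params$E_L) - w) / params$tau_w
  v <- v + dt * dv
  w <- w + dt * dw
  spiked <- v > params$v_cut
  if (spiked) {
    v <- params$v_rest
    w <- w + params$b
  }
  list(state = list(v = v, w = w), spiked = spiked)
}

#' Hodgkin-Huxley gating rates
#'
#' Voltage-dependent opening/closing rates of the n, m, h gates and the
#' steady state / time constant of the slow I_M gate p. The three removable
#' singularities (at `v = V_T + 15` for alpha_n, `V_T + 13` for alpha_m and
#' `V_T + 40` for beta_m) are evaluated by their analytic limits, so the
#' functions are continuous everywhere.
#'
#' @param v Membrane potential(s), mV. Vectorized.
#' @param params [hh_params()].
#' @return A tibble with columns `v`, `alpha_n`, `beta_n`, `alpha_m`,
#'   `beta_m`, `alpha_h`, `beta_h` (1/ms), `p_inf` and `tau_p` (ms).
#' @export
#' @examples
#' hh_gating_rates(c(-65, -53.5 + 15), hh_params())
hh_gating_rates <- function(v, params = hh_params()) {
  stopifnot(all(is.finite(v)))
  m <- hh_rates_cpp(as.numeric(v), params$V_T, params$tau_max)
  tibble(v = as.numeric(v),
         alpha_n = m[, 1], beta_n = m[, 2],
         alpha_m = m[, 3], beta_m = m[, 4],
         alpha_h = m[, 5], beta_h = m[, 6],
         p_inf = m[, 7], tau_p = m[, 8])
}

#' Hodgkin-Huxley time derivatives
#'
#' Right-hand side of the five-dimensional HH system under fixed synaptic
#' conductances.
#'
#' @param state Named list with `v` (mV) and gating variables `n`, `m`, `h`,
#'   `p` in `[0, 1]`.
#' @param params [hh_params()].
#' @param synapse [synapse_params()].
#' @param g_e,g_i Synaptic conductances (nS).
#' @return Named list of time derivatives (`v` in mV/ms, gates in 1/ms).
#' @export
hh_derivatives <- function(state, params, synapse = synapse_params(),
                           g_e = 0, g_i = 0) {
  with(state, {
    if (!all(is.finite(c(v, n, m, h, p)))) abort("non-finite HH state")
    stopifnot(n >= 0, n <= 1, m >= 0, m <= 1, h >= 0, h <= 1, p >= 0, p <= 1)
    r <- hh_gating_rates(v, params)
    i_syn <- g_e * (synapse$E_e - v) + g_i * (synapse$E_i - v)
    dv <- (params$g_L * (params$E_L - v) +
             params$g_Na * m^3 * h * (params$E_Na - v) +
             params$g_K * n^4 * (params$E_K - v) +
             params$g_M * p * (params$E_K - v) + i_syn) / params$c_m
    list(v = dv,
         n = r$alpha_n * (1 - n) - r$beta_n * n,
         m = r$alpha_m * (1 - m) - r$beta_m * m,
         h = r$alpha_h * (1 - h) - r$beta_h * h,
         p = (r$p_inf - p) / r$tau_p)
  })
}

# Steady-state HH gating at voltage v (used for initial conditions).
hh_steady_gates <- function(v, params = hh_params()) {
  r <- hh_gating_rates(v, params)
  list(n = r$alpha_n / (r$alpha_n + r$beta_n),
       m = r$alpha_m / (r$alpha_m + r$beta_m),
       h = r$alpha_h / (r$alpha_h + r$beta_h),
       p = r$p_inf)
}

#' Morris-Lecar activation curves
#'
#' Instantaneous calcium activation `M_ss`, potassium steady state `N_ss`
#' and potassium relaxation time `tau_N` as functions of voltage.
#'
#' @param v Membrane potential(s), mV. Vectorized.
#' @param params [ml_params()].
#' @return A tibble with columns `v`, `M_ss`, `N_ss` (both in (0, 1)) and
#'   `tau_N` (ms).
#' @export
#' @examples
#' ml_activation(c(-1.2, 2), ml_params())
ml_activation <- function(v, params = ml_params()) {
  stopifnot(all(is.finite(v)))
  tibble(v = as.numeric(v),
         M_ss = 0.5 * (1 + tanh((v - params$V1) / params$V2)),
         N_ss = 0.5 * (1 + tanh((v - params$V3) / params$V4)),
         tau_N = 1 / (2 * params$phi * cosh((v - params$V3) / (2 * params$V4))))
}

#' Morris-Lecar time derivatives
#'
#' Right-hand side of the two-variable ML system, including the reference DC
#' current `I0`, under fixed synaptic conductances.
#'
#' @param state Named list with `v` (mV) and `N` in `[0, 1]`.
#' @param params [ml_params()].
#' @param synapse [synapse_params()].
#' @param g_e,g_i Synaptic conductances (nS).
#' @return Named list of time derivatives.
#' @export
ml_derivatives <- function(state, params, synapse = default_synapse("ml"),
                           g_e = 0, g_i = 0) {
  with(state, {
    if (!all(is.finite(c(v, N)))) abort("non-finite ML state")
    stopifnot(N >= 0, N <= 1)
    act <- ml_activation(v, params)
    i_syn <- g_e * (synapse$E_e - v) + g_i * (synapse$E_i - v)
    dv <- (params$g_L * (params$E_L - v) +
             params$g_Ca * act$M_ss * (params$E_Ca - v) +
             params$g_K * N * (params$E_K - v) + i_syn + params$I0) / params$c_m
    list(v = dv, N = (act$N_ss - N) / act$tau_N)
  })
}

#' Detect spikes in a voltage trace
#'
#' One spike per upward crossing of the threshold; after a crossing, no new
#' spike is registered until the trace has fallen back below threshold
#' (debouncing). This is how spike times are defined for the HH and ML
#' models, whose voltage traces are continuous through the action potential.
#'
#' @param trace A uniformly sampled voltage trace: either a numeric vector of
#'   voltages or a data frame with columns `t` (ms) and `v` (mV).
#' @param threshold Detection threshold (mV), default 10.
#' @param dt Sampling interval (ms), used when `trace` is a bare vector.
#' @return Numeric vector of spike times (ms); empty for an empty trace.
#' @export
#' @examples
#' detect_spikes(seq(-70, 20, length.out = 91), threshold = 10, dt = 0.1)
detect_spikes <- function(trace, threshold = 10, dt = 1) {
  if (is.data.frame(trace)) {
    t <- trace$t
    v <- trace$v
  } else {
    v <- as.numeric(trace)
    t <- seq_along(v) * dt
  }
  if (length(v) == 0) return(numeric(0))
  above <- v >= threshold
  crossing <- which(above & !c(TRUE, above[-length(above)]))
  t[crossing]
}
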