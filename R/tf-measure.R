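#' Measure a transfer function by single-neuron simulation
#'
#' Simulates one neuron per grid point under Poissonian bombardment and
#' averages the output rate over seeds. Deterministic given `seeds`.
#'
#' @param params A `neuron_params` object.
#' @param grid A data frame with columns `nu_e`, `nu_i` (Hz).
#' @param synapse [synapse_params()]; model default if `NULL`.
#' @param K_e,K_i Input synapse counts.
#' @param duration Simulated time per point (ms).
#' @param seeds Integer vector of seeds; one simulation per seed per point.
#' @param burn Transient excluded from rate estimates (ms).
#' @param dt Integration step; model default if `NULL`.
#' @return A tibble with columns `nu_e`, `nu_i`, `rate` (mean over seeds,
#'   Hz), `sem` (standard error over seeds) and `n_seeds`, of class
#'   `tf_measurement` with the measurement context in attributes.
#' @export
measure_transfer_function <- function(params, grid, synapse = NULL,
                                      K_e = 400, K_i = 100,
                                      duration = 10000, seeds = 1:4,
                                      burn = 500, dt = NULL) {
  if (nrow(grid) == 0) abort("empty measurement grid")
  model <- model_of(params)
  synapse <- synapse %||% default_synapse(model)
  out <- purrr::pmap_dfr(grid[, c("nu_e", "nu_i")], function(nu_e, nu_i) {
    rates <- vapply(seeds, function(s) {
      simulate_neuron(params = params, synapse = synapse,
                      nu_e = nu_e, nu_i = nu_i, K_e = K_e, K_i = K_i,
                      duration = duration, seed = s, dt = dt,
                      burn = burn)$rate
    }, numeric(1))
    tibble(nu_e = nu_e, nu_i = nu_i, rate = mean(rates),
           sem = if (length(rates) > 1) sd(rates) / sqrt(length(rates)) else NA_real_,
           n_seeds = length(rates))
  })
  structure(out, class = c("tf_measurement", class(out)),
            model = model, cell = params$cell, params = params,
            synapse = synapse, K_e = K_e, K_i = K_i,
            duration = duration, seeds = seeds)
}

#' Build a measurement grid spanning the fluctuation-driven regime
#'
#' For each inhibitory background rate in `nu_i`, locates by bisection the
#' excitatory rate at which the neuron's output reaches `rate_max` Hz (using
#' short pilot simulations), then places `n_nu_e` points from 0 up to that
#' edge. This concentrates the grid on the low-rate region where the
#' semianalytic formula is valid.
#'
#' @param params A `neuron_params` object.
#' @param nu_i Inhibitory background rates (Hz).
#' @param n_nu_e Number of excitatory rates per background.
#' @param rate_max Output rate (Hz) defining the upper grid edge.
#' @param nu_e_max Upper bound for the bisection search (Hz).
#' @param synapse,K_e,K_i Measurement context, as in
#'   [measure_transfer_function()].
#' @param pilot_duration,pilot_seed Length (ms) and seed of the pilot
#'   simulations used by the bisection.
#' @return A tibble with columns `nu_e`, `nu_i`.
#' @export
tf_grid <- function(params, nu_i = c(0.5, 2, 4, 6, 8, 12, 16, 20),
                    n_nu_e = 12, rate_max = 30, nu_e_max = 60,
                    synapse = NULL, K_e = 400, K_i = 100,
                    pilot_duration = 2000, pilot_seed = 1) {
  model <- model_of(params)
  synapse <- synapse %||% default_synapse(model)
  rate_at <- function(nu_e, nu_i) {
    simulate_neuron(params = params, synapse = synapse, nu_e = nu_e,
                    nu_i = nu_i, K_e = K_e, K_i = K_i,
                    duration = pilot_duration, seed = pilot_seed,
                    burn = min(500, pilot_duration / 4))$rate
  }
  purrr::map_dfr(nu_i, function(ni) {
    lo <- 0
    hi <- nu_e_max
    if (rate_at(hi, ni) < rate_max) {
      edge <- hi  # never reaches rate_max (e.g. depolarization block)
    } else {
      for (it in 1:12) {
        mid <- (lo + hi) / 2
        if (rate_at(mid, ni) < rate_max) lo <- mid else hi <- mid
      }
      edge <- hi
    }
    tibble(nu_e = seq(0, edge, length.out = n_nu_e + 1)[-1], nu_i = ni)
  })
}
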