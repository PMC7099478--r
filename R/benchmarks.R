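#' Depolarization-block sweep of a single neuron
#'
#' Sweeps the excitatory Poisson input rate upward (inhibitory background
#' fixed) and measures the output rate at each level. For models with a
#' depolarization block the curve rises, peaks and collapses; the attributes
#' `peak_rate` and `peak_nu_e` report the maximum sustained rate and the
#' input at which it occurs.
#'
#' @param params Neuron parameters; default Hodgkin-Huxley RS, whose block
#'   appears only at very high rates.
#' @param nu_e Excitatory input rates to sweep (Hz); default a logarithmic
#'   grid up to 1000 Hz.
#' @param nu_i Inhibitory background rate (Hz).
#' @param K_e,K_i Input synapse counts.
#' @param duration Simulated time per level (ms).
#' @param seed Seed (one simulation per level).
#' @param synapse,dt Passed to [simulate_neuron()].
#' @return A tibble `(nu_e, rate)` with attributes `peak_rate`, `peak_nu_e`.
#' @export
depolarization_block_sweep <- function(params = hh_params("RS"),
                                       nu_e = 10^seq(0, 3, length.out = 20),
                                       nu_i = 8, K_e = 400, K_i = 100,
                                       duration = 5000, seed = 1,
                                       synapse = NULL, dt = NULL) {
  model <- model_of(params)
  synapse <- synapse %||% default_synapse(model)
  rates <- vapply(nu_e, function(ne) {
    simulate_neuron(params = params, synapse = synapse, nu_e = ne,
                    nu_i = nu_i, K_e = K_e, K_i = K_i, duration = duration,
                    seed = seed, dt = dt, burn = min(500, duration / 5))$rate
  }, numeric(1))
  out <- tibble(nu_e = nu_e, rate = rates)
  structure(out, class = c("db_sweep", class(out)),
            peak_rate = max(rates), peak_nu_e = nu_e[which.max(rates)])
}

#' Maximal local slope (gain) of a measured transfer-function curve
#'
#' Finite-difference slope of output rate versus excitatory input rate along
#' a fixed inhibitory background.
#'
#' @param measurement A tibble with columns `nu_e`, `rate` (one `nu_i`).
#' @return The maximum local slope (dimensionless, Hz output per Hz input).
#' @export
tf_gain <- function(measurement) {
  m <- dplyr::arrange(measurement, .data$nu_e)
  max(diff(m$rate) / diff(m$nu_e))
}

#' Measure a one-row transfer-function curve over a target output range
#'
#' Locates by bisection the excitatory input rates at which the output
#' crosses `rate_range`, then measures `n` points between them. Used to
#' compare RS and FS gains in the fluctuation-driven region.
#'
#' @param params Neuron parameters.
#' @param nu_i Inhibitory background (Hz).
#' @param rate_range Output-rate window (Hz) delimiting the curve.
#' @param n Number of measured points.
#' @param duration,seeds Measurement length (ms) and seeds per point.
#' @param synapse,K_e,K_i Measurement context.
#' @param nu_e_max Bisection upper bound (Hz).
#' @return A `tf_measurement` tibble restricted to one `nu_i`.
#' @export
tf_gain_curve <- function(params, nu_i = 8, rate_range = c(1, 20), n = 10,
                          duration = 10000, seeds = 1:4, synapse = NULL,
                          K_e = 400, K_i = 100, nu_e_max = 60) {
  model <- model_of(params)
  synapse <- synapse %||% default_synapse(model)
  rate_at <- function(ne) {
    simulate_neuron(params = params, synapse = synapse, nu_e = ne,
                    nu_i = nu_i, K_e = K_e, K_i = K_i, duration = 2000,
                    seed = seeds[1], burn = 500)$rate
  }
  edge <- function(target) {
    lo <- 0
    hi <- nu_e_max
    for (it in 1:12) {
      mid <- (lo + hi) / 2
      if (rate_at(mid) < target) lo <- mid else hi <- mid
    }
    hi
  }
  lo_edge <- edge(rate_range[1])
  hi_edge <- max(edge(rate_range[2]), lo_edge * 1.2)
  grid <- tibble(nu_e = seq(lo_edge, hi_edge, length.out = n), nu_i = nu_i)
  measure_transfer_function(params, grid, synapse, K_e, K_i,
                            duration = duration, seeds = seeds)
}

#' FS / RS gain ratio of the AdEx transfer functions
#'
#' Measures both cells' transfer-function curves at a fixed inhibitory
#' background over the fluctuation-driven output window and reports the
#' ratio of their maximal local slopes (FS gain is the larger, by roughly a
#' factor 3-4 in the reference setting).
#'
#' @param model Neuron model id.
#' @param nu_i,rate_range,n,duration,seeds As in [tf_gain_curve()].
#' @return A list with `ratio`, `gain_fs`, `gain_rs` and the two
#'   measurement tibbles.
#' @export
gain_ratio <- function(model = "adex", nu_i = 8, rate_range = c(1, 20),
                       n = 10, duration = 10000, seeds = 1:4) {
  rs <- tf_gain_curve(neuron_params(model, "RS"), nu_i, rate_range, n,
                      duration, seeds)
  fs <- tf_gain_curve(neuron_params(model, "FS"), nu_i, rate_range, n,
                      duration, seeds)
  g_rs <- tf_gain(rs)
  g_fs <- tf_gain(fs)
  list(ratio = g_fs / g_rs, gain_fs = g_fs, gain_rs = g_rs,
       curve_rs = rs, curve_fs = fs)
}

#' Input rate at which a measured transfer function peaks
#'
#' Measures the transfer function on a regular excitatory-rate grid and
#' reports the input at the maximum of the measured curve — for the
#' Morris-Lecar model, the onset of the firing-rate decrease caused by
#' depolarization block.
#'
#' The peak position is localized below the grid spacing by fitting a
#' quadratic to the measured curve in a window around the raw argmax and
#' taking its vertex (standard sub-grid peak localization; on a broad noisy
#' maximum the raw argmax alone jitters by several grid steps).
#'
#' @param params Neuron parameters; default Morris-Lecar RS.
#' @param nu_e Excitatory input grid (Hz).
#' @param nu_i Inhibitory background (Hz).
#' @param duration,seeds Measurement length (ms) and seeds.
#' @param window Half-width (Hz) of the quadratic-vertex window.
#' @return A list with `peak_nu_e` (vertex estimate), `peak_nu_e_argmax`
#'   (raw grid argmax), `peak_rate` and the `measurement`.
#' @export
tf_peak_input <- function(params = ml_params("RS"),
                          nu_e = seq(0, 20, by = 0.5), nu_i = 8,
                          duration = 10000, seeds = 1:4, window = 3) {
  m <- measure_transfer_function(params, tibble(nu_e = nu_e, nu_i = nu_i),
                                 duration = duration, seeds = seeds)
  i_max <- which.max(m$rate)
  keep <- abs(m$nu_e - m$nu_e[i_max]) <= window
  peak <- m$nu_e[i_max]
  if (sum(keep) >= 4) {
    q <- lm(rate ~ nu_e + I(nu_e^2), data = m[keep, ])
    b <- coef(q)
    if (is.finite(b[3]) && b[3] < 0) {
      vertex <- -b[2] / (2 * b[3])
      # only trust the vertex inside the fitted window
      if (abs(vertex - m$nu_e[i_max]) <= window) peak <- unname(vertex)
    }
  }
  list(peak_nu_e = peak, peak_nu_e_argmax = m$nu_e[i_max],
       peak_rate = max(m$rate), measurement = m)
}

#' Mean per-neuron firing rates of a simulated network
#'
#' @param raster A `spike_raster`.
#' @param t_start Spikes before this time (ms) are discarded as transient.
#' @return A tibble `(population, mean_rate)` in Hz per neuron.
#' @export
mean_population_rates <- function(raster, t_start = 0) {
  n_pop <- c(exc = attr(raster, "n_exc"), inh = attr(raster, "n_inh"))
  window <- attr(raster, "duration") - t_start
  purrr::map_dfr(c("exc", "inh"), function(p) {
    n_sp <- sum(raster$population == p & raster$t > t_start)
    tibble(population = p, mean_rate = 1000 * n_sp / (n_pop[[p]] * window))
  })
}
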