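#' Network configuration
#'
#' A random directed network of `N` neurons, a fraction `frac_exc` of which
#' are excitatory RS cells and the rest inhibitory FS cells. Each ordered
#' pair is connected independently with probability `p_conn`. Every neuron
#' additionally receives an external excitatory drive through `K_e_ext`
#' independent Poisson synapses, each firing at `nu_drive` Hz.
#'
#' The reference configuration is `N = 10^4`, `p_conn = 0.05`, giving mean
#' in-degrees `K_e = 400`, `K_i = 100`. Smaller desk-scale networks should
#' preserve those in-degrees by scaling `p_conn` up (e.g. `N = 2500`,
#' `p_conn = 0.2`), since the single-neuron input statistics — which is what
#' the mean field sees — depend on `K`, not on `N`.
#'
#' @param N Total number of neurons (>= 2).
#' @param frac_exc Excitatory fraction, in (0, 1).
#' @param p_conn Connection probability, in (0, 1].
#' @param nu_drive External drive rate per external synapse (Hz).
#' @param K_e_ext Number of external drive synapses per neuron.
#' @param seed Integer seed for connectivity and simulation noise.
#' @return An object of class `network_config`.
#' @export
network_config <- function(N = 10000, frac_exc = 0.8, p_conn = 0.05,
                           nu_drive = 4, K_e_ext = 400, seed = 1) {
  stopifnot(N >= 2, frac_exc > 0, frac_exc < 1, p_conn >= 0, p_conn <= 1,
            nu_drive >= 0, K_e_ext >= 0)
  structure(list(N = as.integer(N), frac_exc = frac_exc, p_conn = p_conn,
                 nu_drive = nu_drive, K_e_ext = as.integer(K_e_ext),
                 seed = as.integer(seed)),
            class = "network_config")
}

#' Desk-scale network preserving reference in-degrees
#'
#' Scales `p_conn` so that `p_conn * N` stays at the reference value
#' (500 synapses from a 10^4-neuron network at p = 0.05).
#'
#' @param N Network size.
#' @param ... Passed to [network_config()].
#' @return A `network_config`.
#' @export
scaled_network_config <- function(N = 2500, ...) {
  network_config(N = N, p_conn = min(1, 0.05 * 10000 / N), ...)
}

#' Build the random directed connectivity
#'
#' Each ordered pair (i, j), i != j, is connected independently with
#' probability `p_conn`; deterministic given `config$seed`.
#'
#' @param config A [network_config()].
#' @return A sparse logical adjacency matrix (`Matrix::ngCMatrix`), with
#'   `A[i, j] == TRUE` meaning a synapse from i onto j. The excitatory
#'   neurons are indices `1..round(N * frac_exc)`.
#' @export
build_connectivity <- function(config) {
  set.seed(config$seed)
  csr <- build_connectivity_cpp(config$N, config$p_conn)
  n_per_source <- diff(csr$ptr)
  Matrix::sparseMatrix(i = rep.int(seq_len(config$N), n_per_source),
                       j = csr$targets + 1L,
                       dims = c(config$N, config$N))
}

# CSR (by source) form used by the simulation kernel.
connectivity_csr <- function(adjacency) {
  tr <- Matrix::t(adjacency)  # ngCMatrix is column-compressed; transpose -> by source
  list(ptr = tr@p, targets = tr@i)
}

#' Generate a homogeneous Poisson spike train
#'
#' @param rate Rate (Hz), >= 0.
#' @param duration Duration (ms).
#' @param seed Integer seed.
#' @return Sorted spike times in (0, duration], ms.
#' @export
#' @examples
#' length(generate_poisson_train(100, 10000, seed = 1)) # ~1000
generate_poisson_train <- function(rate, duration, seed = NULL) {
  if (rate < 0) abort("rate must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || duration <= 0) return(numeric(0))
  # draw slightly more exponential gaps than needed, then trim
  n_guess <- ceiling(rate * duration / 1000 + 4 * sqrt(rate * duration / 1000) + 10)
  t <- cumsum(rexp(n_guess, rate / 1000))
  while (length(t) > 0 && t[length(t)] <= duration) {
    t <- c(t, t[length(t)] + cumsum(rexp(n_guess, rate / 1000)))
  }
  t[t <= duration]
}

#' Simulate the spiking network
#'
#' Event-driven conductance coupling on the integration grid: every
#' presynaptic spike at step k increments its targets' excitatory or
#' inhibitory conductance by `Q_e` or `Q_i` from step k+1 on (no axonal
#' delays), decaying exponentially with time constant `tau`. The external
#' drive adds an independent excitatory Poisson stream of total rate
#' `K_e_ext * (nu_drive + stimulus(t))` per neuron.
#'
#' @param model `"adex"`, `"hh"` or `"ml"`.
#' @param config A [network_config()].
#' @param params_exc,params_inh Neuron parameters per population; defaults
#'   are the model's RS and FS presets.
#' @param synapse [synapse_params()]; default [default_synapse()].
#' @param stimulus Optional [stimulus_profile()] adding a time-varying rate
#'   to the external drive of every neuron.
#' @param duration Simulated time (ms).
#' @param dt Integration step (ms); model default if `NULL`.
#' @param adjacency Optional precomputed adjacency from
#'   [build_connectivity()]; built from `config` if missing.
#' @return A `spike_raster`: a tibble with columns `neuron` (1-based id),
#'   `t` (ms) and `population` (factor `"exc"`/`"inh"`), with attributes
#'   `N`, `n_exc`, `n_inh`, `duration`, `model`.
#' @export
simulate_network <- function(model = c("adex", "hh", "ml"), config,
                             params_exc = NULL, params_inh = NULL,
                             synapse = NULL, stimulus = NULL,
                             duration = 10000, dt = NULL, adjacency = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(config, "network_config"), duration > 0)
  params_exc <- params_exc %||% neuron_params(model, "RS")
  params_inh <- params_inh %||% neuron_params(model, "FS")
  if (model_of(params_exc) != model || model_of(params_inh) != model) {
    abort("population parameters do not match `model`")
  }
  synapse <- synapse %||% default_synapse(model)
  dt <- dt %||% default_dt(model)
  if (is.null(adjacency)) adjacency <- build_connectivity(config)
  csr <- connectivity_csr(adjacency)

  n_exc <- round(config$N * config$frac_exc)
  pop <- c(rep(0L, n_exc), rep(1L, config$N - n_exc))
  pars <- cbind(param_vector(params_exc), param_vector(params_inh))

  n_steps <- round(duration / dt)
  stim_vec <- if (is.null(stimulus)) numeric(0) else {
    stimulus_rate((seq_len(n_steps) - 1) * dt, stimulus)
  }

  # Desynchronized initial condition: conductances start at the stationary
  # mean of the external drive plus a balancing inhibitory conductance
  # (keeps the initial mean voltage near E_L), voltages jittered around E_L.
  # Without this the synchronized onset of the drive can kick the network
  # into a saturated runaway state instead of the asynchronous regime.
  ge0 <- config$K_e_ext * config$nu_drive * synapse$tau * synapse$Q_e / 1000
  E_L_e <- params_exc$E_L
  gi0 <- ge0 * (synapse$E_e - E_L_e) / (E_L_e - synapse$E_i)

  set.seed(config$seed + 1L)  # connectivity used seed; offset for dynamics
  # HH networks start from an adapted state (slow K+ gate p elevated to 0.5):
  # the I_M current needs ~100 ms to build, and an unadapted synchronized
  # onset can fall into a saturated high-rate state instead of the
  # asynchronous regime the adapted network sustains.
  p0 <- if (model == "hh") 0.5 else NA_real_
  res <- sim_network_cpp(model_id(model), pars, pop, synapse_vector(synapse),
                         csr$ptr, csr$targets, config$K_e_ext,
                         config$nu_drive, stim_vec, duration, dt,
                         v_init_jitter = 5, ge0 = ge0, gi0 = gi0,
                         v0_center = NA_real_, p0_init = p0)
  raster <- tibble(neuron = res$neuron, t = res$t,
                   population = factor(ifelse(res$neuron <= n_exc,
                                              "exc", "inh"),
                                       levels = c("exc", "inh")))
  structure(raster,
            class = c("spike_raster", class(raster)),
            N = config$N, n_exc = n_exc, n_inh = config$N - n_exc,
            duration = duration, model = model)
}

#' Population firing-rate series and summary statistics
#'
#' Bins each population's spikes into windows of width `window`; the rate in
#' a window is `count / (window * population size)`. The summary reports each
#' population's mean rate, rate variance across windows, and autocorrelation
#' time (first lag at which the normalized autocorrelation of the rate series
#' drops below 1/e).
#'
#' @param raster A `spike_raster` from [simulate_network()].
#' @param window Window width (ms). 5 ms resolves the time course; 20 ms
#'   (the mean field's Markovian timescale) is the width used when comparing
#'   rate histograms with mean-field covariance predictions.
#' @param t_start Discard spikes before this time (ms), e.g. an equilibration
#'   transient.
#' @return A list with `series`, a tibble (`t` = window center, `population`,
#'   `rate` in Hz) and `summary`, a tibble (`population`, `mean_rate`,
#'   `var_rate`, `sd_rate`, `acf_time`).
#' @export
population_rate <- function(raster, window = 5, t_start = 0) {
  stopifnot(window > 0)
  duration <- attr(raster, "duration")
  if (window > duration - t_start) abort("window larger than (remaining) duration")
  n_pop <- c(exc = attr(raster, "n_exc"), inh = attr(raster, "n_inh"))
  breaks <- seq(t_start, duration, by = window)
  if (tail(breaks, 1) < duration) breaks <- c(breaks, tail(breaks, 1) + window)
  n_bins <- length(breaks) - 1
  mid <- (breaks[-1] + breaks[-length(breaks)]) / 2

  series <- purrr::map_dfr(c("exc", "inh"), function(p) {
    ts <- raster$t[raster$population == p & raster$t > t_start]
    counts <- tabulate(findInterval(ts, breaks, left.open = TRUE,
                                    rightmost.closed = TRUE),
                       nbins = n_bins)
    tibble(t = mid, population = p,
           rate = 1000 * counts / (window * n_pop[[p]]))
  })
  series$population <- factor(series$population, levels = c("exc", "inh"))

  summary <- series |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mean_rate = mean(.data$rate),
                     var_rate = stats::var(.data$rate),
                     sd_rate = stats::sd(.data$rate),
                     acf_time = acf_time(.data$rate, window),
                     .groups = "drop")
  structure(list(series = series, summary = summary, window = window),
            class = "population_rate")
}

# First lag (ms) at which the normalized autocorrelation falls below 1/e.
acf_time <- function(x, window) {
  if (stats::var(x) == 0 || length(x) < 3) return(NA_real_)
  a <- stats::acf(x, lag.max = min(length(x) - 1, ceiling(500 / window)),
                  plot = FALSE)$acf[, 1, 1]
  below <- which(a < exp(-1))
  if (length(below) == 0) return(NA_real_)
  (below[1] - 1) * window
}

#' Write / read a spike raster as delimited text
#'
#' Two columns (`neuron_id`, `t_ms`) plus a small YAML sidecar
#' (`<path>.meta.yml`) holding `N`, `n_exc`, `duration` and the model id.
#'
#' @param raster A `spike_raster`.
#' @param path File path for the spike table.
#' @return `read_raster()` returns the reconstructed `spike_raster`.
#' @export
write_raster <- function(raster, path) {
  utils::write.table(data.frame(neuron_id = raster$neuron, t_ms = raster$t),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  yaml::write_yaml(list(N = attr(raster, "N"), n_exc = attr(raster, "n_exc"),
                        duration = attr(raster, "duration"),
                        model = attr(raster, "model")),
                   paste0(path, ".meta.yml"))
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  meta <- yaml::read_yaml(paste0(path, ".meta.yml"))
  raster <- tibble(neuron = x$neuron_id, t = x$t_ms,
                   population = factor(ifelse(x$neuron_id <= meta$n_exc,
                                              "exc", "inh"),
                                       levels = c("exc", "inh")))
  structure(raster, class = c("spike_raster", class(raster)),
            N = meta$N, n_exc = meta$n_exc, n_inh = meta$N - meta$n_exc,
            duration = meta$duration, model = meta$model)
}
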