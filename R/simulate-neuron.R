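#' Simulate one neuron under Poissonian synaptic bombardment
#'
#' Drives a single AdEx, Hodgkin-Huxley or Morris-Lecar neuron with two
#' independent aggregate Poisson streams: `K_e` excitatory synapses firing at
#' `nu_e` Hz each and `K_i` inhibitory synapses at `nu_i` Hz, through the
#' exponential-decay conductance synapses of [synapse_params()]. This is the
#' numerical experiment from which transfer functions are measured.
#'
#' Integration is fixed-step explicit Euler: `dt = 0.1` ms for AdEx and ML,
#' `dt = 0.01` ms for HH (fast sodium gating). Given the same `seed`, spike
#' times are bit-identical across runs.
#'
#' @param model `"adex"`, `"hh"` or `"ml"`; ignored if `params` is given.
#' @param params A `neuron_params` object; default is the RS preset of
#'   `model`.
#' @param synapse [synapse_params()]; default is [default_synapse()] for the
#'   model.
#' @param nu_e,nu_i Per-synapse presynaptic rates (Hz), must be >= 0.
#' @param K_e,K_i Number of excitatory / inhibitory input synapses.
#' @param duration Simulated time (ms).
#' @param seed Integer seed; every call with the same seed reproduces the
#'   same spike train.
#' @param dt Integration step (ms); defaults to the model's standard step.
#' @param burn Initial transient (ms) excluded from the output-rate estimate
#'   (spike times are still reported from t = 0).
#' @param record If `TRUE`, keep a voltage trace sampled every `record_dt`.
#' @param record_g Also record the synaptic conductance traces.
#' @param record_dt Trace sampling interval (ms).
#' @return An object of class `neuron_sim`: a list with `spikes` (ms),
#'   `rate` (Hz, spike count / measurement window), `duration`, `model`, and
#'   (if recorded) `trace`, a tibble with columns `t`, `v` and optionally
#'   `g_e`, `g_i`.
#' @export
#' @examples
#' sim <- simulate_neuron("adex", nu_e = 4, nu_i = 8, duration = 1000, seed = 1)
#' sim$rate
simulate_neuron <- function(model = c("adex", "hh", "ml"), params = NULL,
                            synapse = NULL, nu_e = 0, nu_i = 0,
                            K_e = 400, K_i = 100,
                            duration = 10000, seed = 1, dt = NULL,
                            burn = 0, record = FALSE, record_g = FALSE,
                            record_dt = NULL) {
  if (!is.null(params)) {
    model <- model_of(params)
  } else {
    model <- match.arg(model)
    params <- neuron_params(model, "RS")
  }
  if (nu_e < 0 || nu_i < 0) abort("presynaptic rates must be >= 0")
  stopifnot(duration > 0, burn >= 0, burn < duration)
  synapse <- synapse %||% default_synapse(model)
  dt <- dt %||% default_dt(model)
  record_dt <- record_dt %||% dt
  set.seed(seed)
  res <- sim_neuron_cpp(model_id(model), param_vector(params),
                        synapse_vector(synapse),
                        nu_e, nu_i, as.integer(K_e), as.integer(K_i),
                        duration, dt,
                        record_dt = if (record || record_g) record_dt else 0,
                        record_g = record_g)
  spikes <- res$spikes
  rate <- 1000 * sum(spikes > burn) / (duration - burn)
  out <- list(spikes = spikes, rate = rate, duration = duration,
              model = model, cell = params$cell, nu_e = nu_e, nu_i = nu_i,
              K_e = K_e, K_i = K_i, dt = dt, seed = seed)
  if (record || record_g) {
    tr <- tibble(t = res$trace_t, v = res$trace_v)
    if (record_g) {
      tr$g_e <- res$trace_ge
      tr$g_i <- res$trace_gi
    }
    out$trace <- tr
  }
  structure(out, class = "neuron_sim")
}

#' @export
print.neuron_sim <- function(x, ...) {
  cat("<neuron_sim: ", x$model, " ", x$cell %||% "", ", ",
      x$duration, " ms, nu_e = ", x$nu_e, " Hz, nu_i = ", x$nu_i,
      " Hz>\n  output rate ", signif(x$rate, 4), " Hz (",
      length(x$spikes), " spikes)\n", sep = "")
  invisible(x)
}

#' Write / read a voltage trace as two-column delimited text
#'
#' @param sim A `neuron_sim` with a recorded trace, or a data frame with
#'   columns `t` and `v`.
#' @param path File path.
#' @return `read_trace()` returns a tibble with columns `t` (ms), `v` (mV).
#' @export
write_trace <- function(sim, path) {
  tr <- if (is.data.frame(sim)) sim else sim$trace
  if (is.null(tr)) abort("no recorded trace (call simulate_neuron(record = TRUE))")
  utils::write.table(data.frame(t_ms = tr$t, v_mV = tr$v), path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  tibble(t = x$t_ms, v = x$v_mV)
}
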