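#' Synaptic parameters
#'
#' Conductance-based synapses: every presynaptic spike increments the target's
#' excitatory or inhibitory conductance by a quantal amount, which then decays
#' exponentially with time constant `tau`. Defaults follow the cortical RS/FS
#' network setting used throughout the package; the Morris-Lecar network uses
#' larger quanta (`Q_e = 4`, `Q_i = 10` nS), see [default_synapse()].
#'
#' @param Q_e Excitatory quantal conductance (nS).
#' @param Q_i Inhibitory quantal conductance (nS).
#' @param tau Synaptic decay time constant (ms), shared by both synapse types.
#' @param E_e,E_i Excitatory / inhibitory reversal potentials (mV). Standard
#'   cortical values are used by default; they are configurable because they
#'   are not uniquely pinned down by the network model itself.
#'
#' @return An object of class `synapse_params` (a named list).
#' @export
#' @examples
#' synapse_params()
synapse_params <- function(Q_e = 1.5, Q_i = 5, tau = 5, E_e = 0, E_i = -80) {
  stopifnot(Q_e > 0, Q_i > 0, tau > 0, E_i < E_e)
  structure(list(Q_e = Q_e, Q_i = Q_i, tau = tau, E_e = E_e, E_i = E_i),
            class = "synapse_params")
}

#' Default synapse for a neuron model
#'
#' AdEx and Hodgkin-Huxley networks use `Q_e = 1.5`, `Q_i = 5` nS; the
#' Morris-Lecar network uses `Q_e = 4`, `Q_i = 10` nS.
#'
#' @param model `"adex"`, `"hh"` or `"ml"`.
#' @return A [synapse_params()] object.
#' @export
default_synapse <- function(model = c("adex", "hh", "ml")) {
  model <- match.arg(model)
  if (model == "ml") synapse_params(Q_e = 4, Q_i = 10) else synapse_params()
}

#' Adaptive Exponential Integrate-and-Fire parameters
#'
#' Two-variable (v, w) model with an exponential spike-initiation term and
#' spike-frequency adaptation. Once `v` passes the unstable region above the
#' nominal threshold `v_t` the exponential term makes it diverge; the spike
#' is registered at the numerical cutoff `v_cut` (default `v_t + 5 Delta`),
#' where `v` is reset to `v_rest` and clamped there for `T_refr`, and the
#' adaptation current `w` is incremented by `b`. The cutoff matters under
#' strong synaptic shunting: resetting already at `v_t` would bypass the
#' soft spike-initiation nonlinearity and overestimate excitability (set
#' `v_cut = v_t` to recover that literal rule). Excitatory regular-spiking
#' (RS) cells carry adaptation (`a = 4` nS, `b = 60` pA) and a shallow spike
#' initiation (`Delta = 2` mV); inhibitory fast-spiking (FS) cells have no
#' adaptation and a sharper initiation (`Delta = 0.5` mV), which gives them
#' the higher gain.
#'
#' @param cell `"RS"` (excitatory) or `"FS"` (inhibitory) preset.
#' @param ... Named overrides of any preset field (`c_m`, `g_L`, `E_L`,
#'   `Delta`, `v_t`, `v_rest`, `T_refr`, `a`, `b`, `tau_w`, `v_cut`).
#' @return An object of class `c("adex_params", "neuron_params")`.
#' @export
#' @examples
#' adex_params("FS")
#' adex_params("RS", E_L = -63)
adex_params <- function(cell = c("RS", "FS"), ...) {
  cell <- match.arg(cell)
  p <- list(c_m = 150, g_L = 10, E_L = -65,
            Delta = if (cell == "RS") 2 else 0.5,
            v_t = -50, v_rest = -65, T_refr = 5,
            a = if (cell == "RS") 4 else 0,
            b = if (cell == "RS") 60 else 0,
            tau_w = 500, v_cut = NULL)
  p <- override_fields(p, ..., what = "adex_params")
  p$v_cut <- p$v_cut %||% (p$v_t + 5 * p$Delta)
  stopifnot(p$c_m > 0, p$g_L > 0, p$tau_w > 0, p$T_refr > 0, p$Delta > 0,
            p$v_rest <= p$v_t, p$v_cut >= p$v_t)
  structure(c(p, list(cell = cell)), class = c("adex_params", "neuron_params"))
}

#' Hodgkin-Huxley parameters
#'
#' Five-variable (v, n, m, h, p) single-compartment model with transient
#' sodium, delayed-rectifier potassium and (for RS cells) a slow
#' non-inactivating potassium current `I_M` responsible for spike-frequency
#' adaptation; FS cells have `g_M = 0`. A spike is registered whenever the
#' membrane potential crosses `spike_threshold` (10 mV) from below.
#'
#' Conductances are absolute (nS) in an AdEx-compatible unit system. The leak
#' (10 nS) and capacitance (200 pF) are taken at face value, giving a resting
#' membrane time constant of 20 ms; the fast channel densities are scaled by
#' the documented factor `active_scale` (default 1000, i.e. the nominal
#' per-area densities read as microsiemens), chosen so that action potentials
#' overshoot well past the detection threshold and depolarization block only
#' appears at very high input rates. The slow I_M density carries its own
#' calibration factor (`g_M` default 45 nS, 1.5x the fast-channel scale),
#' set so that the recurrent network possesses a stable asynchronous
#' irregular state with regular-spiking cells at a few Hz. See the methods
#' vignette.
#'
#' @param cell `"RS"` or `"FS"` preset (they differ only in `g_M`).
#' @param active_scale Multiplier applied to the nominal active densities
#'   (g_Na = 20, g_K = 6, calibrated g_M = 0.045) to obtain absolute nS
#'   values.
#' @param ... Named overrides (`c_m`, `g_L`, `g_Na`, `g_K`, `g_M`, `E_L`,
#'   `E_Na`, `E_K`, `V_T`, `tau_max`, `spike_threshold`).
#' @return An object of class `c("hh_params", "neuron_params")`.
#' @export
hh_params <- function(cell = c("RS", "FS"), active_scale = 1000, ...) {
  cell <- match.arg(cell)
  p <- list(c_m = 200, g_L = 10,
            g_Na = 20 * active_scale, g_K = 6 * active_scale,
            g_M = if (cell == "RS") 0.045 * active_scale else 0,
            E_L = -65, E_Na = 50, E_K = -90, V_T = -53.5,
            tau_max = 400, spike_threshold = 10)
  p <- override_fields(p, ..., what = "hh_params")
  stopifnot(p$c_m > 0, p$g_L > 0, p$g_Na >= 0, p$g_K >= 0, p$g_M >= 0,
            p$E_K < p$E_L, p$E_L < p$E_Na, p$tau_max > 0)
  structure(c(p, list(cell = cell)), class = c("hh_params", "neuron_params"))
}

#' Morris-Lecar parameters
#'
#' Two-variable (v, N) model with an instantaneous calcium activation `M_ss`
#' and a slower potassium gating variable `N`. The activation-curve parameters
#' (`V1`..`V4`) place the model in the type II excitability class: the
#' response to a DC ramp is discontinuous in rate, and strong depolarization
#' silences the cell (depolarization block), producing a bell-shaped transfer
#' function. Excitatory RS cells have `E_L = -50` mV, inhibitory FS cells
#' `E_L = -70` mV.
#'
#' Units are absolute (pF, nS, pA) in the same spirit as [hh_params()], with
#' the intrinsic membrane calibrated as a whole against the fixed synaptic
#' quanta (Q_e = 4, Q_i = 10 nS): the nominal conductance densities map to
#' nS with a factor 0.625 (g_L = 12.5, g_Ca = 50, g_K = 100 nS), the
#' capacitance to 125 pF (so the resting membrane time constant is 10 ms),
#' and the reference DC current `I0` to 875 pA, placing the quiescent cell
#' at rheobase (tonic firing at ~2 Hz without synaptic input). The gating rate `phi` is not pinned down by the
#' nominal parameter set; its default (0.003 / ms) completes the
#' calibration, chosen so the RS transfer function under an 8 Hz inhibitory
#' background peaks near an 8 Hz excitatory input and collapses above
#' (depolarization block). See the methods vignette.
#'
#' @param cell `"RS"` or `"FS"` preset (they differ only in `E_L`).
#' @param ... Named overrides (`c_m`, `g_L`, `g_Ca`, `g_K`, `E_L`, `E_Ca`,
#'   `E_K`, `V1`, `V2`, `V3`, `V4`, `phi`, `I0`, `spike_threshold`).
#' @return An object of class `c("ml_params", "neuron_params")`.
#' @export
ml_params <- function(cell = c("RS", "FS"), ...) {
  cell <- match.arg(cell)
  p <- list(c_m = 125, g_L = 12.5, g_Ca = 50, g_K = 100,
            E_L = if (cell == "RS") -50 else -70,
            E_Ca = 120, E_K = -84,
            V1 = -1.2, V2 = 18, V3 = 2, V4 = 30,
            phi = 0.003, I0 = 875, spike_threshold = 10)
  p <- override_fields(p, ..., what = "ml_params")
  stopifnot(p$c_m > 0, p$g_L > 0, p$g_Ca >= 0, p$g_K >= 0,
            p$E_K < p$E_L, p$E_L < p$E_Ca, p$V2 > 0, p$V4 > 0, p$phi > 0)
  structure(c(p, list(cell = cell)), class = c("ml_params", "neuron_params"))
}

#' Parameter preset for a model/cell combination
#'
#' @param model `"adex"`, `"hh"` or `"ml"`.
#' @param cell `"RS"` or `"FS"`.
#' @param ... Passed to the model-specific constructor.
#' @return A `neuron_params` object.
#' @export
neuron_params <- function(model = c("adex", "hh", "ml"),
                          cell = c("RS", "FS"), ...) {
  model <- match.arg(model)
  switch(model,
         adex = adex_params(cell, ...),
         hh = hh_params(cell, ...),
         ml = ml_params(cell, ...))
}

override_fields <- function(p, ..., what) {
  dots <- list(...)
  if (length(dots) == 0) return(p)
  bad <- setdiff(names(dots), names(p))
  if (length(bad) > 0 || is.null(names(dots)) || any(names(dots) == "")) {
    abort(paste0("unknown ", what, " field(s): ",
                 paste(bad, collapse = ", ")))
  }
  modifyList(p, dots)
}

model_of <- function(params) {
  if (inherits(params, "adex_params")) return("adex")
  if (inherits(params, "hh_params")) return("hh")
  if (inherits(params, "ml_params")) return("ml")
  abort("not a neuron_params object")
}

model_id <- function(model) match(model, c("adex", "hh", "ml"))

default_dt <- function(model) if (model == "hh") 0.01 else 0.1

# Flat numeric vectors in the layout the C++ kernels expect.
param_vector <- function(params) {
  switch(model_of(params),
         adex = unlist(params[c("c_m", "g_L", "E_L", "Delta", "v_t", "v_rest",
                                "T_refr", "a", "b", "tau_w", "v_cut")]),
         hh = unlist(params[c("c_m", "g_L", "g_Na", "g_K", "g_M", "E_L",
                              "E_Na", "E_K", "V_T", "tau_max",
                              "spike_threshold")]),
         ml = unlist(params[c("c_m", "g_L", "g_Ca", "g_K", "E_L", "E_Ca",
                              "E_K", "V1", "V2", "V3", "V4", "phi", "I0",
                              "spike_threshold")]))
}

synapse_vector <- function(syn) {
  stopifnot(inherits(syn, "synapse_params"))
  unlist(syn[c("Q_e", "Q_i", "tau", "E_e", "E_i")])
}

#' Write / read parameter sets as YAML
#'
#' Plain hierarchical config files; keys are the constructor field names, plus
#' a `model` (and optional `cell`) key identifying the constructor.
#'
#' @param params A `neuron_params` or `synapse_params` object.
#' @param path File path.
#' @return `read_params()` returns the reconstructed object.
#' @export
write_params <- function(params, path) {
  x <- unclass(params)
  if (inherits(params, "synapse_params")) {
    x <- c(list(model = "synapse"), x)
  } else {
    x <- c(list(model = model_of(params)), x)
  }
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  x <- yaml::read_yaml(path)
  model <- x$model
  x$model <- NULL
  if (identical(model, "synapse")) {
    return(do.call(synapse_params, x))
  }
  cell <- x$cell %||% "RS"
  x$cell <- NULL
  do.call(neuron_params, c(list(model = model, cell = cell), x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.neuron_params <- function(x, ...) {
  cat("<", model_of(x), " neuron parameters, ", x$cell, " cell>\n", sep = "")
  flds <- x[setdiff(names(x), "cell")]
  cat(paste0("  ", names(flds), " = ", unlist(flds), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
print.synapse_params <- function(x, ...) {
  cat("<synapse parameters>\n")
  cat(paste0("  ", names(x), " = ", unlist(x), collapse = "\n"), "\n")
  invisible(x)
}
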