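# Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) {
    assign(key, force(expr), envir = .cache)
  }
  get(key, envir = .cache)
}

# The spontaneous AdEx network in its asynchronous irregular state
# (desk scale, in-degrees preserved), reused by several tests.
ai_raster <- function() {
  cached("ai_raster", {
    simulate_network("adex", scaled_network_config(N = 2500, seed = 1),
                     duration = 10000)
  })
}

# AdEx transfer-function fits on the reference grid (8 inhibitory
# backgrounds, 12 excitatory points each, 10 s x 4 seeds).
adex_fit <- function(cell) {
  p <- adex_params(cell)
  grid <- tf_grid(p, nu_i = c(0.5, 2, 4, 6, 8, 12, 16, 20), n_nu_e = 12)
  m <- measure_transfer_function(p, grid, duration = 10000, seeds = 1:4)
  fit_transfer_function(m)
}

fs_fit <- function() cached("fs_fit", adex_fit("FS"))

rs_fit <- function() cached("rs_fit", adex_fit("RS"))

# A smooth synthetic Wilson-Cowan-style transfer-function pair with a known
# unique fixed point, used as an oracle target for the mean field.
synthetic_pair <- function() {
  list(
    e = function(nu_e, nu_i) 30 / (1 + exp(-(nu_e - 0.8 * nu_i - 2) / 2)),
    i = function(nu_e, nu_i) 60 / (1 + exp(-(1.5 * nu_e - 0.5 * nu_i - 3) / 3))
  )
}
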