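test_that("AdEx step reproduces the hand-evaluated resting drift", {
  p <- adex_params("RS")
  out <- adex_step(list(v = p$E_L, w = 0), p, g_e = 0, g_i = 0, dt = 1e-3)
  # at v = E_L with no synapses the only current is the spike-initiation
  # exponential: dv/dt = g_L * Delta * exp((E_L - v_t)/Delta) / c_m
  drift <- 10 * 2 * exp((-65 + 50) / 2) / 150
  expect_equal((out$state$v - p$E_L) / 1e-3, drift, tolerance = 1e-6)
  expect_equal(drift, 7.37e-5, tolerance = 0.01)
  expect_false(out$spiked)
})

test_that("AdEx step resets and increments adaptation at the spike cutoff", {
  p <- adex_params("RS")
  out <- adex_step(list(v = p$v_cut + 0.5, w = 10), p, g_e = 50, g_i = 0,
                   dt = 0.1)
  expect_true(out$spiked)
  expect_equal(out$state$v, p$v_rest)
  expect_equal(out$state$v, -65)
  expect_gt(out$state$w, 10 + p$b - 1)  # increment b = 60 pA (plus drift)
  expect_error(adex_step(list(v = NaN, w = 0), p, 0, 0, 0.1), "v")
})

test_that("leak-only dynamics relax to E_L at rate g_L/c_m in all models", {
  dt <- 0.01
  steps <- 2000
  # AdEx without adaptation or spiking nonlinearity near rest
  p <- adex_params("RS", a = 0, b = 0, Delta = 1e-6, v_t = 100, v_cut = 100)
  v <- -55
  w <- 0
  for (k in seq_len(steps)) {
    st <- adex_step(list(v = v, w = w), p, 0, 0, dt)
    v <- st$state$v
    w <- st$state$w
  }
  expect_equal(v, p$E_L + (-55 - p$E_L) * exp(-p$g_L / p$c_m * steps * dt),
               tolerance = 1e-3)
  expect_equal(w, 0)

  # HH with all active conductances off
  ph <- hh_params("RS", g_Na = 0, g_K = 0, g_M = 0)
  st <- list(v = -55, n = 0.1, m = 0.1, h = 0.5, p = 0.1)
  for (k in seq_len(steps)) {
    d <- hh_derivatives(st, ph)
    st <- Map(function(x, dx) x + dt * dx, st, d)
  }
  expect_equal(st$v, ph$E_L + (-55 - ph$E_L) * exp(-ph$g_L / ph$c_m * steps * dt),
               tolerance = 1e-2)

  # ML with calcium/potassium off and no DC current
  pm <- ml_params("RS", g_Ca = 0, g_K = 0, I0 = 0)
  v <- -40
  N <- 0.2
  for (k in seq_len(steps)) {
    d <- ml_derivatives(list(v = v, N = N), pm)
    v <- v + dt * d$v
    N <- N + dt * d$N
  }
  expect_equal(v, pm$E_L + (-40 - pm$E_L) * exp(-pm$g_L / pm$c_m * steps * dt),
               tolerance = 1e-2)
})

test_that("HH gating rates take their analytic limits at the singular points", {
  p <- hh_params()
  r <- hh_gating_rates(p$V_T + c(15, 13, 40), p)
  expect_equal(r$alpha_n[1], 0.032 * 5, tolerance = 1e-9)
  expect_equal(r$alpha_m[2], 0.32 * 4, tolerance = 1e-9)
  expect_equal(r$beta_m[3], 0.28 * 5, tolerance = 1e-9)
  # continuity across the singularities: the value at the singular point
  # equals the average of close neighbours (no jump; smoothness error O(eps^2))
  for (off in c(15, 13, 40)) {
    v0 <- p$V_T + off
    near <- hh_gating_rates(c(v0 - 1e-4, v0, v0 + 1e-4), p)
    for (col in c("alpha_n", "alpha_m", "beta_m")) {
      x <- near[[col]]
      expect_lt(abs(x[2] - (x[1] + x[3]) / 2), 1e-6)
    }
  }
  # midpoint of the slow gate sigmoid
  r35 <- hh_gating_rates(-35, p)
  expect_equal(r35$p_inf, 0.5)
  expect_equal(r35$tau_p, p$tau_max / 4.3)
  # rates are non-negative on a wide voltage range
  wide <- hh_gating_rates(seq(-120, 60, by = 0.5), p)
  expect_true(all(as.matrix(wide[, -1]) >= 0))
})

test_that("HH derivatives vanish at the resting fixed point", {
  p <- hh_params("RS")
  # locate the fixed point by relaxing v with gates at steady state
  v <- p$E_L
  for (k in 1:20000) {
    g <- neuromf:::hh_steady_gates(v, p)
    d <- hh_derivatives(c(list(v = v), g), p)
    v <- v + 0.05 * d$v
  }
  g <- neuromf:::hh_steady_gates(v, p)
  d <- hh_derivatives(c(list(v = v), g), p)
  expect_lt(max(abs(unlist(d))), 1e-6)
  # passive limit
  dpass <- hh_derivatives(list(v = -50, n = 0, m = 0, h = 1, p = 0),
                          hh_params(g_Na = 0, g_K = 0, g_M = 0))
  expect_equal(dpass$v, 10 * (-65 + 50) / 200)
})

test_that("ML activation curves hit their midpoints and saturate", {
  p <- ml_params()
  a <- ml_activation(c(p$V1, p$V3, 1e4, -1e4), p)
  expect_equal(a$M_ss[1], 0.5)
  expect_equal(a$N_ss[2], 0.5)
  expect_equal(a$tau_N[2], 1 / (2 * p$phi))
  expect_equal(a$M_ss[3], 1, tolerance = 1e-12)
  expect_equal(a$N_ss[3], 1, tolerance = 1e-12)
  expect_equal(a$M_ss[4], 0, tolerance = 1e-12)
  # dN/dt = 0 when N is at its steady state
  d <- ml_derivatives(list(v = -20, N = ml_activation(-20, p)$N_ss), p)
  expect_equal(d$N, 0)
})

test_that("spike detection counts debounced upward crossings", {
  expect_length(detect_spikes(seq(-70, 20, length.out = 91), 10, dt = 0.1), 1)
  expect_length(detect_spikes(rep(-60, 100), 10), 0)
  expect_length(detect_spikes(numeric(0)), 0)
  # sine crossing threshold k times upward
  k <- 7
  t <- seq(0, k - 1e-3, by = 1e-3)
  v <- 20 * sin(2 * pi * t)  # threshold 10 crossed upward once per period
  expect_length(detect_spikes(v, threshold = 10, dt = 1e-3), k)
  # a trace that starts above threshold does not register an initial spike
  expect_length(detect_spikes(c(15, 14, 5, 12), threshold = 10), 1)
})

test_that("single-neuron simulation is silent without input and seeded", {
  for (model in c("adex", "hh", "ml")) {
    s <- simulate_neuron(model, nu_e = 0, nu_i = 0, duration = 500,
                         seed = 1)
    if (model == "ml") {
      # ML RS sits at rheobase under its standing DC current and may fire
      # slowly even without synaptic input
      expect_lt(s$rate, 5)
    } else {
      expect_equal(s$rate, 0)
    }
  }
  a <- simulate_neuron("adex", nu_e = 6, nu_i = 8, duration = 2000, seed = 42)
  b <- simulate_neuron("adex", nu_e = 6, nu_i = 8, duration = 2000, seed = 42)
  expect_identical(a$spikes, b$spikes)
  expect_error(simulate_neuron("adex", nu_e = -1), ">= 0")
})

test_that("AdEx refractory period separates spikes by at least T_refr", {
  s <- simulate_neuron(params = adex_params("FS"), nu_e = 20, nu_i = 2,
                       duration = 3000, seed = 1)
  expect_gt(length(s$spikes), 50)
  expect_gte(min(diff(s$spikes)), adex_params("FS")$T_refr - 1e-9)
})

test_that("HH gating variables stay within [0,1] during strong drive", {
  p <- hh_params("RS")
  st <- c(list(v = p$E_L), neuromf:::hh_steady_gates(p$E_L, p))
  dt <- 0.01
  eps <- 1e-6
  ok <- TRUE
  for (k in 1:20000) {  # 200 ms of strong steady excitatory conductance
    d <- hh_derivatives(st, p, g_e = 80, g_i = 5)
    st <- Map(function(x, dx) x + dt * dx, st, d)
    gates <- unlist(st[c("n", "m", "h", "p")])
    if (any(gates < -eps) || any(gates > 1 + eps)) {
      ok <- FALSE
      break
    }
  }
  expect_true(ok)
})

test_that("FS transfer function rises like a sigmoid and saturates below 1/T_refr", {
  rates <- vapply(c(2, 4, 8, 16, 30), function(ne) {
    simulate_neuron(params = adex_params("FS"), nu_e = ne, nu_i = 8,
                    duration = 2000, seed = 1, burn = 300)$rate
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_lt(max(rates), 1000 / adex_params("FS")$T_refr)
  expect_gt(max(rates), 100)
})

test_that("voltage traces export and re-import as two-column text", {
  s <- simulate_neuron("adex", nu_e = 4, nu_i = 8, duration = 200, seed = 1,
                       record = TRUE)
  path <- tempfile(fileext = ".tsv")
  write_trace(s, path)
  tr <- read_trace(path)
  expect_equal(tr$v, s$trace$v)
  expect_equal(tr$t, s$trace$t)
})
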