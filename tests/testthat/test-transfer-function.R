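test_that("conductance moments match the shot-noise formulas and scaling", {
  m <- conductance_moments(4, 0, K_e = 400, K_i = 100, synapse_params())
  expect_equal(m$mu_Ge, 12)
  expect_equal(m$sigma_Ge, 3)

  z <- conductance_moments(0, 0)
  expect_equal(unlist(z[, c("mu_Ge", "sigma_Ge", "mu_Gi", "sigma_Gi")]),
               rep(0, 4), ignore_attr = TRUE)

  base <- conductance_moments(6, 10)
  dblQ <- conductance_moments(6, 10, synapse = synapse_params(Q_e = 3, Q_i = 10))
  expect_equal(dblQ$mu_Ge, 2 * base$mu_Ge)
  expect_equal(dblQ$sigma_Ge, 2 * base$sigma_Ge)
  dblN <- conductance_moments(12, 20)
  expect_equal(dblN$mu_Ge, 2 * base$mu_Ge)
  expect_equal(dblN$sigma_Ge, sqrt(2) * base$sigma_Ge)
  expect_error(conductance_moments(-1, 0), ">= 0")
})

test_that("conductance moments agree with a Monte-Carlo trace within 5%", {
  m <- conductance_moments(4, 8)
  s <- simulate_neuron("adex", nu_e = 4, nu_i = 8, duration = 1e5, seed = 9,
                       record_g = TRUE)
  drop <- s$trace$t > 100  # discard filling transient
  expect_equal(mean(s$trace$g_e[drop]), m$mu_Ge, tolerance = 0.05)
  expect_equal(sd(s$trace$g_e[drop]), m$sigma_Ge, tolerance = 0.05)
  expect_equal(mean(s$trace$g_i[drop]), m$mu_Gi, tolerance = 0.05)
  expect_equal(sd(s$trace$g_i[drop]), m$sigma_Gi, tolerance = 0.05)
})

test_that("voltage moments reduce to the leak in quiescence and match hand values", {
  cell <- adex_params("RS")
  q <- voltage_moments(0, 0, cell)
  expect_equal(q$mu_V, cell$E_L)
  expect_equal(q$sigma_V, 0)
  expect_equal(q$tau_m_eff, 15)  # c_m / g_L = 150 / 10

  v <- voltage_moments(4, 8, cell)
  expect_equal(v$mu_G, 42)             # 12 + 20 + 10 nS
  expect_equal(v$tau_m_eff, 150 / 42)
  expect_equal(v$mu_V, (20 * -80 + 10 * -65) / 42, tolerance = 1e-12)
  expect_equal(v$mu_V, -53.57, tolerance = 1e-3)
  expect_equal(v$tau_V_N, v$tau_V * cell$g_L / cell$c_m)
  # moments respect the physical bounds
  g <- voltage_moments(runif(50, 0, 30), runif(50, 0, 30), cell)
  expect_true(all(g$mu_G >= cell$g_L))
  expect_true(all(g$mu_V <= 0 & g$mu_V >= -80))
  expect_true(all(g$sigma_V >= 0))
  expect_true(all(g$tau_m_eff <= cell$c_m / cell$g_L))
})

test_that("predicted sigma_V matches the fluctuations of a passive membrane", {
  # leak-only cell (no spiking, no adaptation) under the same bombardment
  cell <- adex_params("RS", a = 0, b = 0, Delta = 1e-6, v_t = 100, v_cut = 100)
  s <- simulate_neuron(params = cell, nu_e = 4, nu_i = 8, duration = 5e4,
                       seed = 21, record = TRUE)
  v <- s$trace$v[s$trace$t > 200]
  pred <- voltage_moments(4, 8, cell)
  expect_equal(sd(v), pred$sigma_V, tolerance = 0.15)
  expect_equal(mean(v), pred$mu_V, tolerance = 0.02)
})

test_that("the effective threshold evaluates the full ten-term polynomial", {
  norm <- threshold_norm()
  p0only <- threshold_polynomial(c(P0 = -48), norm)
  mom <- voltage_moments(c(2, 6), c(4, 12), adex_params("RS"))
  expect_equal(effective_threshold(mom, p0only), c(-48, -48))

  # at the normalization centers every term but P0 vanishes
  centered <- tibble::tibble(mu_V = norm$mu_V0, sigma_V = norm$sigma_V0,
                             tau_V_N = norm$tau_VN0)
  full <- threshold_polynomial(
    setNames(c(-50, 1:9), neuromf:::threshold_terms), norm)
  expect_equal(effective_threshold(centered, full), -50)

  # independent term-by-term evaluation as oracle
  set.seed(1)
  coefs <- setNames(rnorm(10), neuromf:::threshold_terms)
  poly <- threshold_polynomial(coefs, norm)
  mom2 <- voltage_moments(c(1, 5, 9), c(2, 8, 20), adex_params("RS"))
  naive <- vapply(seq_len(nrow(mom2)), function(i) {
    x <- (mom2$mu_V[i] - norm$mu_V0) / norm$dmu_V0
    y <- (mom2$sigma_V[i] - norm$sigma_V0) / norm$dsigma_V0
    z <- (mom2$tau_V_N[i] - norm$tau_VN0) / norm$dtau_VN0
    coefs["P0"] + coefs["P_muV"] * x + coefs["P_sigmaV"] * y +
      coefs["P_tauV"] * z + coefs["P_muV2"] * x^2 + coefs["P_sigmaV2"] * y^2 +
      coefs["P_tauV2"] * z^2 + coefs["P_muVsigmaV"] * x * y +
      coefs["P_muVtauV"] * x * z + coefs["P_sigmaVtauV"] * y * z
  }, numeric(1))
  expect_equal(effective_threshold(mom2, poly), naive, tolerance = 1e-12)
  expect_error(threshold_polynomial(c(P_muV = 1)), "P0")
  expect_error(threshold_polynomial(c(P0 = Inf)), "finite")
})

test_that("the erfc rate formula has the right midpoint, tail and monotonicity", {
  cell <- adex_params("RS")
  mom <- voltage_moments(4, 8, cell)
  # polynomial pinned so V_thr_eff equals mu_V at this point
  poly <- threshold_polynomial(
    c(P0 = mom$mu_V),
    threshold_norm(mu_V0 = mom$mu_V, sigma_V0 = mom$sigma_V,
                   tau_VN0 = mom$tau_V_N))
  tf <- transfer_function(poly, cell)
  expect_equal(predicted_rate(4, 8, tf), 1000 / (2 * mom$tau_V))

  # deep subthreshold: rate -> 0
  far <- transfer_function(threshold_polynomial(c(P0 = 60)), cell)
  expect_lt(predicted_rate(4, 8, far), 1e-12)

  # increasing nu_e at fixed threshold raises mu_V and the predicted rate
  tf0 <- transfer_function(threshold_polynomial(c(P0 = -50)), cell)
  r <- predicted_rate(seq(2, 14, by = 2), 8, tf0)
  expect_true(all(diff(r) > 0))
  # zero-fluctuation limit below threshold gives exactly 0
  expect_equal(predicted_rate(0, 0, tf0), 0)
})

test_that("the fast transfer-function closure matches predicted_rate", {
  fit <- fs_fit()
  f <- neuromf:::tf_as_function(fit$tf)
  nu_e <- runif(30, 0, 25)
  nu_i <- runif(30, 0, 25)
  expect_equal(f(nu_e, nu_i), predicted_rate(nu_e, nu_i, fit$tf),
               tolerance = 1e-12)
})

test_that("rate inversion is the exact inverse of the erfc formula", {
  cell <- adex_params("RS")
  mom <- voltage_moments(5, 9, cell)
  tf <- transfer_function(threshold_polynomial(c(P0 = -49)), cell)
  rate <- predicted_rate(5, 9, tf)
  v_thr <- effective_threshold(mom, tf$poly)
  expect_equal(invert_rate(rate, mom), v_thr, tolerance = 1e-9)

  # midpoint identity: nu_out = 1/(2 tau_V) maps to V_thr = mu_V
  expect_equal(invert_rate(1000 / (2 * mom$tau_V), mom), mom$mu_V,
               tolerance = 1e-9)
  # diverges as the rate approaches zero
  expect_gt(invert_rate(1e-10, mom), mom$mu_V + 15)
  expect_error(invert_rate(0, mom), "range")
  expect_error(invert_rate(1e6, mom), "range")
})

test_that("measured transfer functions have the expected qualitative shapes", {
  # pure inhibition: essentially silent
  m0 <- measure_transfer_function(adex_params("RS"),
                                  tibble::tibble(nu_e = 0, nu_i = 8),
                                  duration = 2000, seeds = 1)
  expect_lt(m0$rate, 0.5)
  expect_error(measure_transfer_function(adex_params("RS"),
                                         tibble::tibble(nu_e = numeric(0),
                                                        nu_i = numeric(0))),
               "empty")

  # AdEx FS: monotone nondecreasing in nu_e at fixed nu_i = 8
  mfs <- measure_transfer_function(
    adex_params("FS"), tibble::tibble(nu_e = c(2, 4, 6, 9, 14), nu_i = 8),
    duration = 4000, seeds = 1:2)
  expect_true(all(diff(mfs$rate) >= 0))

  # ML RS: rise then fall (depolarization block)
  mml <- measure_transfer_function(
    ml_params("RS"), tibble::tibble(nu_e = c(2, 8, 18), nu_i = 8),
    duration = 6000, seeds = 1:2)
  expect_gt(mml$rate[2], mml$rate[1])
  expect_gt(mml$rate[2], mml$rate[3])
})

test_that("fitting recovers a known threshold polynomial from noiseless rates", {
  cell <- adex_params("FS")
  true_poly <- threshold_polynomial(
    c(P0 = -51, P_muV = 4, P_sigmaV = -8, P_tauV = 0.3,
      P_muV2 = -0.5, P_sigmaV2 = 1.4, P_tauV2 = -14,
      P_muVsigmaV = 4.5, P_muVtauV = 2.8, P_sigmaVtauV = -15))
  tf_true <- transfer_function(true_poly, cell)
  grid <- expand.grid(nu_e = seq(1, 15, length.out = 8),
                      nu_i = c(1, 4, 8, 14, 20))
  samples <- tibble::tibble(nu_e = grid$nu_e, nu_i = grid$nu_i,
                            rate = predicted_rate(grid$nu_e, grid$nu_i,
                                                  tf_true))
  fit <- fit_transfer_function(samples, cell = cell,
                               synapse = synapse_params(), K_e = 400,
                               K_i = 100)
  expect_lt(fit$rms, 1e-6)
  refit_rates <- predicted_rate(samples$nu_e, samples$nu_i, fit$tf)
  expect_equal(refit_rates, samples$rate, tolerance = 1e-6)
})

test_that("degenerate designs and undersized samples raise fit errors", {
  cell <- adex_params("FS")
  const <- tibble::tibble(nu_e = rep(6, 20), nu_i = rep(8, 20), rate = 12)
  expect_error(fit_transfer_function(const, cell = cell), "degenerate")
  few <- tibble::tibble(nu_e = 1:5, nu_i = 8, rate = 1:5)
  expect_error(fit_transfer_function(few, cell = cell), "10 samples")
})

test_that("the fitted AdEx transfer functions track simulation closely", {
  for (fit in list(rs_fit(), fs_fit())) {
    low <- fit$samples[fit$samples$rate < 30, ]
    expect_lt(sqrt(mean(low$.resid^2)), 1.5)
  }
  # FS fitted curve: increasing in nu_e, decreasing in nu_i in the
  # fluctuation-driven region
  tf <- fs_fit()$tf
  r_e <- predicted_rate(seq(2, 8, by = 1), 8, tf)
  expect_true(all(diff(r_e) > 0))
  r_i <- predicted_rate(5, seq(2, 16, by = 2), tf)
  expect_true(all(diff(r_i) < 0))
})

test_that("the polynomial normalization is a pure reparameterization", {
  fit <- fs_fit()
  poly <- fit$poly
  k <- c(2.5, 0.6, 1.7)  # rescale the three coordinate scales
  n <- poly$norm
  norm2 <- threshold_norm(n$mu_V0, n$dmu_V0 * k[1],
                          n$sigma_V0, n$dsigma_V0 * k[2],
                          n$tau_VN0, n$dtau_VN0 * k[3])
  cf <- poly$coef
  cf2 <- c(cf["P0"],
           cf["P_muV"] * k[1], cf["P_sigmaV"] * k[2], cf["P_tauV"] * k[3],
           cf["P_muV2"] * k[1]^2, cf["P_sigmaV2"] * k[2]^2,
           cf["P_tauV2"] * k[3]^2,
           cf["P_muVsigmaV"] * k[1] * k[2], cf["P_muVtauV"] * k[1] * k[3],
           cf["P_sigmaVtauV"] * k[2] * k[3])
  tf2 <- transfer_function(threshold_polynomial(cf2, norm2), fit$cell)
  nu <- expand.grid(nu_e = c(1, 4, 9), nu_i = c(2, 8, 16))
  expect_equal(predicted_rate(nu$nu_e, nu$nu_i, tf2),
               predicted_rate(nu$nu_e, nu$nu_i, fit$tf), tolerance = 1e-9)
})

test_that("reference coefficient tables load for every model and cell", {
  for (model in c("adex", "hh", "ml")) {
    for (cell in c("RS", "FS")) {
      poly <- reference_thresholds(model, cell)
      expect_s3_class(poly, "threshold_polynomial")
      expect_true(all(is.finite(poly$coef)))
    }
  }
  expect_equal(unname(reference_thresholds("adex", "RS")$coef["P0"]), -49.8)
  expect_equal(unname(reference_thresholds("ml", "FS")$coef["P_sigmaVtauV"]),
               288)
})

test_that("fitted coefficients round-trip through delimited text", {
  fit <- fs_fit()
  path <- tempfile(fileext = ".tsv")
  write_threshold(fit, path)
  poly <- read_threshold(path)
  expect_equal(poly$coef, fit$poly$coef, tolerance = 1e-9)
  expect_equal(unclass(poly$norm), unclass(fit$poly$norm), tolerance = 1e-12)
})

test_that("tidy, glance and augment summarize a fit", {
  fit <- fs_fit()
  td <- tidy(fit)
  expect_equal(nrow(td), 10)
  expect_named(td, c("term", "estimate"))
  gl <- glance(fit)
  expect_equal(gl$cell, "FS")
  expect_true(gl$rms > 0)
  au <- augment(fit)
  expect_true(all(c(".fitted", ".resid") %in% names(au)))
})
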