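test_that("the stimulus envelope is an asymmetric double Gaussian", {
  stim <- stimulus_profile(A = 2, t0 = 2000, T1 = 100, T2 = 150)
  expect_equal(stimulus_rate(2000, stim), 2)
  expect_equal(stimulus_rate(2150, stim), 2 * exp(-1))
  expect_equal(stimulus_rate(1900, stim), 2 * exp(-1))
  expect_lt(stimulus_rate(900, stim), 1e-6)
  expect_lt(stimulus_rate(3500, stim), 1e-6)
  # continuity at the peak
  ts <- seq(1999, 2001, by = 0.01)
  expect_lt(max(abs(diff(stimulus_rate(ts, stim)))), 1e-3)
  expect_error(stimulus_profile(T1 = -1))
})

test_that("finite-difference derivatives are exact on polynomials", {
  lin <- list(e = function(e, i) 3 * e - 2 * i + 1,
              i = function(e, i) 0.5 * e + i)
  d <- tf_derivatives(lin, 5, 7, step = 0.05)
  expect_equal(d$grad, matrix(c(3, 0.5, -2, 1), 2, 2), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lt(max(abs(d$hess)), 1e-7)

  quad <- list(e = function(e, i) e^2, i = function(e, i) e * i)
  dq <- tf_derivatives(quad, 4, 3, step = 0.05)
  expect_equal(dq$hess[1, 1, 1], 2, tolerance = 1e-6)
  expect_equal(dq$hess[2, 1, 2], 1, tolerance = 1e-6)
  expect_equal(dq$hess[2, 1, 2], dq$hess[2, 2, 1])  # symmetric by construction

  # one-sided stencils at the nu = 0 boundary never evaluate negative rates
  probe <- list(e = function(e, i) {
    if (any(e < 0) || any(i < 0)) stop("negative rate")
    e + i
  }, i = function(e, i) e - i)
  expect_silent(tf_derivatives(probe, 0, 0, step = 0.05))
})

test_that("halving the step shrinks smooth first-derivative error ~4x", {
  f <- list(e = function(e, i) sin(e / 3) * exp(-i / 10),
            i = function(e, i) cos(e / 4) + log1p(i))
  exact <- cos(5 / 3) / 3 * exp(-0.7)
  err <- vapply(c(0.4, 0.2), function(h) {
    abs(tf_derivatives(f, 5, 7, step = h)$grad[1, 1] - exact)
  }, numeric(1))
  expect_gt(err[1] / err[2], 3)
  expect_lt(err[1] / err[2], 5)
})

test_that("constant transfer functions give the closed-form covariance", {
  nust <- 10
  fconst <- list(e = function(e, i) rep(nust, length(e)),
                 i = function(e, i) rep(nust, length(e)))
  params <- mean_field_params(T = 20, N_e = 8000, N_i = 2000, order = 2)
  c_ee_expect <- nust * (1000 / 20 - nust) / (2 * 8000)  # = 0.025 Hz^2
  expect_equal(c_ee_expect, 0.025)
  c_ii_expect <- nust * (1000 / 20 - nust) / (2 * 2000)
  stat <- neuromf:::state_vec(nust, nust, c_ee_expect, 0, c_ii_expect)
  d <- mean_field_rhs(stat, fconst, params)
  expect_equal(max(abs(d)), 0, tolerance = 1e-12)

  # first-order fixed point: dnu/dt = 0 at nu = F
  p1 <- mean_field_params(order = 1)
  expect_equal(max(abs(mean_field_rhs(neuromf:::state_vec(nust, nust),
                                      fconst, p1))), 0)

  # integrate to stationarity and compare with the closed form
  s <- find_stationary_state(fconst, params)
  expect_equal(s$nu_e, nust, tolerance = 1e-6)
  expect_equal(s$c_ee, c_ee_expect, tolerance = 1e-6)
  expect_equal(s$c_ii, c_ii_expect, tolerance = 1e-6)
  expect_equal(s$c_ei, 0, tolerance = 1e-8)
})

test_that("large populations with flat F lose their covariance", {
  fconst <- list(e = function(e, i) rep(5, length(e)),
                 i = function(e, i) rep(5, length(e)))
  params <- mean_field_params(T = 20, N_e = 1e12, N_i = 1e12, order = 2)
  d <- mean_field_rhs(neuromf:::state_vec(5, 5, 0.3, 0.1, 0.2), fconst, params)
  # all source terms vanish; covariance decays at rate 2/T
  expect_equal(d[["c_ee"]], -2 * 0.3 / 20, tolerance = 1e-9)
  expect_equal(d[["c_ei"]], -2 * 0.1 / 20, tolerance = 1e-9)
})

test_that("stationary state matches a brute-force self-consistency oracle", {
  pair <- synthetic_pair()
  drive <- 1.5
  # oracle: solve nu = F(nu + drive-convention) on a grid plus bisection,
  # independently of the ODE integrator
  fixed_i <- function(nu_e) {
    lo <- 0
    hi <- 80
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (pair$i(nu_e + drive, mid) > mid) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  gap <- function(nu_e) pair$e(nu_e + drive, fixed_i(nu_e)) - nu_e
  lo <- 0
  hi <- 40
  for (k in 1:60) {
    mid <- (lo + hi) / 2
    if (gap(mid) > 0) lo <- mid else hi <- mid
  }
  oracle <- c(nu_e = (lo + hi) / 2, nu_i = fixed_i((lo + hi) / 2))

  s <- find_stationary_state(pair, mean_field_params(order = 1),
                             external_rate = drive)
  expect_equal(s$nu_e, oracle[["nu_e"]], tolerance = 0.01)
  expect_equal(s$nu_i, oracle[["nu_i"]], tolerance = 0.01)
})

test_that("zero transfer functions give a silent stationary state", {
  f0 <- list(e = function(e, i) rep(0, length(e)),
             i = function(e, i) rep(0, length(e)))
  s <- find_stationary_state(f0, mean_field_params(order = 2))
  expect_lt(max(abs(unlist(s))), 1e-5)
})

test_that("divergent dynamics raise an instability error", {
  frun <- list(e = function(e, i) 3 * e + 10, i = function(e, i) rep(0.1, length(e)))
  expect_error(find_stationary_state(frun, mean_field_params(order = 1)),
               "instability")
})

test_that("AdEx mean field predicts the asynchronous network state", {
  pair <- list(rs_fit(), fs_fit())
  p1 <- mean_field_params(T = 20, N_e = 2000, N_i = 500, order = 1)
  p2 <- mean_field_params(T = 20, N_e = 2000, N_i = 500, order = 2)
  s1 <- find_stationary_state(pair, p1, external_rate = 4)
  s2 <- find_stationary_state(pair, p2, external_rate = 4)

  # inhibitory population leads, as in the network
  expect_gt(s1$nu_i, s1$nu_e)
  # second-order corrections to the rates are small
  expect_lt(abs(s2$nu_e - s1$nu_e) / s1$nu_e, 0.05)
  expect_lt(abs(s2$nu_i - s1$nu_i) / s1$nu_i, 0.05)

  # quantitative agreement with the simulated network
  rates <- mean_population_rates(ai_raster(), t_start = 1000)
  net_e <- rates$mean_rate[rates$population == "exc"]
  net_i <- rates$mean_rate[rates$population == "inh"]
  expect_lt(abs(s1$nu_e - net_e), 2)
  expect_lt(abs(s1$nu_i - net_i), 5)

  # stationary covariance predicts the 20-ms rate variability within 2x
  pr <- population_rate(ai_raster(), window = 20, t_start = 1000)
  sd_net <- pr$summary$sd_rate
  sd_mf <- sqrt(pmax(c(s2$c_ee, s2$c_ii), 0))
  expect_true(all(sd_mf / sd_net > 0.5 & sd_mf / sd_net < 2))
})

test_that("mean-field trajectories stay put without a stimulus and clamp at 0", {
  pair <- synthetic_pair()
  params <- mean_field_params(T = 20, N_e = 2000, N_i = 500, order = 1)
  s <- find_stationary_state(pair, params, external_rate = 1.5)
  traj <- integrate_mean_field(pair, params, stimulus = NULL,
                               external_rate = 1.5, duration = 300,
                               dt = 0.5, init = s)
  expect_lt(max(abs(traj$nu_e - s$nu_e)), 1e-6)
  expect_lt(max(abs(traj$nu_i - s$nu_i)), 1e-6)
  expect_equal(attr(traj, "n_clamped"), 0L)
  expect_error(integrate_mean_field(pair, params, dt = 5), "dt")
})

test_that("covariance symmetry is preserved along trajectories", {
  pair <- list(rs_fit(), fs_fit())
  params <- mean_field_params(T = 20, N_e = 2000, N_i = 500, order = 2)
  stim <- stimulus_profile(A = 2, t0 = 300, T1 = 60, T2 = 90)
  traj <- integrate_mean_field(pair, params, stim, external_rate = 4,
                               duration = 600, dt = 0.5)
  # a single c_ei state carries both off-diagonal entries; the invariant is
  # that the integrated dynamics keep the diagonal entries non-negative and
  # finite while the stimulus passes through
  expect_true(all(is.finite(as.matrix(traj[, 2:6]))))
  expect_true(all(traj$c_ee > -1e-9))
  expect_true(all(traj$c_ii > -1e-9))
  # the AdEx response to the excitatory stimulus is positive
  base <- traj$nu_e[1]
  expect_gt(max(traj$nu_e) - base, 0.1)
})
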