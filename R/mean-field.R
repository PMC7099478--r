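#' Mean-field parameters
#'
#' The master-equation mean field treats population activity as Markovian on
#' a coarse timescale `T` (typically 20 ms) and tracks, at second order, the
#' population-rate covariances alongside the means. Population sizes `N_e`,
#' `N_i` set the finite-size noise floor of the covariance equations.
#'
#' @param T Markovian timescale (ms).
#' @param N_e,N_i Population sizes.
#' @param step Finite-difference step (Hz) for transfer-function derivatives.
#' @param order 1 (Wilson-Cowan-like rate equations) or 2 (rates plus
#'   covariances, with the curvature correction on the rate drift).
#' @return An object of class `mean_field_params`.
#' @export
mean_field_params <- function(T = 20, N_e = 8000, N_i = 2000,
                              step = 0.05, order = 2) {
  stopifnot(T > 0, N_e >= 1, N_i >= 1, step > 0, order %in% c(1, 2))
  structure(list(T = T, N_e = N_e, N_i = N_i, step = step, order = order),
            class = "mean_field_params")
}

#' Asymmetric double-Gaussian stimulus envelope
#'
#' Time-varying extra rate of the external drive: a Gaussian rise with time
#' constant `T1` up to the peak time `t0` (amplitude `A`), then a Gaussian
#' decay with time constant `T2`. Continuous at `t0` with value `A`.
#'
#' @param A Amplitude (Hz), >= 0.
#' @param t0 Peak time (ms).
#' @param T1,T2 Rise and decay time constants (ms), > 0.
#' @return An object of class `stimulus_profile`.
#' @export
#' @examples
#' stimulus_rate(c(1900, 2000, 2150), stimulus_profile(2, 2000, 100, 150))
stimulus_profile <- function(A = 2, t0 = 2000, T1 = 100, T2 = 150) {
  stopifnot(A >= 0, T1 > 0, T2 > 0)
  structure(list(A = A, t0 = t0, T1 = T1, T2 = T2),
            class = "stimulus_profile")
}

#' @rdname stimulus_profile
#' @param t Time(s), ms. Vectorized.
#' @param stim A `stimulus_profile`.
#' @return `stimulus_rate()`: the envelope rate (Hz) at `t`.
#' @export
stimulus_rate <- function(t, stim) {
  stopifnot(inherits(stim, "stimulus_profile"))
  ifelse(t <= stim$t0,
         stim$A * exp(-(t - stim$t0)^2 / stim$T1^2),
         stim$A * exp(-(t - stim$t0)^2 / stim$T2^2))
}

# Normalize user input into a pair of plain functions (nu_e, nu_i) -> Hz.
as_tf_pair <- function(F_e, F_i = NULL) {
  one <- function(f) {
    if (inherits(f, "tf_fit")) return(tf_as_function(f$tf))
    if (inherits(f, "transfer_function")) return(tf_as_function(f))
    stopifnot(is.function(f))
    f
  }
  if (is.null(F_i)) {
    stopifnot(is.list(F_e), length(F_e) == 2)
    list(e = one(F_e[[1]]), i = one(F_e[[2]]))
  } else {
    list(e = one(F_e), i = one(F_i))
  }
}

#' Finite-difference derivatives of a transfer-function pair
#'
#' First and second partial derivatives of `F_e` and `F_i` with respect to
#' `(nu_e, nu_i)`, by central differences of step `step`; at the `nu = 0`
#' boundary the stencil is shifted one-sided so rates are never evaluated at
#' negative values. Mixed partials are built as iterated first-derivative
#' stencils and are therefore symmetric by construction.
#'
#' @param F_pair A list of two functions (or [transfer_function()] /
#'   `tf_fit` objects) `(nu_e, nu_i) -> Hz`, excitatory first.
#' @param nu_e,nu_i Evaluation point (Hz).
#' @param step Difference step (Hz).
#' @return A list with `F` (length-2 value), `grad` (2x2 matrix,
#'   `grad[mu, lambda] = dF_mu / dnu_lambda`) and `hess` (2x2x2 array,
#'   `hess[mu, lambda, eta]`).
#' @export
tf_derivatives <- function(F_pair, nu_e, nu_i, step = 0.05) {
  stopifnot(step > 0)
  F_pair <- as_tf_pair(F_pair)
  stencil <- function(x) {
    if (x >= step) {
      list(o = c(-1, 0, 1), w1 = c(-0.5, 0, 0.5) / step,
           w2 = c(1, -2, 1) / step^2)
    } else {
      list(o = c(0, 1, 2), w1 = c(-1.5, 2, -0.5) / step,
           w2 = c(1, -2, 1) / step^2)
    }
  }
  se <- stencil(nu_e)
  si <- stencil(nu_i)
  pts_e <- nu_e + rep(se$o, times = 3) * step
  pts_i <- nu_i + rep(si$o, each = 3) * step
  vals <- lapply(F_pair, function(f) matrix(f(pts_e, pts_i), 3, 3))
  i0_e <- which(se$o == 0)
  i0_i <- which(si$o == 0)

  Fv <- c(vals$e[i0_e, i0_i], vals$i[i0_e, i0_i])
  grad <- matrix(0, 2, 2, dimnames = list(c("e", "i"), c("e", "i")))
  hess <- array(0, c(2, 2, 2), dimnames = list(c("e", "i"), c("e", "i"),
                                               c("e", "i")))
  for (mu in 1:2) {
    m <- vals[[mu]]
    grad[mu, 1] <- sum(se$w1 * m[, i0_i])
    grad[mu, 2] <- sum(si$w1 * m[i0_e, ])
    hess[mu, 1, 1] <- sum(se$w2 * m[, i0_i])
    hess[mu, 2, 2] <- sum(si$w2 * m[i0_e, ])
    mixed <- sum(outer(se$w1, si$w1) * m)
    hess[mu, 1, 2] <- mixed
    hess[mu, 2, 1] <- mixed
  }
  list(F = Fv, grad = grad, hess = hess)
}

state_vec <- function(nu_e, nu_i, c_ee = 0, c_ei = 0, c_ii = 0) {
  c(nu_e = nu_e, nu_i = nu_i, c_ee = c_ee, c_ei = c_ei, c_ii = c_ii)
}

#' Master-equation right-hand side
#'
#' Time derivative of the mean-field state `(nu_e, nu_i, c_ee, c_ei, c_ii)`.
#' At first order the covariance terms are dropped and the rate equations
#' reduce to the Wilson-Cowan form `T dnu/dt = F - nu`. At second order the
#' rate drift carries the curvature correction
#' `1/2 * sum_{lambda,eta} c_{lambda eta} d2F / dnu_lambda dnu_eta`, and the
#' covariances follow their own relaxation equation with a finite-size source
#' `delta_{lambda eta} F_lambda (1/T - F_eta) / N_lambda` on the diagonal.
#'
#' The external drive rate (spontaneous drive plus stimulus) is added to the
#' excitatory-rate argument of both transfer functions, matching the
#' network's external-synapse convention (`K_e_ext = K_e` synapses at the
#' drive rate).
#'
#' @param state Named vector `(nu_e, nu_i, c_ee, c_ei, c_ii)` (Hz, Hz^2).
#' @param F_pair Transfer functions, as in [tf_derivatives()].
#' @param params [mean_field_params()].
#' @param external_rate External drive rate (Hz), >= 0.
#' @return Named vector of time derivatives (Hz/ms, Hz^2/ms).
#' @export
mean_field_rhs <- function(state, F_pair, params, external_rate = 0) {
  stopifnot(inherits(params, "mean_field_params"), external_rate >= 0)
  F_pair <- as_tf_pair(F_pair)
  nu <- pmax(state[1:2], 0)
  Tms <- params$T
  if (params$order == 1) {
    Fv <- c(F_pair$e(nu[1] + external_rate, nu[2]),
            F_pair$i(nu[1] + external_rate, nu[2]))
    return(state_vec((Fv[1] - nu[1]) / Tms, (Fv[2] - nu[2]) / Tms, 0, 0, 0))
  }
  d <- tf_derivatives(F_pair, nu[1] + external_rate, nu[2], params$step)
  Fv <- d$F
  cmat <- matrix(c(state["c_ee"], state["c_ei"],
                   state["c_ei"], state["c_ii"]), 2, 2)
  N <- c(params$N_e, params$N_i)
  inv_T_hz <- 1000 / Tms  # 1/T on the rate (Hz) scale

  dnu <- numeric(2)
  for (mu in 1:2) {
    corr <- 0.5 * sum(cmat * d$hess[mu, , ])
    dnu[mu] <- (Fv[mu] - nu[mu] + corr) / Tms
  }
  dc <- matrix(0, 2, 2)
  for (lam in 1:2) {
    for (eta in 1:2) {
      src <- if (lam == eta) Fv[lam] * (inv_T_hz - Fv[eta]) / N[lam] else 0
      drift <- (Fv[lam] - nu[lam]) * (Fv[eta] - nu[eta])
      coupling <- sum(d$grad[lam, ] * cmat[eta, ]) +
        sum(d$grad[eta, ] * cmat[lam, ])
      dc[lam, eta] <- (src + drift + coupling - 2 * cmat[lam, eta]) / Tms
    }
  }
  state_vec(dnu[1], dnu[2], dc[1, 1], dc[1, 2], dc[2, 2])
}

rk4_step <- function(state, dt, rhs) {
  k1 <- rhs(state)
  k2 <- rhs(state + dt / 2 * k1)
  k3 <- rhs(state + dt / 2 * k2)
  k4 <- rhs(state + dt * k3)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' Stationary mean-field state
#'
#' Integrates the master equations from `nu = (1, 1)` Hz, `c = 0` until the
#' right-hand side norm falls below `tol` (Hz/ms) or `max_t` of model time
#' has elapsed, and returns the settled state.
#'
#' @param F_pair Transfer functions, as in [tf_derivatives()].
#' @param params [mean_field_params()].
#' @param external_rate External drive rate (Hz).
#' @param dt Integration step (ms), 4th-order Runge-Kutta.
#' @param tol Convergence tolerance on `max(abs(d state / dt))` (Hz/ms).
#' @param max_t Integration horizon (ms).
#' @return A one-row tibble `(nu_e, nu_i, c_ee, c_ei, c_ii)` with attribute
#'   `converged`.
#' @export
find_stationary_state <- function(F_pair, params = mean_field_params(),
                                  external_rate = 0, dt = 0.1,
                                  tol = 1e-8, max_t = 10000) {
  F_pair <- as_tf_pair(F_pair)
  rhs <- function(s) mean_field_rhs(s, F_pair, params, external_rate)
  state <- state_vec(1, 1)
  if (params$order == 2) {
    # settle the rates on the first-order flow before switching on the
    # covariance dynamics: far from the fixed point the covariance transient
    # can grow faster than the rates converge
    p1 <- mean_field_params(T = params$T, N_e = params$N_e, N_i = params$N_i,
                            step = params$step, order = 1)
    s1 <- find_stationary_state(F_pair, p1, external_rate, dt, tol, max_t)
    state <- state_vec(s1$nu_e, s1$nu_i)
  }
  converged <- FALSE
  n_steps <- ceiling(max_t / dt)
  check_every <- 25
  for (k in seq_len(n_steps)) {
    state <- rk4_step(state, dt, rhs)
    state[1:2] <- pmax(state[1:2], 0)
    if (any(state[1:2] > 200) || any(!is.finite(state))) {
      abort("mean-field instability: population rate exceeded 200 Hz")
    }
    if (k %% check_every == 0 && max(abs(rhs(state))) < tol) {
      converged <- TRUE
      break
    }
  }
  out <- as_tibble(as.list(state))
  attr(out, "converged") <- converged
  if (!converged) warning("stationary search did not reach tolerance")
  out
}

#' Integrate the mean field through a stimulus
#'
#' Fixed-step 4th-order Runge-Kutta from the stationary state, with the
#' stimulus envelope added to the external drive. Rates are clamped at 0
#' from below after each step; clamping events are counted in the
#' `n_clamped` attribute.
#'
#' @param F_pair Transfer functions, as in [tf_derivatives()].
#' @param params [mean_field_params()].
#' @param stimulus A [stimulus_profile()] or `NULL`.
#' @param external_rate Spontaneous external drive rate (Hz).
#' @param duration Integration time (ms).
#' @param dt Step (ms); must satisfy `dt <= T / 20`.
#' @param record_dt Sampling interval of the returned trajectory (ms).
#' @param init Initial state (one-row tibble or named vector); defaults to
#'   [find_stationary_state()].
#' @return A tibble trajectory with columns `t`, `nu_e`, `nu_i`, `c_ee`,
#'   `c_ei`, `c_ii`, `stim_rate`.
#' @export
integrate_mean_field <- function(F_pair, params = mean_field_params(),
                                 stimulus = NULL, external_rate = 0,
                                 duration = 4000, dt = 0.1, record_dt = 5,
                                 init = NULL) {
  stopifnot(dt <= params$T / 20)
  F_pair <- as_tf_pair(F_pair)
  if (is.null(init)) {
    init <- find_stationary_state(F_pair, params, external_rate, dt = dt)
  }
  init <- as.list(init)
  state <- state_vec(init$nu_e[1], init$nu_i[1],
                     init$c_ee[1] %||% 0,
                     init$c_ei[1] %||% 0,
                     init$c_ii[1] %||% 0)
  n_steps <- round(duration / dt)
  rec_every <- max(1, round(record_dt / dt))
  n_rec <- floor(n_steps / rec_every) + 1
  out <- matrix(NA_real_, n_rec, 7)
  n_clamped <- 0L
  r <- 1
  stim_at <- function(t) if (is.null(stimulus)) 0 else stimulus_rate(t, stimulus)
  out[r, ] <- c(0, state, stim_at(0))
  for (k in seq_len(n_steps)) {
    t0 <- (k - 1) * dt
    rhs <- function(s) {
      # stimulus evaluated mid-step consistently with the RK4 substeps
      mean_field_rhs(s, F_pair, params, external_rate + stim_at(t0 + dt / 2))
    }
    state <- rk4_step(state, dt, rhs)
    if (any(state[1:2] < 0)) {
      n_clamped <- n_clamped + 1L
      state[1:2] <- pmax(state[1:2], 0)
    }
    if (k %% rec_every == 0) {
      r <- r + 1
      out[r, ] <- c(k * dt, state, stim_at(k * dt))
    }
  }
  traj <- tibble(t = out[, 1], nu_e = out[, 2], nu_i = out[, 3],
                 c_ee = out[, 4], c_ei = out[, 5], c_ii = out[, 6],
                 stim_rate = out[, 7])
  structure(traj, class = c("mf_trajectory", class(traj)),
            n_clamped = n_clamped, order = params$order)
}

#' Write a mean-field trajectory as delimited text
#'
#' @param traj A trajectory from [integrate_mean_field()].
#' @param path File path.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.table(as.data.frame(traj), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
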