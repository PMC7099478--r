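#' Fit the threshold polynomial to measured rates
#'
#' Two-stage semianalytic fit. Stage 1 maps every sample whose measured rate
#' lies strictly inside the attainable range into threshold space with
#' [invert_rate()] and solves for the ten polynomial coefficients by ordinary
#' least squares. Stage 2 refines the coefficients by nonlinear least squares
#' directly on the rate residuals of the erfc formula (Levenberg-Marquardt),
#' starting from the stage-1 solution; samples with measured rate 0 are
#' excluded from stage 1 (their threshold is undefined) but contribute to
#' stage 2.
#'
#' @param samples A data frame with columns `nu_e`, `nu_i`, `rate` (e.g. from
#'   [measure_transfer_function()]); at least 10 samples with nonzero rate.
#' @param cell A `neuron_params` object (leak fields used in the moment
#'   calculus).
#' @param synapse,K_e,K_i Measurement context; taken from `samples`
#'   attributes when it is a `tf_measurement` and not supplied.
#' @param alpha Fixed rate multiplier of the erfc formula.
#' @param norm [threshold_norm()] used for the polynomial coordinates.
#' @return An object of class `tf_fit`: a list with `tf` (the fitted
#'   [transfer_function()]), `poly`, `rms` (root-mean-square rate error in Hz
#'   over the fitted samples), `samples` (with `.fitted` and `.resid`
#'   columns) and `n_stage1`.
#' @export
fit_transfer_function <- function(samples, cell = NULL, synapse = NULL,
                                  K_e = NULL, K_i = NULL, alpha = 1,
                                  norm = threshold_norm()) {
  cell <- cell %||% attr(samples, "params")
  synapse <- synapse %||% attr(samples, "synapse") %||%
    default_synapse(model_of(cell))
  K_e <- K_e %||% attr(samples, "K_e") %||% 400
  K_i <- K_i %||% attr(samples, "K_i") %||% 100
  if (is.null(cell)) abort("`cell` parameters are required")
  samples <- as_tibble(samples[, c("nu_e", "nu_i", "rate")])
  if (sum(samples$rate > 0) < 10) {
    abort("need at least 10 samples with nonzero measured rate")
  }

  mom <- voltage_moments(samples$nu_e, samples$nu_i, cell, K_e, K_i, synapse)
  attainable <- samples$rate > 0 &
    2 * mom$tau_V * (samples$rate / 1000) / alpha < 1.98 &
    mom$sigma_V > 0

  # stage 1: linear fit in threshold space
  mom1 <- mom[attainable, ]
  v_emp <- invert_rate(samples$rate[attainable], mom1, alpha)
  X <- threshold_design(mom1, norm)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    abort(paste("degenerate measurement grid (rank", qrX$rank,
                "of 10 polynomial terms identifiable); broaden the",
                "(nu_e, nu_i) grid"))
  }
  p1 <- qr.coef(qrX, v_emp)

  # stage 2: nonlinear refinement on rate residuals, all samples
  rate_of <- function(p) {
    poly <- threshold_polynomial(setNames(p, threshold_terms), norm)
    v_thr <- effective_threshold(mom, poly)
    z <- ifelse(mom$sigma_V > 0,
                (v_thr - mom$mu_V) / (sqrt(2) * mom$sigma_V),
                ifelse(mom$mu_V < v_thr, Inf, -Inf))
    1000 * alpha / (2 * mom$tau_V) * erfc(z)
  }
  fit2 <- minpack.lm::nls.lm(par = p1,
                             fn = function(p) rate_of(p) - samples$rate,
                             control = minpack.lm::nls.lm.control(maxiter = 200))
  p2 <- setNames(coef(fit2), threshold_terms)

  poly <- threshold_polynomial(p2, norm)
  tf <- transfer_function(poly, cell, synapse, K_e, K_i, alpha)
  fitted <- rate_of(p2)
  samples$.fitted <- fitted
  samples$.resid <- samples$rate - fitted
  structure(list(tf = tf, poly = poly,
                 rms = sqrt(mean((samples$rate - fitted)^2)),
                 samples = samples, n_stage1 = sum(attainable),
                 alpha = alpha, cell = cell),
            class = "tf_fit")
}

#' @export
print.tf_fit <- function(x, ...) {
  cat("<tf_fit: ", model_of(x$cell), " ", x$cell$cell %||% "", ", ",
      nrow(x$samples), " samples (", x$n_stage1, " in stage 1), rms = ",
      signif(x$rms, 3), " Hz>\n", sep = "")
  print(x$poly)
  invisible(x)
}

#' Tidy a fitted transfer function
#'
#' @param x A `tf_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate` (mV).
#' @method tidy tf_fit
#' @export
tidy.tf_fit <- function(x, ...) {
  tibble(term = names(x$poly$coef), estimate = unname(x$poly$coef))
}

#' One-row fit summary
#'
#' @param x A `tf_fit`.
#' @param ... Unused.
#' @return A tibble with `model`, `cell`, `n_samples`, `n_stage1`, `alpha`
#'   and `rms` (Hz).
#' @method glance tf_fit
#' @export
glance.tf_fit <- function(x, ...) {
  tibble(model = model_of(x$cell), cell = x$cell$cell %||% NA_character_,
         n_samples = nrow(x$samples), n_stage1 = x$n_stage1,
         alpha = x$alpha, rms = x$rms)
}

#' Samples with fitted values and residuals
#'
#' @param x A `tf_fit`.
#' @param ... Unused.
#' @return The sample tibble with `.fitted` and `.resid` columns.
#' @method augment tf_fit
#' @export
augment.tf_fit <- function(x, ...) x$samples

#' Write / read fitted threshold coefficients as delimited text
#'
#' One row per fit, columns named after the ten polynomial terms, plus the
#' normalization constants.
#'
#' @param fit A `tf_fit` or `threshold_polynomial`.
#' @param path File path.
#' @return `read_threshold()` returns a [threshold_polynomial()].
#' @export
write_threshold <- function(fit, path) {
  poly <- if (inherits(fit, "tf_fit")) fit$poly else fit
  row <- c(as.list(poly$coef), unclass(poly$norm))
  utils::write.table(as.data.frame(row), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_threshold
#' @export
read_threshold <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t")
  norm <- threshold_norm(x$mu_V0, x$dmu_V0, x$sigma_V0, x$dsigma_V0,
                         x$tau_VN0, x$dtau_VN0)
  threshold_polynomial(setNames(as.numeric(x[1, threshold_terms]),
                                threshold_terms), norm)
}
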