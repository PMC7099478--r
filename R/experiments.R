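#' Read an experiment configuration file
#'
#' Plain YAML; any subset of the fields understood by the `run_*_experiment`
#' functions (`model`, `cells`, `seed`, `duration`, `network`, `tf`,
#' `mean_field`, `stimulus`, plus parameter overrides under `params_exc`,
#' `params_inh`, `synapse`). Missing fields take the experiment defaults.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_experiment_config <- function(path) {
  if (!file.exists(path)) abort(paste("config file not found:", path))
  yaml::read_yaml(path)
}

merge_config <- function(defaults, config) {
  utils::modifyList(defaults, config %||% list())
}

stage_log <- function(verbose, stage, ...) {
  if (verbose) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                    paste0(..., collapse = "")))
  }
}

config_checksum <- function(config) rlang::hash(config)

experiment_params <- function(model, config) {
  syn_over <- config$synapse %||% list()
  synapse <- do.call(default_synapse, list(model = model))
  if (length(syn_over) > 0) synapse <- do.call(synapse_params,
                                               modifyList(unclass(synapse)[c("Q_e", "Q_i", "tau", "E_e", "E_i")],
                                                          syn_over))
  list(exc = do.call(neuron_params,
                     c(list(model = model, cell = "RS"),
                       config$params_exc %||% list())),
       inh = do.call(neuron_params,
                     c(list(model = model, cell = "FS"),
                       config$params_inh %||% list())),
       synapse = synapse)
}

#' Measure and fit transfer functions for RS and FS cells
#'
#' Runs the full semianalytic pipeline for one neuron model: build a
#' measurement grid spanning the fluctuation-driven region (the 8 Hz
#' inhibitory-background row is always included), measure the transfer
#' function by seeded single-neuron simulation, fit the threshold
#' polynomial, and report the rms rate error per cell.
#'
#' @param config A list (e.g. from [read_experiment_config()]) with optional
#'   fields `model` (default `"adex"`), `cells`, `seed`, and a `tf` sublist
#'   (`nu_i`, `n_nu_e`, `duration`, `n_seeds`, `rate_max`, `alpha`).
#' @param out_dir If non-`NULL`, write the measured tables
#'   (`tf_<cell>_measured.tsv`), fitted coefficients (`tf_<cell>_fit.tsv`)
#'   and a YAML report.
#' @param full Use the reference grid (8 inhibitory backgrounds, 12 points,
#'   10 s x 4 seeds); the default desk grid is half that size.
#' @param verbose Stage-level logging.
#' @return A list with per-cell `fits` (class `tf_fit`), `measurements`,
#'   and a one-row-per-cell `report` tibble.
#' @export
run_tf_experiment <- function(config = list(), out_dir = NULL, full = FALSE,
                              verbose = TRUE) {
  model <- config$model %||% "adex"
  cells <- config$cells %||% c("RS", "FS")
  seed <- config$seed %||% 1
  tf_defaults <- if (full) {
    list(nu_i = c(0.5, 2, 4, 6, 8, 12, 16, 20), n_nu_e = 12,
         duration = 10000, n_seeds = 4, rate_max = 30, alpha = 1)
  } else {
    list(nu_i = c(2, 4, 8, 16), n_nu_e = 8,
         duration = 5000, n_seeds = 2, rate_max = 30, alpha = 1)
  }
  tfc <- merge_config(tf_defaults, config$tf)
  if (!(8 %in% tfc$nu_i)) tfc$nu_i <- sort(c(tfc$nu_i, 8))
  prm <- experiment_params(model, config)
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)

  fits <- list()
  measurements <- list()
  for (cell in cells) {
    params <- if (cell == "RS") prm$exc else prm$inh
    stage_log(verbose, "grid", model, " ", cell)
    grid <- tf_grid(params, nu_i = tfc$nu_i, n_nu_e = tfc$n_nu_e,
                    rate_max = tfc$rate_max, synapse = prm$synapse,
                    pilot_seed = seed)
    if (nrow(grid) < 2 || length(unique(grid$nu_e)) < 2) {
      abort("degenerate measurement grid; broaden the nu_e/nu_i ranges")
    }
    stage_log(verbose, "measure", model, " ", cell, " (", nrow(grid),
              " points)")
    m <- measure_transfer_function(params, grid, prm$synapse,
                                   duration = tfc$duration,
                                   seeds = seed + seq_len(tfc$n_seeds) - 1)
    stage_log(verbose, "fit", model, " ", cell)
    fit <- fit_transfer_function(m, alpha = tfc$alpha)
    fits[[cell]] <- fit
    measurements[[cell]] <- m
    if (!is.null(out_dir)) {
      utils::write.table(as.data.frame(m),
                         file.path(out_dir, paste0("tf_", cell, "_measured.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      write_threshold(fit, file.path(out_dir, paste0("tf_", cell, "_fit.tsv")))
    }
  }
  report <- purrr::map_dfr(fits, glance)
  report$config_checksum <- config_checksum(config)
  if (!is.null(out_dir)) {
    yaml::write_yaml(list(report = as.data.frame(report),
                          config = config,
                          grid = tfc),
                     file.path(out_dir, "tf_report.yml"))
  }
  list(fits = fits, measurements = measurements, report = report)
}

network_from_config <- function(config, full = FALSE) {
  net_defaults <- if (full) {
    list(N = 10000, p_conn = 0.05, frac_exc = 0.8, nu_drive = 4,
         K_e_ext = 400)
  } else {
    list(N = 2500, p_conn = 0.2, frac_exc = 0.8, nu_drive = 4,
         K_e_ext = 400)
  }
  netc <- merge_config(net_defaults, config$network)
  network_config(N = netc$N, frac_exc = netc$frac_exc, p_conn = netc$p_conn,
                 nu_drive = netc$nu_drive, K_e_ext = netc$K_e_ext,
                 seed = config$seed %||% 1)
}

mf_from_config <- function(config, net) {
  mfc <- merge_config(list(T = 20, step = 0.05), config$mean_field)
  n_exc <- round(net$N * net$frac_exc)
  mean_field_params(T = mfc$T, N_e = n_exc, N_i = net$N - n_exc,
                    step = mfc$step, order = 2)
}

#' Spontaneous-activity experiment: network versus mean field
#'
#' Simulates the E/I network in its spontaneous asynchronous irregular state,
#' computes per-population rate statistics over 20 ms windows, and compares
#' them with the first- and second-order mean-field stationary state built
#' on the fitted transfer functions.
#'
#' @param config As in [run_tf_experiment()], plus a `network` sublist
#'   (`N`, `p_conn`, `frac_exc`, `nu_drive`, `K_e_ext`), a `duration` field
#'   (ms of network time, default 10 s) and a `mean_field` sublist (`T`,
#'   `step`).
#' @param fits Optional per-cell list of `tf_fit` objects (from
#'   [run_tf_experiment()]); fitted here if missing.
#' @param out_dir Optional output directory (raster, rate series, report).
#' @param full Reference network size (N = 10^4, p = 0.05) instead of the
#'   desk scale (N = 2500, p = 0.2; identical in-degrees).
#' @param verbose Stage-level logging.
#' @return A list with `raster`, `rates` (a [population_rate()] result),
#'   `mf_first`, `mf_second` (stationary states) and a `comparison` tibble.
#' @export
run_spontaneous_experiment <- function(config = list(), fits = NULL,
                                       out_dir = NULL, full = FALSE,
                                       verbose = TRUE) {
  model <- config$model %||% "adex"
  seed <- config$seed %||% 1
  duration <- config$duration %||% 10000
  if (is.null(fits)) {
    stage_log(verbose, "tf", "fitting transfer functions")
    fits <- run_tf_experiment(config, full = full, verbose = verbose)$fits
  }
  net <- network_from_config(config, full)
  prm <- experiment_params(model, config)
  stage_log(verbose, "simulate", model, " network, N = ", net$N, ", ",
            duration, " ms, seed ", seed)
  raster <- simulate_network(model, net, prm$exc, prm$inh, prm$synapse,
                             duration = duration)
  rates <- population_rate(raster, window = 20, t_start = min(1000, duration / 5))

  stage_log(verbose, "integrate", "mean-field stationary states")
  mfp <- mf_from_config(config, net)
  pair <- as_tf_pair(fits$RS, fits$FS)
  mf1 <- find_stationary_state(pair,
                               mean_field_params(T = mfp$T, N_e = mfp$N_e,
                                                 N_i = mfp$N_i,
                                                 step = mfp$step, order = 1),
                               external_rate = net$nu_drive)
  mf2 <- find_stationary_state(pair, mfp, external_rate = net$nu_drive)

  comparison <- tibble(
    population = c("exc", "inh"),
    network_mean = rates$summary$mean_rate,
    network_sd = rates$summary$sd_rate,
    mf1_mean = c(mf1$nu_e, mf1$nu_i),
    mf2_mean = c(mf2$nu_e, mf2$nu_i),
    mf2_sd = sqrt(pmax(c(mf2$c_ee, mf2$c_ii), 0)))
  stage_log(verbose, "compare", "network vs mean field done")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_raster(raster, file.path(out_dir, "raster.tsv"))
    utils::write.table(as.data.frame(rates$series),
                       file.path(out_dir, "population_rates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(comparison = as.data.frame(comparison),
                          config = config,
                          config_checksum = config_checksum(config),
                          network = unclass(net)),
                     file.path(out_dir, "spontaneous_report.yml"))
  }
  list(raster = raster, rates = rates, mf_first = mf1, mf_second = mf2,
       comparison = comparison)
}

#' Stimulus-response experiment: network versus mean field
#'
#' Drives both the network and the mean field with the same double-Gaussian
#' stimulus envelope added to the external drive, and reports time-aligned
#' population-rate traces plus a peak-response comparison.
#'
#' @param config As in [run_spontaneous_experiment()], plus a `stimulus`
#'   sublist (`A`, `t0`, `T1`, `T2`; default A = 2 Hz, t0 = 2 s,
#'   T1 = 100 ms, T2 = 150 ms).
#' @param fits Optional per-cell `tf_fit` list.
#' @param out_dir Optional output directory.
#' @param full Reference network size.
#' @param verbose Stage-level logging.
#' @return A list with `raster`, `network_rates`, `mf_trajectory` (second
#'   order), `mf_first` (first-order trajectory) and a `comparison` tibble
#'   of baseline and peak rates.
#' @export
run_stimulus_experiment <- function(config = list(), fits = NULL,
                                    out_dir = NULL, full = FALSE,
                                    verbose = TRUE) {
  model <- config$model %||% "adex"
  seed <- config$seed %||% 1
  stc <- merge_config(list(A = 2, t0 = 2000, T1 = 100, T2 = 150),
                      config$stimulus)
  stim <- stimulus_profile(stc$A, stc$t0, stc$T1, stc$T2)
  duration <- config$duration %||% (stc$t0 + 8 * stc$T2)
  if (is.null(fits)) {
    stage_log(verbose, "tf", "fitting transfer functions")
    fits <- run_tf_experiment(config, full = full, verbose = verbose)$fits
  }
  net <- network_from_config(config, full)
  prm <- experiment_params(model, config)
  stage_log(verbose, "simulate", model, " network with stimulus")
  raster <- simulate_network(model, net, prm$exc, prm$inh, prm$synapse,
                             stimulus = stim, duration = duration)
  rates <- population_rate(raster, window = 5)

  stage_log(verbose, "integrate", "mean-field trajectories")
  mfp <- mf_from_config(config, net)
  pair <- as_tf_pair(fits$RS, fits$FS)
  traj2 <- integrate_mean_field(pair, mfp, stim, external_rate = net$nu_drive,
                                duration = duration)
  mfp1 <- mean_field_params(T = mfp$T, N_e = mfp$N_e, N_i = mfp$N_i,
                            step = mfp$step, order = 1)
  traj1 <- integrate_mean_field(pair, mfp1, stim,
                                external_rate = net$nu_drive,
                                duration = duration)

  in_stim <- function(t) t > stc$t0 - 2 * stc$T1 & t < stc$t0 + 3 * stc$T2
  base_net <- rates$series |>
    dplyr::filter(!in_stim(.data$t), .data$t > min(1000, duration / 5)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(baseline = mean(.data$rate), .groups = "drop")
  stim_net <- rates$series |>
    dplyr::filter(in_stim(.data$t)) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(mean_during = mean(.data$rate), .groups = "drop")
  peak_sign <- function(traj, col) {
    x <- traj[[col]]
    base <- x[1]
    dev <- x[in_stim(traj$t)] - base
    dev[which.max(abs(dev))]
  }
  comparison <- tibble(
    population = c("exc", "inh"),
    network_baseline = base_net$baseline,
    network_stim_delta = stim_net$mean_during - base_net$baseline,
    mf2_baseline = c(traj2$nu_e[1], traj2$nu_i[1]),
    mf2_peak_delta = c(peak_sign(traj2, "nu_e"), peak_sign(traj2, "nu_i")),
    mf1_peak_delta = c(peak_sign(traj1, "nu_e"), peak_sign(traj1, "nu_i")))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_raster(raster, file.path(out_dir, "raster.tsv"))
    write_trajectory(traj2, file.path(out_dir, "mf_trajectory.tsv"))
    utils::write.table(as.data.frame(rates$series),
                       file.path(out_dir, "population_rates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(comparison = as.data.frame(comparison),
                          stimulus = stc, config = config,
                          config_checksum = config_checksum(config)),
                     file.path(out_dir, "stimulus_report.yml"))
  }
  list(raster = raster, network_rates = rates, mf_trajectory = traj2,
       mf_first = traj1, comparison = comparison)
}
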