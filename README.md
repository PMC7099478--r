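# neuromf

Mean-field models of conductance-based spiking neuron networks.

`neuromf` is for computational neuroscientists who want to connect
single-neuron biophysics to population dynamics. It simulates random
excitatory/inhibitory networks of conductance-based spiking neurons — the
Adaptive Exponential Integrate-and-Fire (AdEx), Hodgkin–Huxley (HH) and
Morris–Lecar (ML) models — in the asynchronous irregular regime typical of
awake cortex, and reduces them to a two-population master-equation mean
field whose only model-specific ingredient is a semianalytically fitted
*transfer function*.

## The method in brief

A neuron bombarded by `K_e` excitatory and `K_i` inhibitory Poisson
synapses (rates ν_e, ν_i; quanta Q_e, Q_i; exponential decay τ) has
subthreshold voltage moments that follow from shot-noise statistics:
mean μ_V, fluctuation σ_V and autocorrelation time τ_V. Its output rate is
modeled as

    F(ν_e, ν_i) = α / (2 τ_V) · erfc( (V_thr_eff − μ_V) / (√2 σ_V) )

where the effective threshold V_thr_eff is a second-order polynomial in
(μ_V, σ_V, τ_V·g_L/c_m) whose ten coefficients are fitted to seeded
single-neuron simulations — once per cell type. The population dynamics is
then the master-equation mean field on a Markovian timescale T ≈ 20 ms:

    T dν_µ/dt = F_µ − ν_µ + ½ Σ c_λη ∂²F_µ/∂ν_λ∂ν_η
    T dc_λη/dt = δ_λη F_λ(1/T − F_η)/N_λ + (F_λ−ν_λ)(F_η−ν_η)
                 + Σ_µ [∂F_λ/∂ν_µ c_ηµ + ∂F_η/∂ν_µ c_λµ] − 2 c_λη

which at first order is a Wilson–Cowan rate model and at second order also
predicts the population-rate covariances. The package validates the chain
end-to-end: the mean field, which never sees a spike, predicts the
spontaneous rates, their fluctuations, and the response to slow stimuli of
the spiking network.

See the methods vignette (`vignettes/mean-field-methods.Rmd`) for the
model equations, the unit calibration of the HH and ML parameter sets, and
all numerical choices.

## Worked example

Fit the AdEx fast-spiking transfer function from simulations, predict the
network's spontaneous state with the mean field, and compare against a
direct network simulation:

```r
library(neuromf)

# 1. measure + fit transfer functions for both cell types
fit_rs <- fit_transfer_function(measure_transfer_function(
  adex_params("RS"), tf_grid(adex_params("RS")), duration = 10000, seeds = 1:4))
fit_fs <- fit_transfer_function(measure_transfer_function(
  adex_params("FS"), tf_grid(adex_params("FS")), duration = 10000, seeds = 1:4))
glance(fit_fs)
#> # A tibble: 1 × 6
#>   model cell  n_samples n_stage1 alpha   rms
#>   <chr> <chr>     <int>    <int> <dbl> <dbl>
#> 1 adex  FS           96       67     1 0.157

# 2. second-order mean-field stationary state under the 4 Hz external drive
mfp <- mean_field_params(T = 20, N_e = 2000, N_i = 500, order = 2)
find_stationary_state(list(fit_rs, fit_fs), mfp, external_rate = 4)
#> # A tibble: 1 × 5
#>    nu_e  nu_i   c_ee  c_ei  c_ii
#>   <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1  2.85  16.2 0.0767 0.137 0.371

# 3. the spiking network itself (N = 2500, in-degrees preserved), 10 s
raster <- simulate_network("adex", scaled_network_config(N = 2500, seed = 1),
                           duration = 10000)
mean_population_rates(raster, t_start = 1000)
#> # A tibble: 2 × 2
#>   population mean_rate
#>   <chr>          <dbl>
#> 1 exc             1.94
#> 2 inh            14.1
```

The fitted transfer function reproduces the simulated rates to 0.16 Hz rms
in the sub-30 Hz fluctuation-driven region; the mean field predicts the
network's spontaneous excitatory/inhibitory rates (2.9/16.2 Hz predicted
vs. 1.9/14.1 Hz simulated) and, through √c_ee and √c_ii, the standard
deviation of the population rates over 20 ms windows. `autoplot()` methods
exist for rasters, rate series, measured/fitted transfer functions and
mean-field trajectories, and `tidy()`/`glance()`/`augment()` summarize
fits.

Stimulus-response experiments (`run_stimulus_experiment()`) drive network
and mean field with the same double-Gaussian rate envelope; AdEx and HH
populations respond with a positive transient, while the Morris–Lecar
network — whose bell-shaped transfer function is decreasing at the
operating point — is *inhibited* by the excitatory stimulus, in both the
network and the mean field.

A thin command-line front end ships in `exec/neuromf` with verbs
`simulate`, `tf`, `spontaneous`, `stimulus` and `meanfield`, all taking
`--seed`, `--out` and an optional YAML `--config`.

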