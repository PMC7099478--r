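---
title: "From single-neuron biophysics to population dynamics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From single-neuron biophysics to population dynamics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neuromf)
```

`neuromf` links the biophysics of single conductance-based neurons to the
collective dynamics of the networks they form. The pipeline has three layers:

1. **Spiking simulation.** Single neurons (Adaptive Exponential
   Integrate-and-Fire, Hodgkin–Huxley, Morris–Lecar) are driven by Poissonian
   synaptic bombardment, and sparse excitatory/inhibitory networks of the
   same neurons are simulated directly.
2. **Semianalytic transfer functions.** Each cell type's stationary
   input–output relation $F(\nu_e, \nu_i)$ is captured by an analytic
   formula with one fitted ingredient, a phenomenological *effective
   threshold*.
3. **Master-equation mean field.** Two coupled populations (excitatory RS,
   inhibitory FS) are reduced to ordinary differential equations for their
   rates and — at second order — rate covariances, built entirely on the
   fitted transfer functions.

The package's claim to validity is that layer 3, which never sees a spike,
quantitatively predicts the spontaneous state and the stimulus response of
layer 1.

## Network and synapse model

Networks are random directed graphs of $N$ neurons (80% excitatory RS, 20%
inhibitory FS; reference size $N = 10^4$, connection probability
$P = 0.05$, so mean in-degrees are $K_e = 400$ and $K_i = 100$). Synapses
are conductance-based: a presynaptic spike increments the target's
excitatory or inhibitory conductance by a quantum $Q_e$ or $Q_i$, which then
decays exponentially with $\tau = 5$ ms. The synaptic current is
$I_{syn} = G_e (E_e - v) + G_i (E_i - v)$ with reversals $E_e = 0$ mV,
$E_i = -80$ mV (standard cortical values; the model set does not pin them
down, so they are configurable in `synapse_params()`). AdEx and HH networks
use $Q_e = 1.5$, $Q_i = 5$ nS; ML networks use $Q_e = 4$, $Q_i = 10$ nS.

Every neuron additionally receives an external excitatory drive through
`K_e_ext = 400` independent Poisson synapses, each at
$\nu_{drive} = 4$ Hz by default. Two remarks on this convention:

* A *single* 4 Hz afferent train cannot sustain any activity; the
  400-synapse reading is also the only one under which the mean-field input
  convention (drive added to the excitatory rate argument of the transfer
  function, which was fitted at $K_e = 400$) is consistent with the network.
* Desk-scale networks (`scaled_network_config()`, default $N = 2500$)
  preserve the in-degrees by raising $P$, because the single-neuron input
  statistics — which is everything the mean field sees — depend on $K$, not
  on $N$.

Synaptic transmission is delayless on the integration grid: spikes emitted
at step $k$ increment their targets' conductances at the end of step $k$ and
act from step $k+1$.

### Initial conditions of network simulations

The spontaneous asynchronous irregular (AI) state coexists with a fully
synchronized saturated state in which every neuron fires at its maximal
rate. The saturated state is absorbing: near the reset potential the
inhibitory driving force $(v - E_i)$ is small, so once a full-population
volley forms, inhibition cannot break the cycle. Whether a simulation finds
the AI state therefore depends on how it starts. `simulate_network()`
initializes voltages jittered around $E_L$ and conductances at the
stationary mean of the external drive plus a balancing inhibitory
conductance, so the first few milliseconds resemble the asynchronous state
rather than a synchronized ramp. HH networks additionally start from an
*adapted* state (slow K$^+$ gate $p$ at 0.5): the I$_M$ current needs about
100 ms to build, and an unadapted onset volley would otherwise tip the
network into saturation before adaptation can act.

## Single-neuron models

All models are integrated with fixed-step explicit Euler — appropriate in a
regime driven by discontinuous synaptic shot noise, where high-order
smoothness is absent — with $dt = 0.1$ ms for AdEx and ML and $dt = 0.01$ ms
for HH (fast sodium gating). Units are mV, ms, nS, pF, pA throughout.

**AdEx** (`adex_params()`): capacitance 150 pF, leak 10 nS to $-65$ mV,
exponential spike initiation with slope $\Delta$ (2 mV RS, 0.5 mV FS),
nominal threshold $v_t = -50$ mV, reset to $-65$ mV with a 5 ms refractory
clamp, and an adaptation current $w$ with
$\tau_w \dot w = a (v - E_L) - w$, incremented by $b$ at each spike
($a = 4$ nS, $b = 60$ pA for RS; none for FS). Two numerical choices
deserve emphasis:

* The *spike cutoff*. A spike is registered when $v$ exceeds
  $v_{cut} = v_t + 5\Delta$, not $v_t$ itself. Between $v_t$ and $v_{cut}$
  the exponential term must actually win against the instantaneous synaptic
  and adaptation currents; under strong shunting the unstable fixed point of
  the voltage equation sits well above $v_t$, so resetting already at $v_t$
  would bypass the soft spike-initiation nonlinearity and grossly
  overestimate excitability. The difference is not cosmetic: with the
  literal $v > v_t$ rule the recurrent network has **no** stable
  asynchronous state at the reference coupling — from any initial condition
  it collapses within milliseconds into the saturated 200 Hz limit cycle.
  With the standard cutoff the same network settles into the AI state
  (RS $\approx 2$ Hz, FS $\approx 14$ Hz). `v_cut` is a parameter; setting
  `v_cut = v_t` recovers the literal rule.
* The *adaptation coupling*. The subthreshold term is implemented as
  $a (v - E_L) / \tau_w$ inside $\dot w$ (the standard AdEx form). Reading
  the coupling as $a (v - E_L)$ *without* the $1/\tau_w$ normalization would
  make the stationary adaptation $a \tau_w (v - E_L) \approx 2$ nA per mV of
  depolarization, clamping RS cells to their resting potential and
  silencing them entirely — inconsistent with RS cells firing at a few Hz
  in the spontaneous network state.

**Hodgkin–Huxley** (`hh_params()`): transient Na, delayed-rectifier K and a
slow non-inactivating K current I$_M$ (RS only), with the usual
$\alpha/\beta$ gating rates parameterized by $V_T = -53.5$ mV. The three
removable singularities of the rate functions are evaluated through
`expm1`-based expressions with their analytic limits, so the rates are
continuous to machine precision. Spikes are upward crossings of $+10$ mV,
debounced (a second spike requires the trace to fall below threshold
first).

**Morris–Lecar** (`ml_params()`): instantaneous Ca activation $M_{ss}(v)$,
slower K gating variable $N$ with rate constant $\phi$, and activation
parameters $V_1..V_4$ that place the model in the type II excitability
class. Strong depolarization silences the cell (depolarization block), so
its transfer function is bell-shaped.

### Unit calibration for HH and ML

The HH and ML parameter sets are published as per-area densities
(mS/cm², µF/cm²) while the synaptic quanta are absolute (nS); no membrane
area is given, and the printed density units are internally inconsistent
(e.g. capacitance in "pF/cm²"). The package therefore adopts an explicit
absolute-unit calibration, chosen once and documented here:

* **HH**: leak and capacitance at face value (10 nS, 200 pF; resting
  $\tau_m = 20$ ms). Fast channel densities scaled by
  `active_scale = 1000` (nominal 20 and 6 read as 20 µS and 6 µS): action
  potentials then overshoot well past the detection threshold and
  depolarization block appears only at very high input rates (peak
  sustained rate $\approx 540$ Hz before collapse). The I$_M$ density
  carries its own factor (default $g_M = 45$ nS, 1.5× the fast-channel
  scale), set so that the recurrent network has a stable AI state: with a
  weaker I$_M$, a self-consistent saturated balanced state at
  $\approx 270$ Hz (verified to be stable even for isolated neurons under
  matched Poisson input) swallows every initial condition.
* **ML**: the whole intrinsic membrane is calibrated against the fixed
  synaptic quanta: densities map to nS with a factor 0.625
  ($g_L = 12.5$, $g_{Ca} = 50$, $g_K = 100$ nS), capacitance to 125 pF
  (resting $\tau_m = 10$ ms), and the reference DC current to
  $I_0 = 875$ pA, which places the quiescent RS cell at rheobase. The
  gating rate $\phi$ is not in the printed set at all; its default
  0.003/ms completes the calibration. The two free constants
  ($I_0$, $\phi$) were fixed by one requirement: the RS transfer function
  under an 8 Hz inhibitory background rises from near-silence, peaks near
  an 8 Hz excitatory input, and collapses above it (depolarization block).
  They were not revisited afterwards.

Because ML FS cells have $E_L = -70$ mV against $-50$ mV for RS (as
published), the ML inhibitory population is *less* excitable than the
excitatory one — the opposite of the AdEx/HH arrangement — and fires below
the RS rate in the spontaneous network state.

## Subthreshold moments and the transfer function

Under Poissonian bombardment at per-synapse rates $(\nu_e, \nu_i)$ the
conductance moments are the shot-noise expressions
$\mu_{G_s} = \nu_s K_s \tau Q_s$ and
$\sigma_{G_s} = Q_s \sqrt{\nu_s K_s \tau / 2}$. The total conductance
$\mu_G = \mu_{Ge} + \mu_{Gi} + g_L$ sets the effective membrane time
constant $\tau_m^{eff} = c_m / \mu_G$, and the passive-membrane voltage
statistics follow: the mean $\mu_V$ is the conductance-weighted combination
of reversal potentials, and $\sigma_V$, $\tau_V$ follow from filtering the
synaptic shot noise with efficacies $U_s = Q_s (E_s - \mu_V) / \mu_G$
(`voltage_moments()`). Spike-generating and adaptation currents are
deliberately excluded from this calculus; their mean effect is absorbed by
the fitted threshold. The approximation degrades as rates grow, which is
one reason the method is restricted to the low-rate fluctuation-driven
regime (output below $\sim$30 Hz).

The output rate is
$$F = \frac{\alpha}{2 \tau_V} \,\mathrm{erfc}\!\left(
  \frac{V_{thr}^{eff} - \mu_V}{\sqrt{2}\,\sigma_V}\right),$$
with $\alpha = 1$ except when fitting across very high rates (the
wide-range HH fit uses $\alpha = 2$). The effective threshold is a full
second-order polynomial — ten coefficients — in the normalized coordinates
$(\mu_V, \sigma_V, \tau_V^N = \tau_V g_L / c_m)$. The normalization
constants (`threshold_norm()`: center $-60$ mV / scale 1 mV for $\mu_V$,
4 / 6 mV for $\sigma_V$, 0.5 / 1 for $\tau_V^N$) are a pure
reparameterization — rescaling them and compensating the coefficients
leaves every prediction unchanged, a property the test suite asserts — so
coefficient tables are only comparable *under the same normalization*. The
published reference tables ship in
`reference_thresholds()` for inspection, but their printed normalization
constants are dimensionally ambiguous (volt/millivolt confusion), so
coefficients fitted here are not numerically interchangeable with them.

### Fitting

`fit_transfer_function()` is a two-stage fit to measured single-neuron
rates:

1. Every sample whose rate lies strictly inside the attainable range
   $(0, \alpha / \tau_V)$ is mapped to an *empirical threshold* by
   inverting the erfc formula (`invert_rate()`), and the ten coefficients
   are obtained by ordinary least squares in threshold space — a linear
   problem.
2. Levenberg–Marquardt refinement minimizes the squared *rate* residuals of
   the full formula over all samples (silent samples included), starting
   from the stage-1 solution.

Zero-rate samples are excluded from stage 1 because their threshold is
undefined (the inverse erfc diverges). A rank check on the stage-1 design
matrix rejects degenerate grids (e.g. a single inhibitory background) with
an instruction to broaden the grid.

The measurement grid (`tf_grid()`) spans inhibitory backgrounds
$\nu_i \in \{0.5, 2, 4, 6, 8, 12, 16, 20\}$ Hz and, per background, places
12 excitatory rates from 0 up to the point where the output reaches 30 Hz,
located by bisection with short pilot simulations. This concentrates
samples in the fluctuation-driven region where the formula is valid; each
point is measured over 10 s and averaged across 4 seeds. On this grid the
fitted AdEx curves track the simulated rates with an rms error well below
1 Hz in the sub-30 Hz region.

## The master-equation mean field

On a coarse Markovian timescale $T$ (default 20 ms), the two population
rates evolve as
$$T \dot\nu_\mu = F_\mu - \nu_\mu
  + \tfrac12 \sum_{\lambda\eta} c_{\lambda\eta}
    \frac{\partial^2 F_\mu}{\partial\nu_\lambda \partial\nu_\eta},$$
and the covariances as
$$T \dot c_{\lambda\eta} =
  \delta_{\lambda\eta} \frac{F_\lambda (1/T - F_\eta)}{N_\lambda}
  + (F_\lambda - \nu_\lambda)(F_\eta - \nu_\eta)
  + \sum_\mu \left[
      \frac{\partial F_\lambda}{\partial\nu_\mu} c_{\eta\mu}
    + \frac{\partial F_\eta}{\partial\nu_\mu} c_{\lambda\mu}\right]
  - 2 c_{\lambda\eta}.$$
Dropping the covariance terms recovers the Wilson–Cowan form (order 1).
The finite-size source term is implemented with the Kronecker prefactor
exactly as written, i.e. it feeds only the diagonal entries; its printed
index pattern mixes $\lambda$ and $\eta$, and no reading other than the
literal one was assumed. The external drive (spontaneous plus stimulus) is
added to the excitatory-rate argument of both transfer functions, matching
the network's external-synapse convention. A constant-$F$ sanity check has
the closed-form stationary covariance
$c = F(1/T - F) / (2N)$, which the implementation reproduces to
$10^{-6}$.

Numerics: derivatives of the fitted transfer functions are central finite
differences with step 0.05 Hz — small against the Hz-scale structure of
$F$, large against fit noise — switching to one-sided stencils at the
$\nu = 0$ boundary so rates are never evaluated negative; mixed partials
are iterated first-derivative stencils and hence symmetric by
construction. Time stepping is fixed-step 4th-order Runge–Kutta with
$dt = 0.1$ ms (the equations are smooth; the constraint is only
$dt \le T/20$). Rates are clamped at zero from below after each step, with
clamping events counted. `find_stationary_state()` integrates from
$\nu = (1, 1)$ Hz until the right-hand side norm falls below
$10^{-8}$ Hz/ms; for the second-order system the rates are first settled
on the first-order flow, because far from the fixed point the covariance
transient can outgrow the rate convergence and destabilize the integration.
Rates exceeding 200 Hz raise an instability error.

## Stimulus protocol

`stimulus_profile()` implements the asymmetric double-Gaussian rate
envelope (amplitude $A$, peak time $t_0$, rise $T_1$, decay $T_2$;
reference values $A = 2$ Hz, $T_1 = 100$ ms, $T_2 = 150$ ms, $t_0 = 2$ s),
added to the external drive of every neuron and to the mean-field drive
argument alike. For AdEx and HH networks the response is a positive
transient tracking the envelope; for ML the same excitatory stimulus pushes
cells over their depolarization block, so both populations' rates *drop* —
an anticorrelated response that the mean field reproduces because the
fitted bell-shaped transfer function is decreasing at the operating point.
The Markovian construction requires stimuli slow compared with $T$; faster
envelopes degrade the prediction.

## What the simulations do and do not emulate

All validation inputs are generated internally: seeded Poisson trains,
Erdős–Rényi connectivity, and the parameter sets above. The generator
emulates stationary asynchronous cortical activity and slow stimuli; it
does not emulate synaptic delays or kinetics beyond single-exponential
decay, depressing/facilitating synapses, bursting or rebound firing,
spatial structure, or heterogeneous parameters within a population.
Passing tests therefore demonstrate internal consistency of the
simulation–fit–prediction chain under these idealized conditions, not
fidelity to any particular experimental recording.

Problem sizes used in the shipped tests and in `scripts/acceptance.R`:
desk-scale networks of $N = 2500$ (in-degrees preserved) simulated for
10 s; transfer functions measured over 10 s per grid point with 4 seeds;
depolarization-block sweeps of 24 drive levels at 5 s each. The
`run_*_experiment()` functions accept a `full = TRUE` flag restoring the
reference $N = 10^4$ network.

## Known limitations

* The absolute-unit calibration for HH and ML is the package's own
  resolution of inconsistent published units; exact numerical parity with
  other implementations of the same models cannot be guaranteed, though
  all qualitative targets (type II ML, late HH block, AI network states)
  are met.
* The AI and saturated network states coexist; the shipped initial
  conditions select the AI basin under the default parameters, but strong
  parameter changes (much larger quanta, much weaker adaptation) can make
  the saturated state dominant again.
* The semianalytic transfer function degrades above ~30 Hz output and near
  depolarization block; the wide-range HH fit requires $\alpha = 2$ and
  remains approximate there.
* Whether HH/ML spike counting should carry an explicit refractory beyond
  threshold debouncing is not specified by the model set; debouncing alone
  is used here.
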