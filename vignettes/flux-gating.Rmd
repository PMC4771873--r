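---
title: "Ion-flux gating in K2P channels: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ion-flux gating in K2P channels: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxgate)
```

## The model

Two-pore-domain (K2P) potassium channels have no voltage-sensing domain,
yet most of them activate with depolarisation and shut at negative
potentials. `fluxgate` implements the quantitative picture in which the
selectivity filter itself is the gate and the sensor: what the filter reads
is not the membrane voltage but the electrochemical driving force on K+,

$$\Delta\mu = V_m - E_{rev},$$

with $E_{rev}$ from the GHK voltage equation (Nernst for a single permeant
ion). Outward flux ($\Delta\mu > 0$) pushes ions into the filter; the
ion-loaded filter then relaxes into a conducting conformation. Inward flux
destabilises the conducting filter, which collapses into an ion-depleted
inactive state. The result is a one-way "check valve": steady-state
conduction only above $E_{rev}$, plus transient inward tail currents right
after repolarisation, while the loaded filter is still open.

### The four-state scheme

The kinetic core (`rate_matrix()`, `propagate()`, `steady_state()`) is a
continuous-time Markov chain over four filter states:

* **ID** — ion-depleted, inactive (the resting state at negative
  $\Delta\mu$; the analogue of C-type inactivation),
* **IO** — ion-occupied, inactive,
* **AO** — active, conducting outward,
* **AI** — active, conducting inward (unstable).

Transitions:

1. **Loading, ID ⇌ IO.** This step carries the gating charge. Forward and
   backward rates are $k_{load,0}\,e^{\pm x/2}$ with
   $x = (\Delta\mu - \Delta\mu_{1/2})\, zF/RT$, a symmetric-barrier
   ($\delta = 0.5$) law whose equilibrium is exactly the Boltzmann
   `loading_equilibrium()` with slope $RT/zF$. The bench-level observable —
   the Boltzmann slope of the tail G-V — therefore recovers the preset $z$
   identically. No rate law for loading is empirically known; fast loading
   ($k_{load,0} = 10$/ms) makes the choice irrelevant to everything except
   sub-sample transients.
2. **Conformational activation, IO → AO** at the voltage-independent rate
   $k_{act}$, with a small back-rate $k_{deact}$. Because loading
   pre-equilibrates, the observed activation relaxes at
   $p_{load} k_{act} + k_{deact}$: voltage independent wherever loading is
   saturated, which is what gives the flat $\tau$–V relation of the
   flux-gated presets. Activation is only available in the outward-flux
   regime ($\Delta\mu \ge 0$). This gating of $k_{act}$ is deliberate: with
   loading still open below $E_{rev}$, any nonzero activation path would
   set up a standing ID→IO→AO→AI→ID cycle and a steady inward current,
   destroying the check-valve property. The rate is still strictly
   voltage-independent over the whole activating range.
3. **Direction relabeling, AO ⇌ AI.** The two active states are a
   conduction-direction tag, not two free-energy wells: both conduct the
   same open-pore current. A fast first-order rate (`k_switch`, 200/ms)
   moves the active population to the label matching the sign of
   $\Delta\mu$, keeping the generator a proper CTMC instead of introducing
   a discontinuous relabeling.
4. **Inactivation, AI → ID** at $k_{inact}$: the inward-conducting filter
   decays to the structurally distinct ion-depleted state. $1/k_{inact}$ is
   the tail decay time constant. Recovery routes through ID (not IO) so
   the resting state after a tail is genuinely ion-depleted.

### Macroscopic current

`simulate_current()` evaluates

$$I(t) = N \gamma \; \mathrm{GHK}(V(t)) \,
  \big[(1 - m)\,(P_{AO} + P_{AI} + f\,(P_{ID} + P_{IO})) + m\big],$$

where $\mathrm{GHK}$ is the open-pore Goldman–Hodgkin–Katz flux summed over
permeant species, $f$ (`po_floor`) is a small residual conductance of the
inactive states, and $m$ (`mode_shift`) is the fraction of channels
converted to pure GHK leak mode by agonists (arachidonic acid, PIP2,
pressure, pH). $f$ is what makes the rectification coefficient finite; the
model takes no position on its physical origin. $m$ follows a per-preset
Hill law in agonist concentration (`mode_shift_fraction()`); the mode
conversion itself is established experimentally, the Hill form is the
package's choice to match dose-response practice.

### Gating-charge decomposition

`field_model()` / `per_site_charge()` / `total_gating_charge()` implement
the electrostatic budget of loading: if ~80% of the membrane field drops
linearly across the filter, ions loaded successively at S1…S4 (fractional
electrical depths 1, 3/4, 1/2, 1/4 from the cavity edge of the field)
contribute $0.8, 0.6, 0.4, 0.2\,e_0$ — a total of $2.0\,e_0$, matching the
measured K2P average of about $2.2\,e_0$ and implying that three to four
ions enter the filter on depolarisation. Depths are electrical, not
geometric; the 12 Å span is metadata. Ion–ion repulsion corrections and
non-linear field profiles are out of scope.

## Parameters that matter

| Parameter | Units | Default | Meaning / why |
|---|---|---|---|
| `z` | $e_0$ | preset | Boltzmann slope of loading; per-channel values are placed inside the measured 1.8–2.6 range with a mean of 2.2 (4.6 for the voltage-gated control) |
| `dmu_half` | mV | preset | loading midpoint on the $\Delta\mu$ axis. Symmetric-K+ presets use −20 mV so loading is saturated by +20 mV (voltage-independent $\tau$); Rb+ presets use strongly positive values so the tail G-V saturates inside the protocol with both plateaus resolved |
| `k_act`, `k_deact` | 1/ms | ~0.25, 0.02 | conformational opening and its small back-rate; calibrated so the fitted activation $\tau$ is ~4 ms |
| `k_inact` | 1/ms | ~0.25 | tail decay rate (τ ≈ 4 ms) |
| `po_floor` | – | 0.01–0.05 | inactive-state residual conductance; sets the rectification coefficient (e.g. 0.0197 gives 47 for TREK-1) |
| `mode_shift` | – | 0 | GHK leak fraction; 1 for the TWIK-1-like leak preset |
| `gamma_scale`, `n_channels` | pA/flux, – | 0.01, 200 | absolute current scale; analysis results are scale-invariant |
| temperature | K | 294 | room-temperature recordings; $RT/F \approx 25.33$ mV |

Relative permeabilities (Rb 0.3, Cs 0.05, Na 0.01, Tl 1.2, NH4 0.15,
NMDG 0) are stated assumptions, not measured values; NMDG+ is a pure
substituent. Every preset ships provenance notes distinguishing experimentally
measured observables from calibration assumptions.

## What the synthetic data emulate — and what they do not

`generate_family()` reproduces the standard voltage-clamp experiment: hold
−80 mV (50 ms), 300 ms steps (−100…+100 mV by default), 100 ms tail at
−80 mV, 0.05 ms sampling, with additive Gaussian noise scaled to the
family's peak current. `generate_dose_response()` draws fold-activation
from the preset's Hill law with multiplicative noise.
`generate_trajectory()` builds per-frame axial ion coordinates with
Poisson-distributed complete filter crossings, partial-excursion
distractors, and resident ions whose presence probabilities reproduce a
target per-site occupancy profile (thinned to compensate for transiting
ions, so recovery is unbiased).

These generators deliberately omit capacitive transients, series
resistance, amplifier filtering, drift, line noise, multi-channel
stochastic gating, and any force-field realism in the trajectories. A
passing test therefore shows that the *pipeline* is correct and that the
*model* reproduces the calibrated observables — not that real recordings
or real MD trajectories are this clean. In particular, the trajectory
module validates the event detector and occupancy estimators against its
own generator, a stated convention; defining and running real MD event
detection is outside this package's scope.

## Numerical choices

* **Propagation** is exact per constant-voltage segment via
  eigendecomposition of the 4×4 generator (complex-safe, with a
  scaling-and-squaring matrix-exponential fallback if the eigenbasis is
  ill-conditioned); ramps are stepped per sample at the midpoint voltage.
  Probability is conserved to ~1e-15 and verified against an explicit-Euler
  oracle at 1/1000 of the sample interval in a slow-rate regime where the
  oracle's first-order error is itself below 1e-6.
* **Loading-rate clamp.** The exponential loading rates are capped at
  $10^3 \times k_{load,0}$ so the generator never becomes stiff relative to
  the 0.05 ms grid; this distorts the equilibrium only where the Boltzmann
  is within $10^{-3}$ of saturation.
* **GHK singularity.** The flux at $|V_m| < 10^{-6}$ mV uses the series
  limit, making the function continuous and exactly linear in symmetric
  solutions.
* **Nonlinear fits** (exponential, Boltzmann, Hill) run on raw
  Levenberg–Marquardt (`minpack.lm::nls.lm`) with box constraints and
  analytic initial guesses (half-rise voltage, 20–80% rise slope,
  1/e-point $\tau$). Standard errors come from the approximate Hessian.
  This path accepts perfect zero-residual fits, which `nls()`-based
  wrappers reject as singular. Boltzmann slopes are bounded to
  $z \in (0.1, 20]$.
* **Tail extraction** blanks 0.3 ms after repolarisation (a capacitive
  settle convention; no value is reported experimentally) and extrapolates
  the fitted exponential back to the repolarisation instant. The reported
  amplitude is the instantaneous *total* current (transient + fitted
  steady baseline): that is the quantity tail I-V plots use, it makes the
  leak-mode fold change exactly 1, and the Boltzmann offset term absorbs
  the baseline. Tail $\tau$ is bounded to 0.5–200 ms — decays faster than
  the blank are unresolvable and would explode the back-extrapolation on
  noisy data. Flat tails (pure leak) are reported with `tau = NA`.
* **End-of-step current** averages the last 5% of the step, excluding the
  boundary sample that already belongs to the tail segment.
* **G-V normalisation**: to the fitted Boltzmann plateau when the fit
  saturates within the sampled range ($V_{1/2} + 3\,\mathrm{slope} \le
  V_{max}$), otherwise to the maximum observed amplitude with a
  non-saturating flag — mirroring the experimental refusal to quote $z$
  from non-saturating K+ curves.
* **Trajectory geometry**: the 1.2 nm filter is split into four equal
  0.3 nm windows (S1 extracellular), with a 0.05 nm hysteresis margin on
  the crossing thresholds; an event is attributed to the frame at which the
  ion clears the far threshold. Window positions are a package convention.

## Design choices where the design was open

* The **tail decay** is modelled as AI → ID inactivation rather than
  deactivation through IO; the two are not distinguishable from macroscopic
  currents, and the inactivation route matches the ion-depleted resting
  state the model requires.
* **Permeant-ion effects** (Rb+ potentiation and saturating G-Vs, poorly
  permeant Cs+) are encoded purely as preset overrides (`dmu_half` shift,
  `gamma_scale`), not predicted from per-site occupancy.
* The **Rb+ loading midpoints** place the G-V midpoint about four Boltzmann
  slopes above $E_{rev}$: far enough that the check-valve cutoff at
  $\Delta\mu = 0$ truncates less than ~2% of the lower limb (fitted-$z$
  bias ≲ 2%), and low enough that the upper plateau is reached by
  +160 mV. The voltage-gated control preset gets the same treatment inside
  its −60…+60 mV protocol.
* **Per-preset z values** are free calibration constants inside the
  experimentally reported range, placed with margin to the 1.8/2.6
  endpoints so that noisy single-family fits stay inside it.
* Simulation is **deterministic (ODE-level)**; single-channel stochastic
  gating, temperature-dependent kinetics, and mechanosensitive tension
  terms are out of scope (pressure activation appears only as a mode-shift
  override).

## Problem sizes

The shipped tests and the acceptance script run the full pipelines at the
sizes the package documents as its reference conditions: 11–13-trace
families at 0.05 ms sampling (9 000 samples per trace), 10 noisy replicates
for the control-channel fit, six presets × five seeds for the K2P average,
10 µs trajectories (10 000 frames) over 20 seeds, and 7-point dose-response
series over 10 seeds. A full acceptance run takes a few seconds on one
core.

## Known limitations

* The inactive-state residual conductance `po_floor` is phenomenological;
  the model cannot attribute it to a mechanism.
* The AI state has no independent quantitative constraints beyond the tail
  τ; its occupancy during inward conduction is a model construct.
* The Euler-oracle agreement bound applies in the slow-rate regime; in
  stiff regimes the eigendecomposition path is the more accurate of the
  two, so the oracle comparison is not meaningful there.
* Trajectory statistics validate against the package's own generator only;
  reading real MD formats is explicitly out of scope.
* Ion-activity corrections, surface potentials and divalent block are not
  modelled.
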