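---
title: "A reduced CA1 microcircuit for theta-nested slow gamma: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A reduced CA1 microcircuit for theta-nested slow gamma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ca1pac)
```

## The scientific question

Hippocampal CA1 shows phase-amplitude coupling (PAC) between a slow theta
rhythm (~3-8 Hz) and a faster slow-gamma rhythm (~15-50 Hz): the gamma
amplitude waxes and wanes with the theta phase. `ca1pac` implements a
desk-scale model of one candidate circuit mechanism: oriens-lacunosum/
moleculare (OLM) interneurons, which have a weak intrinsic tendency to fire
irregular bursts of gamma-interval spikes when driven just above threshold,
are coupled to pyramidal (PYR) cells in a feedback loop. The loop produces a
PING-like reverberation (pyramidal-interneuron network gamma) that
synchronizes and amplifies the OLM bursting, turning it into a robust
population oscillation in which the theta rhythm *requires* the gamma one.
The package contains both the simulator for this circuit and the complete
oscillation-analysis toolchain used to quantify its output, plus synthetic
generators so every analysis operation is testable against constructions
with known answers.

## The neuron model

All three cell classes (PYR, PVBC = parvalbumin basket cells, OLM) are
reduced to single-compartment adaptive conductance-based
leaky-integrate-and-fire units,

$$C \frac{dV}{dt} = -g_L (V - E_L) - \sum_k g_k(t)(V - E_k^{rev})
  - \big(w + g_{KCa}(\mathrm{Ca})\big)(V - E_K),$$

with exponential-Euler integration at `dt = 0.05` ms, a 2 ms refractory
clamp at the reset potential, `E_K = -90` mV, and synaptic reversals 0 mV
(excitatory) / -80 mV (inhibitory). Two spike-triggered adaptation
variables carry the mechanism-critical OLM phenotype:

* a **fast AHP conductance** `w` (jump `w_fast_jump` per spike, decay
  `tau_fast`), the reduced analogue of the delayed-rectifier potassium
  current — it paces spikes within a burst at gamma intervals;
* a **calcium-gated potassium conductance**
  `g_KCa = g_kca_max * Ca / (Ca + k_half)` with a per-spike calcium
  increment (`ca_jump`, decay `tau_ca`) — calcium accumulated over a burst
  activates it, terminates the burst, and its ~220 ms decay sets the
  theta-period silence before the next burst can start.

This is the deliberate central reduction of the package: the original
mechanism was demonstrated with morphologically detailed multicompartment
models carrying nine active conductances. Only the *phenotypes* those
models contribute to the circuit mechanism are retained: near-rheobase
noisy drive elicits irregular stutter-bursts (2-4 spikes at 20-30 Hz
intervals recurring at theta intervals), far-above-rheobase drive elicits
tonic gamma-interval firing, PVBC never burst, and PYR fire regularly at
13-26 Hz over the explored drive range. `calibrate_report()` documents
these gates; the quantitative frequencies of the detailed models are
calibration targets, not guarantees.

Channel knock-outs are exposed through `apply_knockout()`:
`KDR_analog` removes the fast AHP and `CAGK_analog` the Ca-gated K
conductance (zeroing a maximal conductance, as in the detailed-model
experiments). Calcium enters the reduced model only through the per-spike
increment, so a calcium-channel knock-out collapses onto `CAGK_analog`
rather than being separately resolvable — the degeneracy among CaN/CaL/CaT
in the detailed model is deliberately not reproduced. The parameter
`g_kdr_tonic` (default 0) adds a tonic subthreshold potassium conductance
to the KDR analogue; see *Known limitations* for why it is off by default.

## The synapse model

Synapses are event-driven Tsodyks-Markram (TM) units. Between presynaptic
events the utilization `u` relaxes to 0 with time constant `F` and the
resource fraction `R` recovers to 1 with time constant `D`; at an event,

```
u <- u * exp(-dt/F);  u <- u + U * (1 - u)      (F = 0: u = U)
R <- 1 - (1 - R) * exp(-dt/D)                   (D = 0: R = 1)
release <- u * R;  R <- R * (1 - u)
```

so a quiescent synapse's first event releases exactly `U`. The conductance
event amplitude is `g_peak * release / U`, making an unfacilitated,
undepressed event deliver exactly `g_peak`; whether the original
implementation scales by `u R` or `u R / U` is not documented, and this
normalization is the package's recorded choice. Under a periodic train the
recursion has a closed-form fixed point (`tm_periodic_steady_state()`),
which the event recursion reaches to 1e-9 in tests, and the whole recursion
is checked against an independent fine-step RK4 integration of the TM
differential equations to a relative error of 1e-6.

Conductance kernels are peak-normalized single-exponential decays
(instantaneous rise); an NMDA-like slow component is a second exponential
scaled by the published NMDA ratio. Two reductions apply: the voltage
dependence of the NMDA Mg block is omitted, and instead every slow
component is multiplied by a fixed `nmda_scale = 0.06`, a stand-in for the
resting-potential Mg-unblock fraction (~5-10% near -60 mV); without it the
long NMDA decay (148.5-298.75 ms) integrates to an unphysiologically large
tonic conductance in a point neuron.

The published projection parameters are carried verbatim in
`synapse_registry()`: PYR->OLM facilitating (U 0.07, F 470 ms, D 38 ms,
AMPA 1.7 ms, NMDA 148.5 ms, ratio 0.28), PYR->PVBC depressing (U 0.32,
F 0, D 110 ms, AMPA 4.12 ms, NMDA 298.75 ms, ratio 0.28), OLM->PYR
depressing (U 0.3, F 6 ms, D 1770 ms, GABA 18 ms), PVBC->PYR depressing
(U 0.16, F 8.6 ms, D 965 ms, GABA 5.94 ms). PYR->PYR and PVBC->PVBC STP
constants are not published for this circuit; they default to static
synapses rather than guessed values. The PVBC->PVBC GABA decay is likewise
unpublished and defaults to 5.94 ms, the same as PVBC->PYR.

## The network

Wiring follows the published statistics: every ordered model-cell pair of a
projection draws its synaptic contact count from `Binomial(N, p)` with
`N = group_size(pre) x synapses_per_connection` and `p` the connection
probability (PYR->OLM 0.35/5, PYR->PVBC 0.35/6, OLM->PYR 0.4/13,
PVBC->PYR 0.25/11, PYR->PYR 0.35/3, PVBC->PVBC 0.35/5). The full model
(FM) uses 480 PYR, 20 OLM and 20 PVBC model cells (PVBC representing 4
cells each); the simplified model (SM) uses 120 PYR groups of 4 and 10 OLM
groups of 2, only the PYR->OLM and OLM->PYR projections, no recurrence, no
PVBC, OLM->PYR without STP and a GABA decay of 11.8 ms. Variants: `FMx` /
`SMx` remove the OLM->PYR feedback, `FMfix` removes its STP, `SM7` / `SM25`
set the OLM->PYR GABA decay to 7 / 25 ms with tripled conductance.

Schaffer-collateral drive: the input level `scil` means `scil/20`
independent 34 Hz Poisson processes per PYR cell, each making six contacts
with conductance uniform in [0.55, 0.65] nS and delays uniform in
[0.5, 2] ms, no STP. Internal synaptic delays also default to
[0.5, 2] ms per contact (the source documents delays only for the SC
inputs). Each connection's peak conductance is drawn once, uniformly from
the projection's published range, and shared by that connection's contacts;
delays are per contact. Simulations run 6.3 s and the first 2 s are
discarded at analysis time.

### Conductance calibration

Point neurons lack the dendritic attenuation of the detailed models, so
each projection carries a dimensionless scale factor on top of its
published conductance range (`g_scale`, see `build_network()`). The
calibration procedure, run once and frozen: (1) scale the SC drive so the
isolated PYR f-I curve spans the published operating range (13-26 Hz over
SCIL 120-200) — giving `SC_PYR = 1/6`, i.e. the six contacts of a drive
process act like one published-strength contact; (2) scale PYR->OLM so
the OLM population sits just above rheobase at the working SCIL
(`PYR_OLM = 0.016`); (3) scale OLM->PYR so the feedback pause supports a
PING reverberation in the slow-gamma band without tonic lock-up
(`OLM_PYR = 0.25`); (4) with those fixed, scale the FM-only projections
for plausible FM rates (PYR ~15 Hz, PVBC ~30 Hz, OLM ~6 Hz at SCIL 140):
`PYR_PVBC = 0.1`, `PVBC_PYR = 0.1`, `PYR_PYR = 0.008`,
`PVBC_PVBC = 0.05`. The calibrated operating point for the SM family is
SCIL 180. At that point the SM's OLM population shows a theta peak near
7.8 Hz and a slow-gamma peak near 18 Hz — both inside the analysis bands
but higher/lower respectively than the 4.5 Hz / 25 Hz of the detailed
model, an accepted cost of the reduction.

## The analysis chain

All statistics operate on population rate series (4 ms bins, Hz per cell).

* **Spectra**: Welch averaged periodograms, Hann taper, 2048 ms windows,
  50% overlap, per-segment mean removal, then a 2-point moving average of
  the power values. Band peaks are the maxima over the closed theta
  (1-8 Hz) and slow-gamma (15-50 Hz) bands; "strength" is returned raw and
  log-transformed, since both conventions are used for display.
* **Comodulogram**: for each phase frequency the series is band-passed
  (half-width 1 Hz) and the instantaneous phase taken from the analytic
  signal; for each amplitude frequency the envelope is extracted with
  half-width `max(4, f_theta)` Hz — wide enough to pass the coupling
  sidebands, whose offset equals the phase frequency. PAC is the
  coefficient of determination of `A ~ b0 + b1 cos(phi) + b2 sin(phi)`, a
  GLM-style estimator bounded in [0, 1] and invariant to amplitude
  scaling. Band-pass filtering uses zero-phase FFT-domain masks with
  cosine-tapered edges (stable at any band and trivially zero-phase);
  scalar statistics are the mean/peak of the matrix over 1-8 x 15-50 Hz
  (the caption convention 1-12 x 12-50 Hz is available as an option — the
  two conflict in the source material and the Methods bands are the
  default).
* **Surrogates**: the calibrated null for significance is the circular
  time-shift of the amplitude envelope against the phase series (spectra
  and autocorrelation exactly preserved). A full shuffle of the envelope
  is also provided; it destroys the phase-amplitude alignment entirely and
  is the right null for construction fixtures with line spectra, where the
  regression estimator — which fits the coupling phase freely — retains
  its value under Fourier phase randomization.
* **Theta-cycle averaging**: the theta peak of the reference (OLM) rate is
  found in 1-8 Hz, the reference band-passed in a 2 Hz band around it with
  a 5th-order zero-phase Butterworth filter, local troughs below the mean
  located, all rates cut trough-to-trough, segments outside the closed
  interval `[0.9, 1.1]/f_theta` discarded, the rest decimated by
  block-averaging to the shortest retained length and averaged. Constant
  or oscillation-free references raise an explicit "no valid theta cycles"
  error rather than averaging filter transients.
* **Spectrogram / covariation**: 256 ms Hann windows (50% overlap); theta
  and gamma power series are spectrogram averages over a 1 Hz band at the
  theta peak and an 8 Hz band at the gamma peak, standardized to zero mean
  and unit variance, then regressed (gamma on theta) for the coefficient
  of determination and slope. The alternative 1 s moving-window, 4/16 Hz
  band convention can be reproduced via the exposed window and bandwidth
  arguments.
* The 30-point rate smoothing seen in display figures is never applied
  before spectral estimation; `smooth3()` implements the 3-point moving
  average across neighbouring SCIL levels used on sweep curves, which are
  means over two randomly configured replicate simulations with SEM.

## Synthetic generators

Three generators make every analysis operation testable without a
simulation. `gen_pac_signal()` produces
`sin(2 pi f_p t) + [1 - d + d (1 + sin(2 pi f_p t))/2] sin(2 pi f_a t)`
plus Gaussian noise: the fast amplitude is a *linear* function of the slow
sinusoid, chosen because the comodulogram estimator regresses amplitude on
phase sinusoids, so the optimum is analytically at `(f_p, f_a)` and
`d = 0` switches coupling off exactly. The noisy-fixture noise level is
0.3 (noise RMS about a third of the slow component) — a moderate-SNR
regime in which seeds matter but localization should succeed.
`gen_burst_spikes()` gates a gamma-beat spike placement by a theta duty
cycle: per cell and cycle a Poisson count (truncated to the active
window's gamma-beat capacity) of spikes at consecutive gamma periods from
the window start, jittered; the mean rate is analytically
`theta_f * E[min(N, capacity)]`, intra-burst intervals sit at
`1000/gamma_f` ms, and the silence fraction mimics the quiet periods
between bursts. `gen_covarying_powers()` is the bivariate-normal
construction with exact population correlation `rho`, for which the
regression R² converges to `rho^2`. All generators are seed-deterministic
and restore the caller's RNG state.

What the generators do *not* emulate: membrane-potential waveforms,
1/f-like broadband backgrounds, non-stationary frequency drift, or
asymmetric (non-sinusoidal) theta. Passing tests on them validates the
estimators' algebra and calibration, not their behaviour on arbitrary real
recordings.

## Numerical choices

Integration uses `dt = 0.05` ms; event delivery is quantized to the step.
Drive randomness runs on a private, portable 64-bit Mersenne Twister in
the compiled core; wiring randomness uses R's RNG under a per-call seed;
`derive_seed()` fans out child seeds counter-style so adding replicates
never perturbs earlier ones. Welch/comodulogram/spectrogram estimates use
FFTs without zero-padding; frequency resolution is 0.49 Hz for the 2048 ms
window at 250 Hz. Tie-breaks: band peaks take the first maximum; the
comodulogram argmax on noiseless fixtures can tie across adjacent phase
bands that all contain the slow component (tests use noisy fixtures for
localization). Degenerate inputs (constant series, empty tables,
zero-variance powers) raise errors naming the problem instead of
propagating NaN.

Problem sizes used by the test-suite and reproduction scripts (chosen once
as representative desk-scale conditions): 6.3 s simulations with 2 s
discarded, two replicate seeds per condition, 10-seed recovery runs at
60 s of synthetic signal, 50-run null calibrations at 12 s per run, and
100-200 surrogates per test.

## Design choices where the ground was open

* **Variant conductance factors**: `SM7`/`SM25` triple the OLM->PYR
  conductance alongside their decay changes, as specified for the original
  experiments. At this package's operating point the tripling largely
  cancels the decay-speedup effect on the gamma frequency (the inhibitory
  pause scales as `tau * log(3 G / G_crit)`), so the named-variant
  comparison shows frequency ties; the fixed-strength decay sweep in
  `analysis/04_sm_mechanism.R` (`gaba_tau` override, equal conductance)
  exhibits the clean monotone effect: ~23 Hz at 7 ms, ~19 Hz at 11.8 ms,
  no detectable gamma at 25 ms.
* **KDR analogue**: mapped to the spike-triggered fast AHP. A purely
  spike-triggered conductance cannot move the firing threshold, so the
  threshold-lowering effect of the detailed model's K_DR knock-out is not
  reproduced by default. The optional `g_kdr_tonic` component restores it
  (a tonic K leak that the knockout removes), but the added conductance
  load degrades the regularity of the theta bursts that the mechanism
  experiments measure; with one parameter set serving all experiments, the
  default keeps the burst phenotype and accepts the missing threshold
  effect.
* **Replicate aggregation**: band-peak detectability is assessed on the
  PSD averaged over the two replicate simulations, matching how the sweep
  curves average replicates.
* **Group scaling**: a model cell representing k cells scales its outgoing
  contact counts (through `N = group_size x synapses_per_connection`), not
  its conductances; the "remaining" ~9500 below-threshold PYR cells of the
  full-density circuit are simply absent.

## Known limitations

The reduced neurons place the operating frequencies a few Hz away from the
detailed models (theta ~7.8 vs 4.5 Hz; SM slow gamma ~18 vs 23 Hz); the
conductance scale factors absorb dendritic attenuation into single
numbers; NMDA voltage dependence is a fixed scale; single-cell
spectra/strengths are computed by the same chain as population statistics
but were not separately calibrated; and the FM calibration targets
plausible rates rather than a quantitative fit. None of the acceptance
properties depend on reproducing the detailed models' absolute numbers.
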