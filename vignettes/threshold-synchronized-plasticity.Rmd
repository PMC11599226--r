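---
title: "Synchronized stepwise threshold plasticity in a spiking recurrent network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synchronized stepwise threshold plasticity in a spiking recurrent network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnnip)
```

## The model

`srnnip` simulates a three-layer system for online anomaly detection in
periodic 1-D signals: an input layer of Poisson spike generators, a randomly
connected middle layer of leaky integrate-and-fire (LIF) neurons (80%
excitatory, 20% inhibitory), and a linear readout trained to predict the next
input. What distinguishes the model from a generic liquid-state machine is a
pair of hardware-oriented learning rules that *reconstruct* the middle layer
before use, and in particular the way their thresholds are kept synchronized.

**Membrane.** Each neuron integrates `C dVmem/dt = I_in - Vmem/R` with
`R = 400` MOhm and `C = 10` pF (membrane time constant 4 ms). When `Vmem`
strictly exceeds the firing threshold `Vthr` the neuron fires, resets to
`Vreset = 0` V and is clamped there for a refractory period `tref = 3` ms,
bounding the firing rate by about `1/tref ≈ 333` fires/s. The simulator is
clock-driven with `dt = 0.1` ms; each per-step update uses the exact
exponential solution of its ODE, so results are robust to `dt` (halving the
step changes per-bin population rates by well under 2% when the same input
spikes are presented).

**Synapses.** A presynaptic spike injects charge through
`tau_syn dIsyn/dt = -Isyn + alpha W delta(t - t_spike)` with
`tau_syn = 5` ms: the current jumps by `alpha W / tau_syn` and decays. The
charge scale `alpha` is not a printed parameter of the model; the package
calibrates it with `calibrate_alpha()` so that one spike through a weight-1
synapse depolarizes a resting membrane by a chosen fraction of the initial
0.2 V threshold. The default fraction is 20%. This is a deliberate design
choice: with small unitary potentials (a few percent of threshold) the
recurrent synapses — 5% connectivity among 160 excitatory neurons, weights
bounded by 2 — merely perturb the membrane, the network behaves as a
feedforward rate encoder, plasticity has nothing to reorganize, and the
untrained network is already as good a reservoir as the trained one. At 20%
the recurrent population genuinely shapes the state: the untrained,
uniform-weight network shows the erratic, synchrony-prone dynamics that
motivate reconstruction, and the reconstructed network carries usable state
across input bins.

**SDSP.** Spike-driven synaptic plasticity acts only on the recurrent
excitatory-to-excitatory weights, at the moment a presynaptic spike arrives:
the weight steps up by `LR_SDSP` if the postsynaptic membrane potential is
above the learning threshold `VLthrUP`, down if it is below `VLthrDOWN`, and
is clipped to `[0, 2]`. The membrane is sampled before the arriving spike's
own current acts. With the headline step `LR_SDSP = 2` the weights are
binary after their first effective update. Arrivals during the postsynaptic
refractory period participate (the clamped membrane sits at the reset
potential, below `VLthrDOWN`, so they depress); this is switchable
(`sdsp_during_refractory`) since either convention is defensible.

**Event-driven stepwise IP.** Each neuron tracks a calcium-like trace:
`tau_ip dCfire/dt = -Cfire + sum delta(t - t_fire)` with `tau_ip = 100` ms,
whose long-run mean is `rate * tau_ip`. When an excitatory neuron fires, its
threshold steps by `LR_thr` — up if the trace is above the healthy band
`(1 ± sigma/2) C_IP` (with `C_IP = 15` fires/s, `sigma = 0.3`), down if
below — and is clipped to `[0.125, 0.4]` V. Two conventions reconciled here:

* *Units.* The trace is dimensionless while `C_IP` is printed in fires/s;
  the package compares `Cfire / tau_ip` against `C_IP` (equivalently
  `Cfire` against `C_IP tau_ip`), so the regulated rate is 15 fires/s. The
  raw comparison is available behind `raw_cfire_compare`.
* *Increment order.* Whether the triggering spike's own +1 is applied before
  or after the comparison is not derivable from the update rule alone. The
  package compares first (increment after): at spike times the
  pre-increment trace of an irregularly firing neuron is an unbiased sample
  of `rate * tau_ip` (Poisson arrivals see time averages), so the rule
  regulates the rate to `C_IP` itself. With the opposite order the rule
  regulates `rate * tau_ip + 1` into the band, i.e. a rate of about
  3–7 fires/s under these constants — far from the printed target. The
  opposite order remains available (`ca_increment_before_ip`).

**Threshold synchronization.** If the learning thresholds were fixed while
IP moved `Vthr`, a lowered `Vthr` could fall below `VLthrDOWN`; the membrane
would then never reach the potentiation region and every arrival would
depress until all plastic weights hit zero (this failure is a regression
test). The package therefore recomputes `VLthrUP = VLthrDOWN = Vthr/2` after
every IP event; stepping the learning thresholds by `LR_thr/2` on the same
trigger is algebraically identical (also tested).

## Encoding, readout and the detection statistic

A sample `E` (mV) is held for `T_bin = 150` ms while every input neuron
fires Poisson spikes at `F_in = F_poisson (4 + 2E)/5`, non-negative on the
admissible range `E ∈ [-2, 0.5]` mV (out-of-range samples are clipped and
counted). The default `F_poisson = 75` Hz places the network — through 100
input neurons connecting with probability 0.1 at the 20% calibration — in
the regime where the mean input-driven depolarization spans roughly
0.18–0.37 V across the signal range, against thresholds in
`[0.125, 0.4]` V.

The pipeline runs in three phases. Phase 1 presents the anomaly-free
training segment with SDSP and IP active. Phase 2 freezes all plasticity,
presents the training segment again, collects per-bin excitatory firing
rates and fits a rectified-linear readout (`F_out = max(0, w·x + b)`) by
ridge-regularized least squares against the *next* sample's `F_in` (the
ridge default `1e-6` is numerical conditioning only). Phase 3 presents the
labeled test segment frozen and computes `D[k+1] = |F_out[k] - F_in[k+1]|`.

`D_thr_no` is the largest `D` over normal-labeled samples; `D_thr_ab` is
the smallest of the per-event peaks of `D` (an event is a maximal run of
abnormal labels); their difference `delta_thr` is the judgment margin. A
positive margin means any threshold inside it detects every anomaly event
with zero false positives; `tpr_fpr_curve()` reports event-level and
point-level rates. Since `D_thr_ab` is unknowable in deployment, the
practical threshold `D_thr_no (1 + 0.05)` is also reported.

## The synthetic benchmark

`default_benchmark()` generates 120 beats at 80 bpm, 128 samples/s: a flat
baseline at -0.75 mV with three Gaussian bumps per beat (P, QRS, T; the QRS
18 ms wide, peaking at +0.5 mV), white noise of 0.02 mV, the first 60 beats
anomaly-free (training), and 5 of the last 60 beats transformed (test). The
default transform inverts the QRS and triples its width — an ectopic-like
morphology whose encoded frequency drops out of the normal range.

Two generator findings shaped this design, recorded here because they
determine what passing tests do and do not show:

* *Within-range morphology anomalies are not detectable one-step-ahead at
  this sampling rate.* A widened QRS at unchanged amplitude produces only
  transitions that also occur, sample pair by sample pair, in normal beats;
  an ideal regression on the encoded frequencies themselves (up to 4
  samples of context) leaves the margin negative. Detecting such anomalies
  requires beat-phase memory spanning seconds of presented time, which no
  network with sub-second time constants can hold when each sample is
  presented for 150 ms. The benchmark therefore uses an amplitude-novel
  anomaly, and a passing margin says nothing about subtle within-range
  morphology changes.
* *The untrained network fails for a specific reason.* With the defaults,
  the untrained (all weights 1.0, all thresholds 0.2 V) network responds
  weakly and erratically; during the anomaly's out-of-range stretch the
  network falls nearly silent and the untrained readout's prediction
  collapses toward zero, so `|F_out - F_in|` stays small exactly where it
  should peak — the anomaly is invisible and the margin is negative. The
  IP-regulated network maintains calibrated baseline activity, so its
  prediction stays at normal levels through the silent stretch and the
  margin is positive. This is the package's analogue of the
  initial-versus-reconstructed contrast.

What the generator does not emulate: beat-to-beat period variability,
baseline wander, measurement artifacts, or multiple coexisting anomaly
morphologies of real long-term ECG. Results on the benchmark therefore
demonstrate the mechanism, not clinical performance.

## Numerical and design choices

* Unspecified constants: `Vreset = 0` V (comparator-reset convention),
  `tref = 3` ms (must be positive; it sets the rate ceiling), uniform
  `U(0, Wmax)` draws for the non-plastic projections, no autapses
  (switchable). Inhibitory neurons share the excitatory cell constants,
  keep `Vthr = 0.2` V fixed, and are exempt from both rules.
* Spike delivery carries one `dt` of delay from fire to postsynaptic
  current, making the in-step update order well defined; external input
  spikes act in their own step. At a plastic synapse the injected current
  uses the stored weight and the SDSP update follows (pre-update weight
  injected).
* The current is held constant within a step for the membrane update;
  currents decay, then spikes inject, then membranes integrate, then fires
  and plasticity apply.
* Exponential decays are flushed to zero below physically meaningless
  magnitudes (1e-30 A; 1e-15 spike counts) — subnormal arithmetic would
  otherwise dominate the run time.
* Degenerate inputs: `dt <= 0`, unsortable rasters, out-of-range neuron
  indices and `F_in dt >= 1` are errors; a diverging membrane aborts with
  the step number; ties at threshold do not fire; clipping (not update
  suppression) enforces all bounds, so the binary attractors
  `{0, 2}` / `{0.125, 0.4}` V are reached exactly.
* The single-neuron homeostasis demonstration drives one neuron through 10
  weight-2 synapses at 120 Hz each, using the 5% PSP calibration: the drive
  exceeds the target band initially, and the unitary kicks are large enough
  that the 25 mV threshold steps resolve the band. In the steep
  fluctuation-driven regime of small kicks, one threshold step can swing
  the rate across the whole band and the time-averaged rate settles below
  it — a real limitation of coarse stepwise control, not of the
  implementation.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the full pipeline on the
120-beat benchmark (11,520 samples at `T_bin = 150` ms, i.e. about 2,600
simulated seconds per full pipeline at `dt = 0.1` ms, 200 neurons), the
single-neuron homeostasis run for 60 s, and scaled-down variants (tens of
beats, tiny networks) for the unit and property tests. These sizes were
chosen so the whole suite completes on a single CPU in well under half an
hour while leaving the statistics (margins, rates) clearly resolved.

## Known limitations

* The absolute synaptic scale and the base Poisson coefficient are
  calibrated, not printed constants; other calibrations move the network
  between silent, graded and saturated regimes, and the initial-network
  failure mode appears only when recurrence is strong (see above).
* Event-driven IP can only lower a threshold when the neuron fires; a
  neuron whose drive cannot reach the upper threshold bound may be left
  stranded by a transient. The demo avoids this regime; simulations of
  fully silent networks will too.
* The readout is a single abstract rectified-linear unit, not a spiking
  output neuron; point-level and event-level true-positive rates are both
  reported because the margin definition is event-level.
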