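---
title: "Calcium-based plasticity with fixed points and learning rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium-based plasticity with fixed points and learning rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fplr)
```

## The model

The calcium control hypothesis holds that the direction and rate of
long-term synaptic change are set by the postsynaptic calcium concentration:
below a depression threshold $\theta_D$ nothing happens (or weights drift
slowly toward stable states), between $\theta_D$ and a potentiation threshold
$\theta_P$ the synapse depresses, and above $\theta_P$ it potentiates. The
fixed point–learning rate (FPLR) formulation makes the asymptotic endpoint
and the speed of approach explicit and independent. Per time step,

$$\Delta w = \eta(Ca)\,\bigl(F(Ca) - w\bigr),$$

where $F$ is a step function of calcium giving the *fixed point* the weight
is relaxing toward and $\eta$ a step function giving the *learning rate* —
the fraction of the remaining distance traversed per step. One step contracts
the distance to the active fixed point by exactly $1-\eta$; under constant
calcium the weight relaxes geometrically, and in continuous time

$$w(t_E) = F(C) + \bigl(w(t_S) - F(C)\bigr)\,e^{-\eta\,(t_E - t_S)},$$

which `closed_form_weight()` evaluates and the discrete integrator matches to
better than $10^{-8}$ relative error. We require $\eta \le 1$ everywhere to
prevent oscillations; $\eta = 1$ makes the weight jump to the fixed point in
a single step, which is convenient for discrete-state synapses and for the
early phase of the late-phase experiment below.

The package also implements the classical rules this formulation
generalizes:

* the linear two-threshold rule $\Delta w = \eta\,\Omega(Ca)$ with signed
  rates $k_D < 0 < k_P$ (`sbc_rule()` with `lambda = 0`), its weight-decay
  variant $\Delta w = \eta(\Omega(Ca) - \lambda w)$ whose per-region fixed
  points are $0$, $k_D/\lambda$, $k_P/\lambda$, and the variant with a
  sigmoidal calcium-dependent learning rate;
* the bistable cubic-drift rule (`gb_rule()`),
  $\tau\Delta w = -w(1-w)(w_\ast - w) - \eta_D w\,\Theta(Ca-\theta_D) +
  \eta_P(1-w)\,\Theta(Ca-\theta_P)$, in which drift, depression and
  potentiation act cumulatively (so $w = 1$ is not a fixed point during
  potentiation), with the stochastic noise term omitted; and
* its simplified variant (`gb_simplified_rule()`) in which exactly one
  process is active for any (calcium, weight) pair.

The two-dimensional rule (`fplr_rule2d()`) lets fixed points and rates depend
on the current weight as well: each calcium region holds either a scalar
$(F, \eta)$ pair or a set of $N$ stable fixed points with $N+1$ basin-of-
attraction boundaries (`basin_spec()`). Each fixed point must lie strictly
inside its basin; since $\eta \le 1$ and targets lie within the basin, a
weight can never jump across a boundary, so basins cannot "leak". A weight
sitting exactly on a boundary (within $10^{-12}$) is treated as an unstable
fixed point; half-stable boundaries can be declared per boundary
(`boundary_mode`).

Protein gating (`protein_gated_rule()`) switches between a 1D rule (no
stabilizing protein: weights drift back to a single baseline) and a 2D rule
(protein present: potentiated and depressed weights are stabilized at
distinct late-phase states) according to a binary protein trace.

## Calcium

Step stimuli (`step_stimulus()`) probe the fixed points directly. Spike-driven
calcium (`spike_calcium()`) jumps by $C_{pre}$ per presynaptic and $C_{post}$
per postsynaptic spike and decays exponentially with $\tau_{Ca}$. Two
numerical choices matter:

* the per-step decay factor is the exact $e^{-dt/\tau_{Ca}}$ rather than the
  Euler $1 - dt/\tau_{Ca}$, removing integration error from dwell-time
  arithmetic; and
* a spike's jump lands undecayed at the sample containing it (the sample at
  the spike holds the full peak), so single-transient peaks and analytic
  threshold-crossing times are exact. Pre and post spikes landing on the same
  sample sum.

`compute_barcode()` assigns every sample to a region (half-open intervals,
lower bound included) and reports depressive/potentiative intervals and
dwell durations — the "bar code" of a protocol. For a transient decaying from
any peak above $\theta_P$, the depressive dwell on the way down is
$\tau_{Ca}\,\ln(\theta_P/\theta_D)$ regardless of the peak ("what goes up
must come down"); the tests assert this against the analytic value to within
two samples.

## Learning-rate units

The printed parameter sets state learning rates alongside a separate
integration step: the frequency and STDP sets use $\eta_D, \eta_P$ of order
$10^{-3}$–$10^{-2}$ with $dt = 0.01$ ms, and the late-phase calibration
states rates "in units of seconds". We therefore read those $\eta$ as
continuous rates (per ms, or per s) integrated by forward Euler, i.e. the
per-step fraction is $\eta_{step} = \eta \cdot dt$; preset files declare
their units (`eta_units`) explicitly. Reading them instead as per-step
fractions at $dt = 0.01$ ms would saturate both processes within ~2 ms of
dwell time and destroy the frequency-dependence of the protocol outcomes
(every stimulus would end at the depressive fixed point), so that reading is
untenable. The conversion used by the closed form,
$\eta_{cont} = -\ln(1-\eta_{step})/dt$, is exact for geometric relaxation and
equals the table rate to first order.

## Canonical protocols

**Frequency-dependent plasticity** (`run_frequency_protocol()`,
`frequency_sweep()`): five presynaptic spikes at a given frequency, calcium
per the frequency preset ($C_{pre} = 1.05$, $\tau_{Ca} = 10$ ms,
$\theta_D = 1$, $\theta_P = 1.3$, $F_D = 0.42$, $F_P = 2.25$), weights by the
1D rule with pre-depressive drift off. Every run extends past the last spike
until calcium has decayed below $\theta_D(1 - 10^{-6})$, so the depressive
tail is part of the result. Low-frequency trains (isolated 1.05-high
transients) each spend $\tau_{Ca}\ln(1.05/1) \approx 0.49$ ms in the
depressive region and produce small net depression; high-frequency trains sum
above $\theta_P$ and potentiate weak synapses, while synapses near $F_P$ are
net-depressed even at high frequency because the potentiation they can still
express is smaller than the decay-tail depression.

**STDP** (`run_stdp_pair()`, `stdp_sweep()`): one pre and one post spike at
interval $\Delta t$ (positive = pre before post), earliest spike at 50 ms,
calcium per the STDP preset ($C_{pre} = 0.9$, $C_{post} = 1.55$,
$\tau_{Ca} = 7$ ms). $C_{pre}$ alone stays below $\theta_D$; $C_{post}$ alone
crosses both thresholds, and the preset's rates balance the potentiation on
the way up against the depression on the way down, so a lone post spike
produces almost no net change — the requirement for the classic curve shape.
Per-pairing changes are small by design (experimentally, dozens of pairings
are needed); `n_pairings` repeats the pairing with full calcium decay in
between.

**Late phase** (`run_late_phase_experiment()`): calcium is held in the
depressive region for 9 s (LTD; the low-frequency protocol's 900 pulses ×
10 ms of calcium) or above $\theta_P$ for 3 s (LTP; 3 × 100 pulses × 10 ms)
with $\eta = 1$ per second, driving the weight to the early fixed point
(0.42 or 2.25 of baseline); then calcium is 0 for 4.5 h (LTD) or 10 h (LTP)
while the weight drifts at 0.0046 per second. Without protein it returns to
baseline (1.0); with protein the 2D rule stabilizes it in the basin it ends
in. The held calcium levels (1.15 and 2.0) only select the region — the
asymptote is the region's fixed point regardless of the level — and the
late-phase basin boundaries, which are not published, are placed at
[0, 0.8, 1.2, 2.5] so that 0.42 falls in the basin of 0.61, baseline in the
basin of 1.0, and 2.25 in the basin of 1.42; the endpoints are insensitive to
the exact boundary positions within those brackets. The drift rate 0.0046 /s
is the published mean of the LTP and LTD estimates and is adopted as given; a
single 1D drift cannot reproduce the slightly different no-protein endpoints
reported for LTD (~92%) and LTP (100%), so the shipped no-protein baseline is
1.0 and only the LTP endpoint is asserted.

## The place-field (BTSP) simulation

`run_btsp_session()` simulates an animal running 10-s laps of a circular
track past a leaky-integrator neuron with $N = 1000$ spatially tuned
synapses. Field centers tile the track every $T/N$ ms; the per-step spike
probability is $P_{max} e^{-(d/r)^2}$ with $d$ the *circular* distance
(wraparound; the printed plain difference is recovered away from the seam).
Spikes are independent Bernoulli draws. Each spike injects charge
proportional to its weight (`syn_scale` = 0.4 pC per unit weight, chosen so
a strongest-weight synapse produces a ~1 mV EPSP, since the model states the
synaptic current in weight units without a conversion constant); the voltage
otherwise leaks to $V_{rest} = -75$ mV with $\tau_V = 15$ ms and is clamped
to $V_{plateau} = -30$ mV exactly during a plateau induction.

Per-synapse calcium is the sum of a local component (jump 0.1 per
own-synapse spike) and a globally broadcast plateau component (rectangular
1.33 step for 300 ms), both decaying with $\tau_{Ca} = 2$ s — the deliberate
simplification of treating cytosolic plus endoplasmic-reticulum calcium as
one seconds-scale trace. Weights follow the 1D rule with drift off
($\theta_D = 1.5$, $\theta_P = 2.15$, $F_D = 0.2$, $F_P = 2.5$,
$\eta_D = 0.0017$, $\eta_P = 0.15$ per ms) and start at $F_D$.

Choices the printed parameters do not fix:

* **Time step.** $dt = 1$ ms, making $P_{max} = 0.02$ a ~20 Hz peak rate,
  consistent with place-cell firing; all model time constants are ≥ 15 ms.
  Note the input rate (and hence the local calcium amplitude) scales with
  the choice of $dt$, since $P_{max}$ is a per-step probability.
* **Ramp detection.** Background input alone holds the mean voltage about
  1.7 mV above rest (sum of tiled Gaussian rates ≈ 1.4 spikes/ms × 0.08 mV ×
  $\tau_V$), so a fixed `V_rest + 0.5 mV` criterion would flag the whole lap.
  `detect_ramps()` instead smooths the voltage (200 ms moving average) and
  detects excursions 0.5 mV above the mean smoothed voltage of a reference
  lap (lap 1, which never has an induction).
* **RNG.** One seed; draws in a fixed (step, synapse) order inside the
  compiled loop. Identical seed and configuration give bit-identical
  sessions.

With the default schedule (inductions at 3.5 s of lap 2, 2 s of lap 4, 7.5 s
of lap 6) the simulation reproduces the qualitative experiment: a place field
forms around 3.5 s, is overwritten by the nearby 2 s induction, and coexists
with the far 7.5 s field; the mirror schedule (6.5 s, 8 s, 2.5 s) mirrors the
outcome. Only synapses previously potentiated above $F_D$ are ever depressed
— synapses sitting at the depressive fixed point cannot go lower, which is
what prevents a Mexican-hat depression ring around each field.

One quantitative caveat: with the printed parameters and $dt = 1$ ms, the
total calcium at the synapse centered on the first induction exceeds
$\theta_P$ for ≈ 0.6 s on average (the deterministic expected-calcium trace
gives 0.53 s), somewhat shorter than the ~1 s read off the published example
run; expected local calcium peaks near 1.07, so the crossing of
$\theta_P = 2.15$ above the 1.33 plateau is marginal and the dwell varies
strongly across seeds. We report the simulated value rather than adjusting
any parameter to lengthen it.

`weight_change_map()` runs a single lap with a mid-track induction and, since
calcium is input-driven and independent of the weights, integrates the rule
over each recorded calcium trace for every initial weight: near-field weak
synapses potentiate, near-field strong synapses depress, far-field weak
synapses barely change, far-field strong synapses depress slightly.

## What the generator does and does not emulate

The synthetic inputs are Bernoulli spikes from static Gaussian tuning curves,
a constant-velocity animal, one plateau per scheduled lap, and noiseless
deterministic plasticity. Real recordings have theta-modulated and bursty
spiking, velocity variation, trial-to-trial tuning drift, stochastic
plasticity, and postsynaptic spiking — none of which are modeled (the neuron
is deliberately subthreshold-only). Passing tests therefore demonstrate the
internal consistency of the rule framework and its qualitative agreement
with the published protocol outcomes, not a fit to physiological recordings.

## Numerical notes and problem sizes

Degenerate inputs are rejected at construction (non-increasing thresholds,
rates outside $[0,1]$, inverted stimulus times, probabilities above 1,
protein values outside $\{0,1\}$); `validate_basins()` returns violations as
data rather than raising, for use in configuration tooling. Basin-boundary
equality uses a $10^{-12}$ tolerance. The test suite integrates the
frequency/STDP protocols at the preset $dt = 0.01$ ms (traces of order
$10^4$–$10^6$ samples), runs full 7-lap, 1000-synapse BTSP sessions in the
compiled loop, and uses 10 sessions for the stochastic dwell-time summary;
the whole suite runs in well under a minute on one core.
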