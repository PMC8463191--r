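---
title: "Methods: a coupled thalamocortical model of absence seizures and its stimulation therapies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coupled thalamocortical model of absence seizures and its stimulation therapies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Absence seizures show a characteristic 2–4 Hz spike-wave discharge (SWD)
on the EEG, generated by pathological interplay between the cerebral
cortex and the thalamus.  `ctmbc` simulates a neural mass model of this
loop: two identical Taylor-type cortico-thalamic circuits ("module I"
and "module II"), each containing four populations — excitatory
pyramidal cells (PY), inhibitory interneurons (IN), the excitatory
specific relay nucleus (SRN) and the inhibitory thalamic reticular
nucleus (TRN) — coupled to one another through a long-range channel, so
that the full state is the vector of eight mean membrane potentials
`(py1, in1, srn1, trn1, py2, in2, srn2, trn2)`.

Within module *i* the dynamics are

$$
\begin{aligned}
\dot{PY_i} &= (\epsilon_{py} - PY_i + h_1 Q[PY_i] - h_2 Q[IN_i] + h_3 Q[SRN_i])\,\tau_1 \\
\dot{IN_i} &= (\epsilon_{in} - IN_i + h_4 Q[PY_i])\,\tau_2 \\
\dot{SRN_i} &= (\epsilon_{srn} - SRN_i + h_5 Q[PY_i] - h_6 K[TRN_i])\,\tau_3 \\
\dot{TRN_i} &= (\epsilon_{trn} - TRN_i + h_7 Q[PY_i] + h_8 K[SRN_i] - h_9 K[TRN_i])\,\tau_4 + \beta_i(t)\,u(t)
\end{aligned}
$$

with the sigmoid activation $Q[x] = 1/(1+\varepsilon^{-x})$
($\varepsilon = 250000$) for cortical and relay outputs and the linear
activation $K[y] = a y + b$ ($a = 2.8$, $b = 0.5$) for thalamic outputs.
$K$ is an affine approximation of the sigmoid in the thalamic operating
range and is deliberately not clipped: clipping it to $[0,1]$ collapses
the whole $(h_7, h_8)$ plane onto a saturated fixed point and destroys
the oscillatory dynamics.

One point deserves emphasis because the notation is easy to misread: the
time-scale coefficients $\tau_{1..4} = (26, 32.5, 2.6, 2.6)$ are
**multiplicative rate constants** (units 1/s), not divisors.  Dividing
by them instead turns the system into a near-integrator that drifts to a
single saturated fixed point everywhere in the parameter plane; with the
multiplicative convention the model produces the 2–4 Hz spike-wave
rhythms it is built to study.

Cross-module (long-range) projections reuse the intra-module coupling
strengths divided by `intermodule_scale` (default 6; 3 selects the
short-range variant) and sit *outside* the $\tau$ factor: PY–PY
($h_1/6$), IN–PY ($h_2/6$) and PY–IN ($h_4/6$) between the cortices,
TRN–SRN ($h_6/6$), SRN–TRN ($h_8/6$) and TRN–TRN ($h_9/6$) between the
thalami.  A `cross_inside_tau` switch multiplies the cross terms by the
same rate constants for sensitivity analysis; it is off by default.

Default parameters: $h_{1..9} = (1.8, 1.5, 1, 4, 3, 0.6, h_7, h_8, 0.2)$,
$\epsilon_{py,in,srn,trn} = (-0.35, -3.4, -2, -5)$.  The two excitatory
pathways onto TRN — $h_7$ (PY→TRN) and $h_8$ (SRN→TRN) — are the free
parameters of all sweeps, over $[1.5, 2.5] \times [9, 11]$.

### Topologies

* `bidirectional` — both modules receive cross input (the full model).
* `unidirectional` — the analysed module I is driven by an autonomous
  module II.  The direction matters: the published comparison gives the
  unidirectional configuration the *larger* SWD area, which is only
  possible when the module whose mean field is analysed is the one
  receiving the cross input.  With the opposite direction module I is
  simply the isolated single-module circuit and its SWD area drops far
  below the bidirectional value, contradicting the comparison the
  topology flag exists to reproduce.
* `uncoupled` — no cross terms; each module is an independent
  single-module (Taylor-type) circuit.  The test suite verifies this
  equivalence against an independently written single-module
  right-hand side.

## Integration protocol

The equations are integrated with a classic fixed-step fourth-order
Runge–Kutta scheme, implemented in C++ for speed (about 60 ms per 30 s
trajectory on one core).  Defaults follow the published protocol:
`dt = 0.25` ms, 30 s per run, the first 10 s discarded as transient,
and ensembles of independent runs whose initial states are drawn
uniformly from $[-1, 1]^8$ (the attractors live at order-1 magnitudes
given the $\epsilon$ inputs; the paper does not state its initial
distribution).  A single seeded RNG block generates all initial states,
so every ensemble is bit-reproducible from `(params, protocol, config,
seed)`.  The stimulation current is evaluated analytically at each RK4
sub-step time rather than held over the step: a 4 ms pulse spans 16
integration steps and sub-step evaluation keeps the pulse edges sharp.

States exceeding an overflow guard (default $10^6$) flag the run as
divergent and truncate it instead of raising an error, so parameter
sweeps survive pathological corners; divergent cells form their own map
category and are excluded from area denominators by default.

## Stimulation protocols

All protocols inject current into the TRN equations only, gated by the
binary pair $\beta_1(t), \beta_2(t)$.

* **DBS** — a periodic rectangular pulse train: amplitude $\alpha$,
  period $\rho = 1/f$, pulse width $\delta$, the pulse occupying
  $[0, \delta)$ of each period.  Defaults $f = 130$ Hz, $\delta = 4$ ms.
  Both TRNs are stimulated simultaneously ($\beta_1 = \beta_2 = 1$).
* **CBBP** — a biphasic waveform: an anodic phase of width $\delta$
  followed by a cathodic phase filling the rest of the period.  Two
  parameterizations are provided.  The charge-balanced form uses
  amplitudes $(\alpha,\; -\alpha\delta/(T-\delta))$ so the net charge
  per period is exactly zero.  The `cbbp_literal` form uses the
  numeric amplitudes $(\delta,\; -\delta/(T-\delta))$, i.e. a
  negligible anodic phase and a cathodic phase of about $-1.08$, which
  carries a net hyperpolarizing DC of about $-0.52$ per period.
* **CRS m:n** — coordinated reset: the DBS pulse train gated by an
  ON–OFF schedule over cycles of length `crs_cycle` (default one
  stimulus period, so each ON cycle delivers one pulse; the cycle length
  is not stated in the source material and is configurable).  Within a
  super-period of $m+n$ cycles the first $m$ are ON and the rest OFF;
  ON cycles alternate their target, TRN1 first.  The gates are mutually
  exclusive by construction.  `crs = c(1, 0)` is perpetual alternation,
  `c(3, 2)` stimulates three cycles and rests two.

### Polarity

The amplitude is signed, and the default is $\alpha = -3$ (cathodic).
This is a deliberate reading: with a *positive* (depolarizing) pulse
train the injected current raises TRN activation — the very mechanism
that generates spike-wave discharge in this model — and the measured
SWD area under "therapy" *grows*: on an 11 × 11 grid with three
repeats per cell, 50.4% at baseline becomes 76.9% under +3 DBS but
5.0% under −3 DBS.  Hyperpolarizing pulses of magnitude 3 suppress
TRN activation, which is the mechanism the therapies are described to
exploit, and reproduce the published suppression maps closely (DBS
about 5% area, CRS 1:0 about 25%, CRS 3:2 about 36% on the 21 × 21
grid).  Users who want the depolarizing convention simply pass a
positive amplitude.

For the therapy comparison the package uses the literal CBBP form: the
charge-balanced variant has zero DC component, and a zero-mean 130 Hz
forcing of the TRN equation averages out almost completely (its ripple
in TRN is about $\alpha/(2\pi f) \approx 0.004$), so it measurably
does not change the SWD area at all.  A biphasic pulse can only act in
this model class through its DC component.  Even the literal form
(DC $\approx -0.52$) suppresses the SWD area only to about 35%, short
of the published 18.8%, which would require a per-target DC near $-1$;
no printed parameterization produces that value.  This residual
discrepancy is documented rather than tuned away.

### Energy metric

`rms_current` implements the standard root-mean-square
$\sqrt{N^{-1}\sum u_k^2}$ over the sampled total gated current (the
printed norm notation is ambiguous about the squaring; the standard RMS
is assumed).  The published energy-expenditure percentages
(40.9–76.8%) cannot be anchored because their normalization baseline is
never defined; the package therefore reports raw RMS per scheme plus a
percentage relative to the maximum-RMS scheme, clearly labelled.

## State classification

Each post-transient mean-field trace $0.5\,(PY_1 + IN_1)$ — the model's
EEG surrogate — is assigned one of four regimes:

1. peak-to-peak amplitude below `amp_tol` (default 0.01) → fixed point;
   the mean level splits **I** (high saturated) from **IV** (low
   firing) at `sat_threshold` (default 0.3).  The model's two
   stationary branches sit near mean-field 0.46 and 0.16, so 0.3 is
   their midpoint; a threshold at 0 would misfile every low-firing
   state as saturated since both branches are positive.
2. otherwise the trace is oscillatory.  The dominant frequency is the
   periodogram peak (mean-removed FFT, single segment, no taper) in
   (0.5, 50] Hz; with the default 20 s window the resolution is
   0.05 Hz.  Local maxima whose prominence exceeds
   `prominence` × (peak-to-peak range) (default 0.15) are counted as
   spikes.  **III** (SWD) requires a dominant frequency inside
   `swd_band` (default 2–4 Hz) *and* at least `min_spikes` = 2 spikes
   per fundamental period (minus a small `spike_tol` absorbing window
   edge effects); everything else oscillatory is **II**.

The prominence threshold is relative rather than absolute: a spike is a
feature of the waveform's shape, not of its absolute scale.  The value
0.15 was fixed once against the published regime assignments along the
$h_7$ axis: at the printed simple-oscillation anchor
$(h_7, h_8) = (2.1, 9.2)$ the cycle carries a secondary bump of 13% of
the range (one spike per period, visually a simple oscillation), while
at the printed SWD anchors the secondary spike prominence exceeds 40%;
0.15 separates these with margin on the II side, keeping the detection
inclusive for borderline spike-wave cycles.  All thresholds are exposed
in `classify_control()` for sensitivity analysis.

Ensembles are combined per cell by majority vote over the per-run
labels, with ties broken toward the more pathological state
(SWD > oscillation > fixed points) because the maps exist to detect
pathology; the dominant frequency reported per cell is the ensemble
median, which resists the occasional outlier run.

## Sweeps and therapy metrics

`bifurcation_scan` collects post-transient prominent extrema of the
mean field per $h_7$ value: one band for a fixed point, two for a
simple oscillation, at least four for a spike-wave cycle.
`sweep_2d` builds the two-parameter state map and its SWD area
fraction, the percentage of non-divergent cells labelled III.
`therapy_comparison` recomputes the map per protocol on identical
grids and seeds and reports per scheme: SWD area, percentage reduction
$100\,(A_0 - A)/A_0$ against the unstimulated baseline, RMS of the
total gated current over the post-transient window, and the
energy-expenditure percentage described above.

### Problem sizes

The default grid is 41 × 41 with 20 repeats per cell.  The bundled
acceptance analyses use 21 × 21 with 3 repeats per cell — about 1,300
thirty-second integrations per map, under a minute on one core with
the compiled integrator — which resolves the regime geometry while
keeping a full six-map comparison within a few minutes.  Sweep
trajectories are thinned to 500 Hz before classification; the rhythms
of interest live at 2–4 Hz and the spectral analysis is unaffected,
while memory traffic drops eightfold.

## What the defaults do and do not reproduce

With the conventions above, the package reproduces: the regime sequence
I → II → III along $h_7$ at $h_8 = 9.2$ and II → III at $h_8 = 10.2$
with the published anchor labels at five of the six printed
$(h_7, h_8)$ anchor points; SWD rhythms in the 2–4 Hz band throughout;
the unidirectional ≥ bidirectional ordering of baseline SWD areas; and
the DBS and CRS therapy maps near their published areas.

Known, documented discrepancies, stated here because no configuration
of the printed model reproduces them in our hands: (i) the published
low-firing (IV) region at strong $h_7, h_8$ — the printed equations
sustain a globally attracting spike-wave cycle there (tested from
initial conditions across $[-5, 5]^8$), and the IV branch only appears
at $h_8 \gtrsim 12$, outside the default plane; correspondingly the
anchor $(2.5, 10.2)$ classifies as III, not IV; (ii) the baseline SWD
areas run some 10 percentage points above the published 42.3%/44%,
consistent with the missing IV corner plus a wide, finely interleaved
II/III transition band; and (iii) the CBBP area, as discussed under
Polarity.  Raising the ensemble to the full 20 repeats per cell moves
the baseline areas by only a few percentage points; the discrepancy is
structural, not sampling noise.

## What the synthetic fixtures do and do not show

`synthetic_traces()` generates analytic waveforms — pure tones, a
spike-wave composite (fundamental plus strong second harmonic),
constants at the two stationary branch levels — with known labels and
frequencies.  They validate the classifier's decision rule in
isolation: band edges, spike counting, fixed-point splitting.  They do
not emulate model output (no transients, no amplitude drift, no
chaotic jitter), so classifier performance on them bounds nothing about
borderline model trajectories; the bifurcation-anchor tests cover
those.

## Numerical choices

* RK4 is fixed-step by design: the published protocol prescribes the
  step, the stimulus has kilohertz-scale edges that adaptive steppers
  chatter on, and bit-reproducibility across runs is a requirement.
  Fourth-order convergence is verified by Richardson ratio in the test
  suite.
* Pulse-edge tie-breaks: sample times landing within a relative
  $10^{-9}$ of a period boundary count as phase 0, and the pulse
  occupies $[0, \delta)$.  On the rational grid
  $dt/\rho = 13/400$ many samples hit edges exactly; without the
  tie-break, floating-point rounding tips them inconsistently and the
  sampled duty cycle (hence the recorded RMS) drifts off the analytic
  value.  The R waveform generators and the C++ integrator share the
  same rule, and a round-trip test asserts bitwise agreement of the
  recorded stimulus traces.
* The steep sigmoid is evaluated in log space with clamping at
  $|kx| > 700$ to avoid overflow; within double precision it saturates
  exactly to 0/1 beyond $|x| \approx 2.8$, which is harmless because
  the states never leave the resolvable range in normal operation.
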