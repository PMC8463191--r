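# ctmbc

Simulation and analysis of a **coupled thalamocortical model with a
bidirectional channel** — a two-module, eight-population neural mass
model of absence seizures — together with the four reticular-nucleus
stimulation therapies studied on it.

## Who this is for

Computational neuroscientists studying spike-wave discharge (SWD)
generation and its control by electrical stimulation.  Absence
seizures show a 2–4 Hz spike-and-wave EEG rhythm produced by the
cortico-thalamic loop.  This package couples two Taylor-type
cortico-thalamic circuits — pyramidal (PY), interneuron (IN), specific
relay nucleus (SRN) and thalamic reticular nucleus (TRN) populations
per module — through a long-range channel and asks two questions: for
which coupling strengths does the loop generate SWD, and how well do
different stimulation protocols suppress it?

## The model

Each module follows

```
dPY/dt  = (eps_py  - PY  + h1 Q[PY] - h2 Q[IN] + h3 Q[SRN]) tau1  (+ cross terms)
dIN/dt  = (eps_in  - IN  + h4 Q[PY]) tau2                         (+ cross terms)
dSRN/dt = (eps_srn - SRN + h5 Q[PY] - h6 K[TRN]) tau3             (+ cross terms)
dTRN/dt = (eps_trn - TRN + h7 Q[PY] + h8 K[SRN] - h9 K[TRN]) tau4 (+ cross terms)
                                                                  + beta(t) u(t)
```

with sigmoid activation `Q[x] = 1/(1 + 250000^(-x))`, linear thalamic
activation `K[y] = 2.8 y + 0.5`, rate constants
`tau = (26, 32.5, 2.6, 2.6)`, and cross-module projections at strength
`h/6`.  The two excitatory pathways onto TRN — `h7` (PY→TRN) and `h8`
(SRN→TRN) — are swept over `[1.5, 2.5] x [9, 11]`; each
post-transient mean-field trace `0.5 (PY1 + IN1)` is classified as
high saturated (I), simple oscillation (II), 2–4 Hz spike-wave
discharge (III) or low firing (IV).  Stimulation (`u(t)`, gated per
target by `beta1/beta2`) enters the TRN equations only: deep brain
stimulation (DBS), charge-balanced biphasic pulses (CBBP), and
coordinated reset (CRS) in 1:0 and 3:2 ON–OFF schedules.  See the
methods vignette (`vignettes/ctmbc-methods.Rmd`) for conventions,
thresholds and their rationale.

## Worked example

```r
library(ctmbc)

# a spike-wave cell of the (h7, h8) plane
p   <- ctmbc_params(h7 = 2.5, h8 = 9.2)
sim <- ctmbc_simulate(p, config = sim_config(seed = 1, record_every = 8L))
summary(sim)
#> state III, dominant frequency 2.45 Hz, mean level 0.356
#>   (h7 = 2.5, h8 = 9.2, protocol none)

# cathodic 130 Hz DBS pulses suppress the discharge
dbs <- stim_protocol("dbs", amplitude = -3)
summary(ctmbc_simulate(p, dbs, sim_config(seed = 1, record_every = 8L)))
#> state II, dominant frequency 2.40 Hz, mean level 0.398
#>   (h7 = 2.5, h8 = 9.2, protocol dbs)
```

The first run sits on the spike-wave attractor: a 2.45 Hz rhythm whose
cycles carry two prominent maxima (spike plus wave), hence label III.
Under hyperpolarizing DBS the same cell relaxes to a simple oscillation
(label II): the pulse train suppresses TRN activation, releasing the
relay nucleus and breaking the discharge.

A small therapy comparison (coarser grid than the published one, for
speed):

```r
tab <- therapy_comparison(
  ctmbc_params(),
  protocols = list(dbs  = stim_protocol("dbs",  amplitude = -3),
                   crs10 = stim_protocol("crs", amplitude = -3, crs = c(1, 0))),
  h7 = seq(1.5, 2.5, length.out = 11),
  h8 = seq(9, 11, length.out = 11),
  config = sim_config(n_repeats = 3, seed = 1, record_every = 8L))
tab
```

Each row reports the SWD area (percentage of grid cells in state III),
the percentage reduction against the unstimulated baseline, the RMS of
the injected current, and the energy expenditure relative to the
most current-hungry scheme.

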