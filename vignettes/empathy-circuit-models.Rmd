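---
title: "Spiking circuit models of personal distress, empathic concern and compassion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking circuit models of personal distress, empathic concern and compassion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`empathynet` simulates two spiking neural-circuit models of empathically
motivated caregiving. The first distinguishes three network states —
*personal distress*, *weak empathic concern* and *strong empathic concern*
— in a limbic circuit built from the basolateral/basomedial amygdala (a
negatively valent group BLMA−, a positively valent group BLMA+, and a pool
of inhibitory interneurons BLMAi), the anterior and posterior insula (AI,
PI), the anterior midcingulate cortex (aMCC), the medial prefrontal cortex
(mPFC), and a disinhibitory caregiving pathway mPOA → VTA → NAc → VP
(medial preoptic area, ventral tegmental area, nucleus accumbens, ventral
pallidum). Dopaminergic VTA activity inhibits NAc, which releases VP from
tonic inhibition so that amygdalar (BLMA+) excitation can drive it:
caregiving output is read from the VP firing rate. The second model adds
the medial orbitofrontal cortex (mOFC) with excitatory projections to AI,
BLMAi and BLMA+, and is used to represent the progression of
self-attachment therapy toward a *compassion* state in which mOFC-driven
BLMAi activity suppresses the negatively valent amygdala.

Neurons are two-variable Izhikevich point neurons,

$$v' = 0.04 v^2 + 5v + 140 - u + I, \qquad u' = a(bv - u),$$

with a spike emitted when $v \ge 30$ mV, followed by the reset
$v \leftarrow c$, $u \leftarrow u + d$. The canonical presets are used:
regular spiking (RS; most excitatory populations, NAc), fast spiking (FS;
interneurons, BLMAi and the whole VP), and intrinsically bursting (IB; the
dopaminergic VTA). Synapses are current-based with fixed weights: a spike
at time $t$ adds its signed weight to the target's input current at
$t + \delta$, where $\delta$ is the synapse's integer conduction delay.

## The injection protocol

A run lasts 30,000 iterations on a 1-ms grid, split into three phases of
$p = 10{,}000$ ms. Stimulation is parameterized by three proportions,
$L = 0.05$, $M = 0.1$, $H = 0.15$. For each stimulated region $G$ a
designated subset $g(G)$ with $|g(G)| = \lfloor |G| H \rfloor$ is drawn
(uniformly for BLMA−, AI, PI, aMCC and mOFC). At every step, 10% of each
designated set is swapped against neurons outside it, and an injected
subset $c_t(G) \subseteq g_t(G)$ receives a 90-unit-amplitude pulse. Fixed
band rules draw $|c_t(G)|$ as a uniform integer in
$[\lfloor |G|\,\ell_1 \rfloor, \lfloor |G|\,\ell_2 \rfloor]$; ramp rules
use the linear count formulas whose endpoints meet the band levels exactly
at the phase boundaries (see `?ramp_count`). BLMA− is stimulated in the
$(M, H)$ band at every step of every phase.

mPFC is special: its injections target either the *close-other* or the
*distant-other* subpopulation along a ventral–dorsal axis. Both are
realized by truncated negative-binomial draws over the excitatory mPFC
index axis (close: $r = 7$, $p = 0.0025$; distant: $r = 14$, $p = 0.035$;
draws outside the axis are rejected and resampled, never clamped, so no
mass piles up at the boundary). With the packaged orientation the highest
index is the ventral end, so close-other draws land ventrally, and the
mPFC → mPOA and mPFC → BLMA+ projections sample their *sources* from the
same close-other distribution. This is what makes close-other stimulation
engage the caregiving pathways much more strongly than distant-other
stimulation: close-mode injections and caregiving projection sources
occupy the same ventral band. The designated sets for the two modes are
themselves drawn from the corresponding truncated negative-binomial
distributions (the uniform-\(g\) variant is available through the same
machinery), and perturbation swap-ins are drawn from the same
distribution, so the gradient is preserved over time.

## What is calibrated, and why

The original work specifies the architecture, the neuron classes, the
protocol constants and the target firing rates, but its per-edge
connection probabilities, weights and population sizes live in a
supplement that is not part of the available text. The packaged parameter
set is therefore a *calibrated stand-in*: population sizes of 200
excitatory / 50 inhibitory neurons per region (BLMAi 100, NAc and VP 200,
VTA 100, mPFC 1000/250), an intragroup E→I/I→E/I→I motif in every
mixed region, and projection weights found by bounded random search plus
coordinate refinement against the packaged reference table of mean firing
rates (`reference_mfr()`), using the package's own `calibrate()`
machinery. mPFC is larger than the other regions because the two printed
negative-binomial parameterizations only separate into distinct ventral
and dorsal bands when the index axis is on the order of a thousand
neurons; with a 200-neuron axis both truncated distributions collapse onto
nearly the same band and the close/distant distinction disappears.

Three further choices are part of the calibrated set and deserve
explanation:

* **Current gain.** Injection amplitude is specified as "90" in the
  original simulator's units. Those units are not the textbook Izhikevich
  current units: an RS cell driven by a sustained 90-unit textbook current
  fires at ~190 Hz, and since the protocol keeps ~83% of each designated
  subset injected at every millisecond, *every* weight configuration
  would leave the injected populations far above the reported ~1 Hz
  excitatory rates. The unit mapping is therefore treated as one more
  non-identifiable constant of the unavailable parameter tables: injected
  pulses are scaled by a single calibrated `current_gain` (packaged value
  0.035 simulator units per protocol unit). Near this value a pulse is
  just below rheobase, so firing requires temporal summation across
  consecutive selected steps; this both reproduces the ~1 Hz scale and
  produces the strong super-linear contrast between the $(M,H)$ and
  $(L,M)$ bands that the reported rates show.
* **Distributed delays.** With delta synapses and a uniform 1-step delay
  the E–I loops lock into network-wide synchronous volleys (whole regions
  firing in lockstep at up to the grid rate), a well-known pathology of
  pulse-coupled oscillators with identical delays. Packaged configs draw
  each synapse's delay uniformly from 1–10 ms, which spreads volleys into
  an asynchronous barrage. The one-step contract remains the default of
  `projection()` and of the R-level `accumulate_synaptic_input()`.
* **Membrane floor.** Current-based synapses have no reversal potential,
  so strong inhibitory volleys can push $v$ arbitrarily negative, where
  the 0.5-ms Euler half-steps of the quadratic model become unstable and
  produce artifact spikes, and where the model generates spurious
  post-inhibitory rebound. Integration therefore clamps $v \ge -80$ mV
  (the GABA-A reversal). Per-neuron heterogeneity (the canonical
  published randomization of $(c, d)$ for excitatory and $(a, b)$ for
  fast-spiking cells) is enabled in the packaged configs to help
  desynchronize the network; the named presets themselves are immutable.

Current injections target the excitatory (principal) subpopulations.
Fast-spiking interneurons receiving direct suprathreshold pulse trains
would fire far above every reported inhibitory rate; the reported
inhibitory rates (roughly 2–12 Hz) are consistent with locally driven
interneurons, which is how the model produces them.

## Reporting and classification

`rate_summary()` reports mean firing rates per (region, subpopulation)
over a trailing window ending at each report time (default 10, 20, 30 s —
the phase ends). The window length is 1000 ms by default: the original
results quote point-in-time rates without defining a window, and 1 s
matches their reporting granularity while smoothing burst structure.

`classify_states()` labels each phase from its end-of-phase rates with
configurable thresholds: caregiving output is *silent* below 0.5 Hz in VP
and *high* at or above 2 Hz; *compassion* additionally requires an active
mOFC (≥ 1 Hz excitatory) and a negatively valent amygdala suppressed
below 70% of its phase-1 rate. With the packaged calibration the empathy
model's phases label as personal distress / weak empathic concern /
strong empathic concern, and the self-attachment model's as personal
distress / strong empathic concern / compassion.

## Reproducibility and numerics

Every run is driven by one master seed from which three named sub-streams
are derived (connectivity realization, target designation, per-step
perturbation and selection), so resampling the circuit never shifts the
protocol draws. The per-step protocol runs inside the compiled engine
with its own generator seeded from the selection stream; the exported R
operations implement the identical algorithms and the engine's logged
per-step injection counts are held to the R-side band and ramp rules
exactly in the test suite. Fractional counts are floored (band bounds,
designated-set sizes, ramp counts); ramp time is absolute simulation time,
the only reading under which the printed formulas' endpoints equal the
band levels; counts are clipped to the designated-set size.

Degenerate inputs are rejected rather than repaired: probabilities outside
$[0,1]$, bands wider than the designated set, negative-binomial $p \ge 1$,
schedules naming regions absent from the circuit, and non-finite neuron
state all raise errors naming the offending entry.

## What the tests do and do not show

The test suite verifies the protocol algebra exactly, holds the engine to
an R-level recomposition of the public operations on a deterministic toy
circuit, and checks the calibrated models against the packaged reference
table at the tolerance max(0.3 Hz, 25%) for the headline entries, plus
seed-robust ordinal relations (VP increasing across phases, AI/PI higher
under self-pain than other-pain input, BLMA− non-increasing under the
self-attachment protocol, aMCC stability). Unit and property tests use
reduced problem sizes (toy circuits of tens of neurons, runs of a few
hundred steps); the acceptance layer uses full-length 30-s runs of the
full circuits averaged over 5 seeds (10 seeds for the ordinal checks).
Calibration self-recovery is demonstrated at reduced scale (one free
weight, small budget) rather than at the scale used to produce the
packaged set.

Passing these tests shows that the implementation realizes the stated
protocol and architecture and that the calibrated stand-in reproduces the
reported rate table within tolerance on the entries it can reach. It does
not validate the biological claims, and a handful of reported entries are
structurally out of reach of any parameter set under this architecture —
most notably the phase-2 inhibitory rates of PI (reported ~2 Hz with
excitatory PI at 0.06 Hz, although nothing in the published edge set
drives PI), the phase-3 rebound of PI, and exact equality of mPFC rates
between close- and distant-other stimulation at the same band, which the
ventral concentration of the close-other distribution precludes. These
entries are reported faithfully by `compare_to_reference()` and discussed
here rather than hidden.

## Known limitations

Conductance-based synapses, synaptic plasticity and neuromodulator
dynamics are out of scope (they are explicitly future work for the
modeled system). The AI↔NAc and mPFC↔NAc connections whose nature the
source literature leaves open are not modeled. PI participates only as an
injection target (an optional PI→AI projection ships disabled). Run-time
variance across seeds is real and quantifiable (`run_cli --replicates`);
single-seed rates for sparse populations can differ from the 5-seed means
by several tenths of a hertz.
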