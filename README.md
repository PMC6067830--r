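# empathynet

Spiking neural-circuit models of empathically motivated caregiving.

`empathynet` simulates, in Izhikevich point-neuron networks, how the brain
may move between **personal distress** (self-focused pain with no
caregiving drive), **weak** and **strong empathic concern** (other-focused
pain with increasing caregiving drive), and **compassion** (positively
valenced caregiving). Two circuits are packaged:

* an *empathy-states* model — the valence-split amygdala (BLMA−, BLMA+,
  inhibitory BLMAi), the empathy-for-pain core (AI, PI, aMCC), a medial
  prefrontal cortex carrying a ventral–dorsal self–other gradient, and the
  disinhibitory caregiving pathway mPOA → VTA → NAc → VP whose ventral
  pallidum output stands for caregiving behavior;
* a *self-attachment* extension that adds the medial orbitofrontal cortex
  (mOFC → AI, mOFC → BLMAi, mOFC → BLMA+), modeling how reward
  associations learned in therapy can shift the network from empathic
  concern into compassion, suppressing the negatively valent amygdala.

Neurons follow the two-variable Izhikevich model
(`v' = 0.04v² + 5v + 140 − u + I`, `u' = a(bv − u)`, spike-and-reset at
30 mV) with the canonical regular-spiking, fast-spiking and intrinsically
bursting presets; synapses are current-based with fixed signed weights and
distributed integer conduction delays. The experiment is a 30-s run at a
1-ms grid in three 10-s phases. Each phase stimulates region-specific
random subsets: a designated pool `g(G)` holding ⌊0.15·|G|⌋ neurons is
perturbed by 10% every millisecond, and a per-step subset `c_t(G)` drawn
from a low/medium/high band (L = 0.05, M = 0.1, H = 0.15 of |G|) — or from
a linear ramp between bands — receives a 90-unit pulse. mPFC injections
target *close-other* or *distant-other* subpopulations drawn from
truncated negative-binomial distributions over the ventral–dorsal axis
(close: r = 7, p = 0.0025; distant: r = 14, p = 0.035), the same
distribution from which the mPFC → mPOA and mPFC → BLMA+ projections
sample their sources. Windowed mean firing rates (MFR) at the phase ends
are the model's readout, and a rule-based classifier labels each phase's
network state.

Connection weights ship as a calibrated parameter set produced by the
package's own `calibrate()` search against the packaged table of reported
firing rates; see the methods vignette
(`vignettes/empathy-circuit-models.Rmd`) for what is calibrated and why.

## Worked example

```r
library(empathynet)

res <- run_model("self_attachment", seed = 1)
res
#> Simulation of 'self_attachment' model: 30000 ms, 3600 neurons, 358503 spikes (seed 1)
summary(res)          # spikes per phase + full MFR table
classify_states(rate_summary(res))
#> Network-state labels:
#>   phase 1: personal_distress        [VP=0.00; BLMA_neg=1.04; mOFC=0.01; VP < 0.5 (silent caregiving output)]
#>   phase 2: strong_empathic_concern  [VP=2.96; BLMA_neg=0.98; mOFC=0.01; VP >= 2]
#>   phase 3: compassion               [VP=3.98; BLMA_neg=0.69; mOFC=1.52; VP >= 2, mOFC >= 1, BLMA_neg <= 0.7 * phase-1]
```

A silent ventral pallidum with an active self-pain network is personal
distress; VP output at or above 2 Hz is strong empathic concern; and the
compassion label additionally requires an active mOFC with the negatively
valent amygdala suppressed below 70% of its phase-1 rate. Compare a
seed-averaged summary against the packaged reference table with

```r
sums <- lapply(1:5, function(s) rate_summary(run_model("empathy", seed = s)))
compare_to_reference(average_rate_summaries(sums), reference_mfr("empathy"))
```

A shell entry point with the same machinery is available via
`run_cli()` / `inst/scripts/run_model.R`:

```sh
Rscript inst/scripts/run_model.R --model empathy --seed 1 --out out/
```

writing a spike table, an MFR table and a run manifest.

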