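# blafear

A biophysically detailed model of fear learning in the basolateral amygdala
(BLA), for computational neuroscientists studying how interneuron-generated
rhythms gate synaptic plasticity.

During fear conditioning a neutral stimulus (CS) becomes associated with an
aversive one (US). The model implements the circuit hypothesis that three
interneuron classes make this association possible by timing the activity of
two excitatory projection neurons:

* **VIP** cells burst at low theta (~3-4 Hz) through a D-type potassium
  current, opening periodic disinhibition windows;
* **SOM** cells pace at high theta (~12 Hz) through H- and persistent-sodium
  currents;
* **PV** cells form a pyramidal-interneuron network gamma (PING) with the
  fear-encoding cell F, biasing the CS-encoding cell ECS to fire a few
  milliseconds before F.

The ECS→F synapse evolves under a depression-dominated spike-timing-dependent
plasticity rule with potentiation/depression traces P and M
(`A± = 0.005`, `τ+ = 14 ms < τ− = 28 ms`, conductance clipped to
`[0, 0.18] mS/cm²`). Because `A+τ+ < A−τ−`, uncorrelated firing depresses
(expected drift `r_pre·r_post(A+τ+ − A−τ−) < 0`); only gamma-timed
pre-before-post pairs *plus* low-theta pauses (during which M decays) yield
net potentiation — which is why removing any interneuron class abolishes
learning. A realization is a *learner* when the pathway conductance exceeds
0.12 mS/cm² after the 40 s conditioning interval. After learning, the
newly-driven F→PV AMPA currents are paced at low theta, which raises the
low-theta peak of an LFP proxy (the summed AMPA, GABA, D-, H- and
NaP-currents) — a spectral biomarker of successful conditioning.

Cells are single-compartment Hodgkin-Huxley models integrated with RK4 at
dt = 0.05 ms (C++ core); CS/US arrive as 800 events/s Poisson trains through
auxiliary relay neurons calibrated to drive their targets at ~50 Hz.

## Worked example

```r
library(blafear)

# natural rhythms of the isolated cells
natural_frequency_scan("VIP", duration = 30000, seed = 1)
#>   seed  rate_hz intra_burst_hz burst_rate_hz burst_peak_hz
#> 1    1 7.107143       39.43909      3.620296      3.540039
natural_frequency_scan("SOM", duration = 10000, seed = 1)$rate_hz
#> [1] 12.125
natural_frequency_scan("F", duration = 10000, seed = 1)$rate_hz
#> [1] 11.125

# one-trial fear conditioning: 40 s of paired CS and US effects
sim <- simulate_network(network_config(), "conditioning", seed = 1)
classify_learner(sim)
#>   g_15s     g_end learner threshold
#> 1  0.18 0.1754708    TRUE      0.12

# remove any interneuron class and learning fails
run_ablation("noVIP", n_realizations = 2, seed = 11)$learners$g_end
#> [1] 4.848937e-05 8.783135e-05
```

The VIP cell fires ~39 Hz gamma bursts recurring at ~3.5 Hz; SOM paces at
~12 Hz; the F-type projection neuron at ~11 Hz. With all interneurons
present the ECS→F conductance crosses the 0.12 mS/cm² learner criterion
within 40 s; without VIP it stays at zero.

A thin CLI over the same functions ships in `inst/cli/blafear`
(subcommands `simulate`, `scan-frequencies`, `condition`, `ablate`,
`biomarker`).

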