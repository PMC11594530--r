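---
title: "A biophysical BLA circuit model of fear learning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A biophysical BLA circuit model of fear learning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(blafear)
```

This vignette documents the model implemented by **blafear**, the choices we
made where the design was genuinely open, and what the shipped tests do and
do not establish. Nothing here states an empirical result that the test
suite and the acceptance script do not themselves compute.

## The circuit and its cell types

The basolateral amygdala (BLA) is the principal site of fear conditioning:
a neutral conditioned stimulus (CS) paired with an aversive unconditioned
stimulus (US) comes to drive a fear response on its own. The model treats
this as a small conductance-based network with four Hodgkin-Huxley cell
types, each defined by its intrinsic currents:

* **VIP interneurons** carry, besides fast Na/K/leak currents, a
  fast-activating slowly-inactivating potassium **D-current**
  (`g_D a^3 b (V - E_K)`, `tau_a = 2` ms, `tau_b = 150` ms). At the baseline
  drive of 4 uA/cm^2 this produces short gamma bursts (intra-burst ~38-42 Hz)
  recurring at low theta (~3-3.5 Hz): the slow inactivation gate `b`
  terminates each burst and its slow recovery sets the long inter-burst
  interval. The fast potassium current of this cell type carries two
  activation gates (`n^2`), as in its source description.
* **SOM interneurons** carry an H-current
  (`g_H (0.65 h_f + 0.35 h_s)(V - E_H)`) and a persistent sodium current
  (`g_P p (V - E_Na)`), the pairing known from hippocampal O-LM cells. They
  pace at ~12 Hz (upper high-theta) at a baseline drive of 0.1 uA/cm^2.
* **PV interneurons** are fast-spiking cells with Na/K/leak only. They are
  silent without input and, coupled reciprocally with an excitatory
  projection cell, generate pyramidal-interneuron network gamma (PING);
  their GABAa decay constant (8.3 ms) sets the gamma period together with
  the excitation level.
* **Excitatory projection neurons (E)** implement the CS-encoding cells
  (ECS), the fear-encoding cells (F) and the auxiliary stimulus relays. The
  sodium activation is instantaneous (`m = m_inf(V)`), as for VIP.

All membrane equations use `c_m = 1` uF/cm^2, so with mV/ms/uA-per-cm^2
units the voltage derivative equals the current sum; the capacitance is a
convention, not a fitted value.

Two transcription notes on the printed kinetics, both resolved against the
cited source models and validated against the cells' stated natural
frequencies: the SOM H-current time constants and `h_s` steady state use the
standard O-LM forms (`tau_hf = 0.51/(exp((V-1.7)/10)+exp(-(V+340)/52))+1`,
`tau_hs = 5.6/(exp((V-1.7)/14)+exp(-(V+260)/43))+1`,
`h_s_inf = [1/(1+exp((V+2.83)/15.9))]^58`), and the E-cell `h`/`n` kinetics
carry the source model's temperature factor `phi = 5` (it scales the
opening and closing rates together, leaving steady states untouched).
Without `phi` the isolated F cell fires ~18 Hz at its baseline drive instead
of its ~11 Hz natural frequency; with it, 11 Hz. The E-cell choice is
therefore anchored on the F-cell frequency, which the acceptance script
measures.

## Synapses and connectivity

All synapses are single-exponential conductances whose gate obeys
`ds/dt = R(V_pre)(1 - s) - s/tau`, with the open-rate `R` specific to the
presynaptic type: `2(1+tanh(V/4))` for VIP, `7.5(1+tanh(V/0.1))` for PV,
`2.5(1+tanh(V/0.1))` for SOM (GABAa, reversal -80 mV, decay 10/8.3/20 ms
respectively) and `5(1+tanh(V/4))` for AMPA (reversal 0 mV, decay 2 ms).

The circuit has nine projections: VIP->PV, VIP->SOM, PV->F, PV->ECS,
SOM->F, SOM->ECS (inhibitory), and ECS->F, F->PV, F->VIP (excitatory).
VIP disinhibits the projection cells by silencing SOM and PV; PV and F form
the PING pair; feedback inhibition PV->F (0.5) is stronger than lateral
inhibition PV->ECS (0.4), which biases ECS to fire just before F — the
timing that the plasticity rule rewards. Inhibitory conductances divide by
a population count exactly as printed; the printed VIP->SOM scaling uses
the postsynaptic SOM count, which is asymmetric with VIP->PV (presynaptic
count). We implement the printed form as the default and expose
`network_config(scale_by = "pre")` for the symmetric reading, since the two
coincide in every configuration where the counts are equal.

**Multi-cell scaling.** For the heterogeneous network (3 cells per
interneuron type, 10 per projection type, of which 5 ECS receive CS and 5 F
receive US) the printed per-projection values are stated only for the
single-cell circuit. We scale each excitatory per-synapse conductance — and
the plastic ceiling — by the number of stimulus-receiving presynaptic
cells, so every target receives the same total drive as in the single-cell
circuit, and we report the *pathway* conductance (summed plastic input per
F cell) wherever the single-cell model reports its one synapse. Without
this, PV cells receive several times the calibrated excitation, fire far
above the PING regime, and the timing needed for potentiation collapses;
the verbatim per-synapse values remain available via
`network_config(scale_excitatory = "printed")`.
Heterogeneity itself enters as a multiplicative uniform jitter (±5%) on
each cell's background current plus independent noise and initial states.

## Plasticity

The ECS->F synapse follows a trace-based STDP rule that integrates over the
whole spike history. A potentiation trace P (incremented by `A+ = 0.005` at
each ECS spike) and a depression trace M (decremented by `A- = 0.005` at
each F spike) decay with `tau+ = 14` ms and `tau- = 28` ms. At each ECS
spike the conductance is weakened by the current M (floored at 0); at each
F spike it is strengthened by the current P (capped at
`g_max = 0.18 mS/cm^2`). With equal amplitudes and `tau+ < tau-` the rule
is depression-dominated: under uncorrelated steady firing the expected
drift is `r_pre r_post (A+ tau+ - A- tau-) < 0`, so potentiation requires
both fine pre-before-post timing (provided by PING) and pauses during which
the accumulated depression decays (provided by the VIP/SOM low-theta
cycle). Event ordering within one integration step is: decay both traces to
the step, apply the conductance update using the traces *excluding* the
current spike's own increment, then increment the trace; simultaneous pre
and post spikes process the pre update first. A spike therefore never
potentiates or depresses through its own trace. The update is applied
clock-synchronously at detected spikes and matches an exact event-driven
computation to better than 1e-9 when spikes lie on grid points (tested).

The F->VIP synapses can optionally be made plastic with `A+ = 0.00065`,
`A- = 0.0003` (ceiling 0.04); with `A+ tau+ > A- tau-` that variant is not
depression-dominated.

## Stimuli

CS and US are each a homogeneous Poisson event stream (`lambda = 800`
events/s) driving one auxiliary excitatory relay neuron; the CS relay
projects to the CS-receiving ECS cells and all PV cells, the US relay to
the US-receiving F cells (a variant routes the US relay to PV instead).
Relay-to-target AMPA conductance is the printed 0.2 mS/cm^2. The coupling
of the raw Poisson events to the relay is not specified beyond the
requirement that targets fire at ~50 Hz in isolation; we model each event
as a 1 ms excursion of a virtual presynaptic unit to 0 mV, passed through
the standard AMPA gate with drive conductance `g_drive`. `g_drive = 0.03`
was calibrated once so isolated relay-driven ECS/PV fire ~51 Hz, then
frozen; it is the only fitted constant in the stimulus pathway. The US also
raises the VIP background current from 4 to 5 uA/cm^2 and the targeted F
cells' from 0.35 to 0.5 uA/cm^2.

Paradigm presets: `paired_2s` (2 s of CS with the US effects in the second half), `conditioning`
(CS+US effects on continuously; 40 s default, the one-trial acquisition
interval, reflecting the sustained activity attributed to neuromodulator
release), `conditioning15_30` (15 s CS+US then 30 s CS alone), `baseline`
and `cs_only` probes.

## Integration and noise

The coupled system is integrated with classical RK4 at `dt = 0.05` ms.
Noise is a zero-mean unit-variance Gaussian current with a per-cell-type
amplitude (`k = 5` for VIP, `4` for the rest, times a power of the step),
redrawn every step and held constant across the four RK4 stages (the
source text does not state intra-step treatment; holding it constant keeps
the integrator classical). The stated amplitude's units are ambiguous; we
default to the dt-invariant Euler-Maruyama scaling `k sqrt(dt)`, under
which the VIP burst statistics land on their stated values (intra-burst
39.4 Hz vs ~38; burst-rate spectral peak 3.54 Hz vs ~3.5) and noise plays
the realization-differentiating role attributed to it; the literal
per-step amplitude `k dt` remains available as
`noise_scaling = "printed"` (VIP anchors 42.2 Hz / 3.08 Hz). Gates are clamped to [0, 1] after each step; spike
detection uses upward 0 mV crossings with a 2 ms refractory, far below any
inter-spike interval the model produces. Initial voltages are uniform on
[-70, -60] mV with gates at steady state, per realization. The first
2000 ms of every run are flagged transient and excluded from all spectral
analysis. Simulations are bit-for-bit reproducible given (configuration,
seed).

For the test suite and acceptance script we use problem sizes that keep a
full run on one CPU in seconds to a few minutes: 10-30 s isolated-cell
scans, 40 s conditioning runs, five realizations per ablation variant, and
five learners plus five harvested non-learners for the spectral biomarker
(the study-scale experiment uses 20-40 realizations; the drivers expose
`n_realizations` so the full sizes are one argument away).

## LFP proxy and spectra

Because the model has no spatial extension, the LFP is a proxy: the linear
sum of the AMPA and GABA currents of the nine internal projections plus the
D-, H- and NaP-currents of the interneurons (the stimulus relay synapses
are excluded; the network's AMPA component is generated by ECS->F, F->VIP
and F->PV). All currents enter the sum in the outward-positive convention;
a rectified variant sums absolute values instead, accumulated per current
before summation. Components can be extracted separately (AMPA-only,
GABA-only, intrinsic-only) for decomposition analyses. Current traces are
accumulated at every integration step and boxcar-averaged to 1 kHz before
spectral analysis — all bands of interest lie below 70 Hz.

Spectra use Thomson's multitaper estimator with discrete prolate spheroidal
tapers computed from the tridiagonal Slepian eigenproblem (Sturm bisection
plus inverse iteration; no installed package provides them) and adaptive
eigenspectrum weighting; the default time-half-bandwidth `NW = 4` with
`2 NW - 1 = 7` tapers follows the reference implementation's default and is
config-exposed. Band powers are trapezoidal integrals with interpolated
band edges, so adjacent bands partition exactly; band-peak locations are
also reported since "power at the peak" and "band-integrated power" are
both in use. Percentile summaries use the linear-interpolation convention
of `stats::quantile(type = 7)`.

Learner classification follows the printed thresholds on the ECS->F
pathway conductance: above 0.12 mS/cm^2 at the end of the 40 s paradigm, or
above 0.037 mS/cm^2 at 15 s for the split paradigm. For the spectral
biomarker, "pre" is a baseline run (no CS/US). For "post" two readings are
implemented: the default analyses the final 10 s window of the trained
dynamics themselves (conditioning drive still on) — chosen because the
non-learner group is defined directly from 10 s conditioning runs, so both
groups are then treated identically — and `post_probe = "cs_only"`
instead runs a separate CS-alone probe seeded with the learned
conductances (plasticity stays active either way). In this implementation
the learned low-theta power increase expresses strongly under the default
reading (the potentiated ECS->F pathway paces F, whose AMPA output onto PV
is low-theta locked) and only in the AMPA component under the CS-alone
probe, where the fear cells' CS-evoked firing is weaker than the study
reports. Non-learners are harvested the way the study protocol describes:
repeated 10 s conditioning runs (up to 60), keeping realizations whose
pathway conductance stays below 0.037 mS/cm^2. Group comparisons use the
two-sided Wilcoxon rank-sum test (exact for small tie-free samples).

## What the synthetic experiments do and do not show

The generator reproduces the study's *conditions* — cell counts, printed
conductances and drives, stimulus statistics, noise recipe — not real BLA
data. Passing tests therefore show that the implemented equations produce
the claimed emergent behaviour (cell-type rhythms, PING, learning and its
interneuron dependence, the low-theta biomarker) under those conditions;
they say nothing about how well the equations describe a real amygdala,
about pip-structured auditory input (deliberately replaced by stationary
Poisson drive), or about neuromodulator dynamics (folded into the
phase-scheduled applied currents). Known limitations we have measured: a
minority of heterogeneous-network realizations fail the learner criterion
at 40 s (VIP cells, which share no synapses with one another, can
desynchronize and blur the disinhibition windows), and the unresponsive
ECS cells sit above their stated ~11 Hz natural rate because their printed
background current is anchored elsewhere (see the E-cell `phi` note above).
Both are surfaced by the experiment drivers rather than hidden: learner
flags condition every downstream comparison.
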