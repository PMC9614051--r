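---
title: "neuroclock: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{neuroclock: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model in one page

A recurrent network of `N_E` excitatory (E) and `N_I` inhibitory (I)
spiking neurons is divided into `N_C` equal clusters of E neurons.  Driven
for one hour of biological time with *sequential* external input — each
cluster excited in turn for 9 ms at 22.5k spk/s, inhibited at 4.5k spk/s
otherwise, with 6 ms gaps — and for a second hour with unstructured
*spontaneous* input, three plasticity mechanisms imprint a cyclic
feedforward structure on the EE connectivity: strong within-cluster
weights and strong weights from cluster *i* to cluster *i*+1 (wrap-around
included), weak *i* to *i*−1 weights, and negligible weights elsewhere.
Under spontaneous input alone, the trained network then activates its
clusters cyclically, one after another — a *neural clock* whose ~10–15 ms
cluster activations discretize continuous time.

A read-out layer sits on top of the frozen clock: one read-out neuron (R)
per sequence element, each with one supervisor (S) and one interneuron
(H).  During read-out training the sequence (e.g. ABCBA) is presented by
driving each element's supervisor for `t_element` ms in turn, locked to
the clock cycle; voltage-based STDP on the all-to-all E→R connections
stores *when* within the cycle each element occurred.  Afterwards,
spontaneous input to the RNN alone replays the sequence: the read-out
neurons fire in the trained order, every cycle, indefinitely.

## Dynamics

E, R and S neurons are adaptive exponential integrate-and-fire units,

$$\frac{dV}{dt} = \frac{E_L - V + \Delta_T e^{(V - V_T)/\Delta_T}}{\tau_m}
  - \gamma\,a + Q,$$

where `Q` is the conductance-based synaptic drive
$Q = [g_\mathrm{exc}(E_\mathrm{exc} - V) + g_\mathrm{inh}(E_\mathrm{inh}
- V)]/c_q$ with strictly segregated excitatory and inhibitory channels
and a unitless double-exponential kernel (the constant `c_K` = 1 ms
absorbs the kernel's 1/ms; `c_q` = 1 ms plays the analogous role in `Q`).
Adaptation — the spike-triggered current `a` *and* the adaptive threshold
`V_T` — is an E-only mechanism (`γ_E` = 1, `γ_R` = `γ_S` = 0); this
package treats the threshold dynamics, whose constants the model
description defers to supplementary material, the same way as the
adaptation current, because burst-terminating adaptation is what gives E
clusters their ~10–15 ms dwell time, while read-out and supervisor
neurons must follow their teaching input without throttling.  I and H
neurons are plain leaky integrate-and-fire.

Integration is exponential-Euler on the linear part (leak plus
conductances, with the conductance-dependent effective time constant
folded in exactly), the exponential spike-initiation term evaluated
explicitly with a capped argument, and a hard ceiling `V_peak` at which a
spike is declared and the membrane reset — membrane potentials can never
run away, and a non-finite value aborts the run naming the neuron and
time.  All reads within a step (voltages, traces) use the values holding
at the step start.

## Plasticity

**Voltage-based STDP** (EE and RE): depression is a *jump* of
$-A_\mathrm{LTD}\,(u_i - \theta_-)^+$ at each delayed presynaptic spike,
with `u` a slow (τ_u = 10 ms) low-pass of the postsynaptic potential;
potentiation accrues continuously as
$A_\mathrm{LTP}\, x_j(t-d)\,(V_i - \theta_+)^+ (v_i - \theta_-)^+$, with
`x` a presynaptic spike trace (τ_x per class) and `v` a fast (τ_v = 7 ms)
voltage low-pass.  The spike-train terms are Dirac impulses and are
integrated as per-spike jumps — never as rate×dt products, which would
make depression vanish as the step shrinks.  The continuous term is
integrated in closed form within each step (`ltp_window_integral()`),
including the possible sign change of the rectified `v` term inside the
window, so the accumulated weight change on a fixed scenario is invariant
to the step size up to floating-point rounding; the test suite pins this
against a dt/100 dense trapezoidal integrator.  RE connections use the
same rule without weight-dependent potentiation.

**Inhibitory plasticity** (EI): purely spike-triggered;
$A_\mathrm{inh}(y^E_i - 2\alpha r_0 \tau_y)$ per delayed presynaptic
(inhibitory) spike and $A_\mathrm{inh} y^I_j$ per postsynaptic spike.
The offset makes inhibition onto a neuron firing below the target rate
`r_0` weaken and above it strengthen — the homeostat that keeps the
excitatory population near `r_0` and the network balanced.

**Synaptic normalization** (EE): every `tau_norm` = 450 ms, each E
neuron's summed incoming EE weight is reset subtractively to its initial
value `K_i` (exactly, before clipping; the post-clip residual is reported,
not iteratively corrected).  The printed update rule's parenthesization is
ambiguous; the implemented reading
$W_{ij} \leftarrow W_{ij} - [(\sum_k W_{ik}) - K_i]/l_i$ is the only one
that conserves the sum.

Trace conventions (fixed identically in the scenario runner, the dense
reference integrator, and the compiled engine): spike-triggered terms read
traces at their left limits; trace jumps of `alpha` (= 1 ms⁻¹, the
unit-fixing impulse scale) occur at the spike instant and then decay.  The
synaptic delay `d` applies to presynaptic spike trains and traces;
postsynaptic quantities are read undelayed.

## Parameter provenance

Every parameter carries a provenance tag in `parameter_table()`:

* **paper** — printed in the model description or its figure captions:
  sizes (2400/600/30, 80 per cluster), `t_stim` 9 ms, `t_gap` 6 ms,
  `lead` 25 ms, `t_element` 75 ms, the rates 22.5k/4.5k/10k/1k spk/s,
  `tau_norm` 450 ms, `c_K` = 1 ms, α.
* **lineage** — from the published model family this network builds on
  (AdEx constants, Clopath-rule thresholds and trace constants, reversal
  potentials).
* **provisional** — deferred by the description to supplementary material
  not restated here; defaults follow the lineage and are exposed in the
  config (`p`, bounds, learning rates, delays, `rexcI`, `rexc2E`,
  `rexcH`, kernel constants, adaptation constants).
* **choice** — replication choices of this package (see below).

## The desk preset

The shipped `desk` preset reproduces the model's qualitative behavior at
1/12 the size: 10 clusters × 20 E neurons, 100 I neurons, 5 min per
clock-learning phase (2000 stimulation rounds of a 150 ms period), and a
read-out phase of 100 s on a 3-element higher-order sequence (ABA, 35 ms
elements, 15 ms lead).  Choices that differ from the full preset, and
why:

* `p_EE` = 0.8 (vs 0.2): with 20-neuron clusters, an in-cluster in-degree
  of ~15 is needed for regenerative cluster ignition; at full scale
  `p` = 0.2 gives the same in-degree from 80-neuron clusters.
* EE initial weight 0.011 and `W_max` 0.08: the normalization budget `K`
  must accommodate the concentrated post-learning state (≈16 intra-cluster
  edges near 0.08 plus ≈16 feedforward edges near 0.035 per neuron), and
  single learned EPSPs must be large enough (~2–4 mV) that a handful of
  coincident partner spikes ignites the cluster.
* 100 s of read-out training (vs 12 s at full scale): each desk cluster
  has a quarter of the presynaptic mass behind every read-out band, so the
  same per-synapse learning rate needs proportionally more presentations.
* The sequence ABA is higher-order in the cyclic stream (element A is
  followed by both B and A), uses a 2-letter alphabet so each element maps
  to one read-out triple, and fits the desk clock cycle
  (15 + 3×35 = 120 ms < ~140 ms period).

With these settings the desk clock attains a sequentiality score of
~0.85–0.9, a period of ~130–150 ms (nominal stimulation period 150 ms),
~11 ms cluster activations, and replay that decodes the trained sequence
in the large majority of cycles across seeds.  What desk-scale success
does *not* show: the full-scale quantitative targets (470 ms period,
~15 ms activations, one read-out spike per element), which
`scripts/validate_full_scale.R` asserts at the published configuration,
nor robustness to parameter perturbations, which neither scale probes.

## Design choices made where the design was open

* **Cycle-locked teaching via an online trigger.**  Each presentation must
  start at the same clock phase, but the autonomous period wanders a few
  percent around the nominal one, so a fixed-period schedule drifts out of
  phase within seconds.  The engine therefore restarts the supervisor
  program whenever the reference cluster (cluster 0) fires a threshold
  number of spikes within a short window (3 ms window, ~30% of the cluster,
  refractory 60% of a period), and holds the program at its baseline tail
  otherwise.  This implements "each element always appearing at the same
  time relative to the activation of the first cluster" with only locally
  observable quantities.
* **Read-out feedback inhibition.**  Each read-out neuron excites its own
  interneuron (class HR), which inhibits it back (RH).  The description's
  wiring table lists the S and H afferents of R; the H afferent is only
  functional if something drives H when external input is off, and during
  replay the feedback loop is what terminates each element's read-out
  burst so that a repeated element later in the cycle can fire again.
  During training, externally driven H activity suppresses clock-driven
  (wrong-phase) read-out firing, keeping the learned bands selective.
* **Spectrum classification.**  The leading set is the `N_C` eigenvalues
  of largest modulus: for an idealized ring matrix the whole ring (half of
  which has negative real part) is recovered exactly, which a
  largest-real-part rule cannot do; the E-I balance pair is the most
  negative-real-part conjugate pair among the remainder.
* **Clock-metrics estimator.**  Per-cluster population rates are smoothed
  with a 2 ms Gaussian on a 0.5 ms grid; activations are maximal runs
  where one cluster is the arg-max above 30 Hz/neuron; the period is the
  mean interval between successive cluster-0 activation onsets; the
  sequentiality score is the fraction of episode transitions going
  i → i+1 (mod N_C).  The estimator is a documented convention — the
  source description does not define one — and is invariant to uniform
  time shifts.
* **Initial conditions** (unspecified in the description): membrane
  potentials and voltage traces start at the resting potential, spike
  traces and conductances at zero.  State is never reset during a run;
  phases chain the full neuron/trace state (in-flight spikes within the
  1 ms delay line are flushed at phase boundaries).
* **External input** enters the same conductance channels as recurrent
  input, with its own per-population weight, delivered without delay.
  Poisson sampling draws full per-bin counts (at 22.5k spk/s and 0.1 ms
  bins the expectation is 2.25 per bin; Bernoulli thinning would
  systematically undershoot).

## Numerical notes

* `dt` = 0.1 ms; all protocol times are validated as integer multiples.
* Exact exponential updates are used for every linear decay (conductance
  states, traces, thresholds, adaptation), so halving `dt` changes
  subthreshold trajectories only through the explicit exponential term
  and conductance sampling.
* Weight clipping to `[W_min, W_max]` happens after every update; clip
  events are counted and reported per class.
* Determinism: all randomness (topology, Poisson input) flows through R's
  RNG; a fixed seed triple gives bit-identical spike records on one
  platform.

## Known limitations

* The supplementary parameter table of the replicated study was not
  available; all `provisional` values are lineage-based reconstructions,
  so exact quantitative agreement with the published full-scale run is
  not guaranteed even at full scale.
* The desk preset's read-out stage is tuned for 2–3-element sequences; at
  35 ms per element a desk cycle cannot hold the five-element ABCBA that
  the full configuration learns.
* Parallel learning of several sequences with selective read-out
  inhibition is out of scope.
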