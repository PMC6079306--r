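---
title: "The cuneate neuron model and its self-stabilizing synaptic learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cuneate neuron model and its self-stabilizing synaptic learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cuneate)
```

## Overview

Cuneate nucleus projection neurons (CNs) are the first central relay for
tactile primary afferents (PAs). In adult animals their PA synaptic weight
distributions are highly skewed — a few strong inputs, many weak ones —
suggesting an extensive learning history. This package implements a
conductance-based model of that learning loop end to end: a bionic-fingertip
front end that converts analog sensor waveforms into 80 PA spike trains, a
CN membrane model whose intermediate (~10 ms) dynamics generate the
intracellular calcium signal, a calcium-gated Hebbian plasticity rule with
two homeostatic controls, protocols for long learning runs, and the analysis
metrics used to characterize the outcome (Victor–Purpura spike-train
distance, response correlation, classical MDS of weight landscapes, l2/l1
sparseness), plus a Nelder–Mead harness for fitting the intermediate
dynamics to voltage traces.

## The membrane model

The membrane follows a conductance-based exponential integrate-and-fire
(EIF) equation

$$C_m \dot V_m = -g_L (V_m - E_L) + g_L \Delta_T e^{(V_m - V_t)/\Delta_T}
  + I_{Ca} + I_K + I_{syn} + I_{ext},$$

with low-threshold voltage-activated calcium channels (LVA) and
calcium-dependent potassium channels (CAP):

$$I_{Ca} = -\bar g_{Ca}\, x_{Ca,a}^3 x_{Ca,i} (V_m - E_{Ca}), \qquad
  I_K = -\bar g_K\, x_{KCa}^4 x_{KVm}^4 (V_m - E_K).$$

Each gate relaxes first-order toward a two-parameter sigmoid equilibrium in
voltage (or, for the CAP calcium gate, in calcium concentration). The LVA
pair produces the post-inhibitory rebound bursts characteristic of these
neurons: hyperpolarization de-inactivates $x_{Ca,i}$ (its equilibrium is
only ~0.01 at rest, midpoint $-68$ mV), and on release the fast activation
gate ($\tau = 0.27$ ms) opens, producing a calcium-carried depolarizing
transient. The intracellular calcium concentration gains the LVA influx
($B_{Ca} |I_{Ca}|$, so depolarization-activated LVA always *raises*
calcium) plus a small increment per action potential (below), and leaks
back to its 101 nM resting value with $\tau = 6.3$ ms. The CAP conductance,
gated by both voltage and calcium, terminates bursts.

Three deliberate choices depart from the most literal reading of the model
equations as usually printed for this architecture; each is forced by
internal consistency:

* **CAP calcium gate is an activation gate.** With the parameter values
  used here (gate midpoint 222 nM, rest 101 nM) an *inactivation* reading
  would leave the potassium conductance ~90% open at rest and close it as
  calcium rises. That contradicts what calcium-dependent potassium channels
  do (repolarize the cell as calcium rises), produces a standing ~0.4 nA
  potassium current at subthreshold potentials, and removes the only
  burst-termination mechanism. The gate therefore opens with calcium.
* **$B_{Ca}$ rescaled.** The published mantissa is kept but the exponent is
  recalibrated (default $3.374\times10^{5}$ M/C) so that stimulus-evoked
  LVA transients traverse the dynamic range of the CAP calcium sigmoid
  (~100–300 nM). Dimensional analysis shows that no unit system makes the
  originally printed exponent produce calcium excursions on the scale of
  the printed sigmoid constants: the concentration would stay pinned at
  rest and the entire calcium-driven learning signal would be constant.
* **Spike-evoked calcium.** Each action potential adds `ca_per_spike`
  (default $2\times10^{-8}$ M) to the calcium pool, standing in for
  high-voltage-activated channels that open during the spike. A pure-LVA
  calcium signal is blind to tonic firing (sustained depolarization
  inactivates LVA, so runaway activity reads as *resting* calcium), which
  turns the hyperexcited state into an inescapable trap for the inhibitory
  homeostat below. With spike-evoked calcium, hyperactivity registers as a
  high calcium-spike rate and inhibition self-corrects.

## Spikes and integration

A spike is registered when the depolarization speed crosses
`spike_detect_slope` (20 V/s) on the upstroke, with a numeric ceiling at
$V_t + 10\Delta_T$ as fallback during sustained drive. The membrane is
reset to the potential at which the spike initiated — capped at the formal
EIF threshold $V_t$, so the fast afterhyperpolarization always ends below
the spike-generation region — and held there for a 1 ms refractory window
modelling the stereotyped fast AHP. Without the cap and the hold, a
reset-to-initiation rule fires once per integration step under sustained
suprathreshold drive (a rate of $1/dt$, divergent under step-halving),
which is numerically meaningless.

The membrane uses an integrating-factor (exponential Euler) update over the
instantaneous total conductance. This is the standard stable scheme for
conductance-based synapses: the largest synaptic conductance constants on
the intrinsic-parameter grid ($9\times10^{-7}$, $2.3\times10^{-6}$ S)
exceed the explicit-Euler stability bound at $dt = 0.1$ ms by orders of
magnitude. Gates relax exactly (exponentially, with equilibria evaluated at
the step-midpoint voltage), and calcium relaxes exponentially toward its
instantaneous influx-balanced equilibrium. The default step is
$dt = 0.1$ ms; a guard rejects steps above half the fastest time constant.
The test suite verifies step-halving convergence of rebound spike times to
within 0.2 ms.

## Synapses and the local calcium signal

Each of the 80 PAs drives one excitatory synapse (weight $w_i \in
[0.001, 1]$) and, through a lumped population of inhibitory interneurons
that are not simulated explicitly, one shared inhibitory synapse. Both use
single-exponential conductance kernels ($\tau = 6.4$ ms), scaled by the
maximum synaptic conductance constant $g_{max}$. The inhibitory stream is
delayed by `inh_delay` (default 1 ms), the measured onset lag of
interneuron-relayed compound IPSPs relative to direct PA EPSPs. This delay
matters: with identical kernels and zero delay, excitation and inhibition
form a single effective conductance toward one mixed reversal and the
membrane never swings below rest, which silences the LVA machinery. With
the delay, each afferent volley opens with an excitation-only window that
triggers the LVA transient, while the ensuing inhibition swings the
membrane below rest and re-primes LVA for the next event.

The subsynaptic ("local") calcium transient of one presynaptic spike is a
difference of exponentials with rise 4 ms, decay 12.5 ms and scaling
constant 21 ms (peak ~0.983 at ~6.7 ms). Supralinearity is approximated by
subtracting 75% of that single-pulse peak from the summed signal and
rectifying at zero: a lone spike barely clears the offset, while
high-frequency bursts produce disproportionately large local activity.

## The plasticity rule and its two homeostats

After each stimulus presentation, every excitatory weight changes by

$$\Delta w_i = \eta \, K(w_i, \mathrm{sign}\, wc_i) \, wc_i, \qquad
  wc_i = \int \big(A_{tot}(t) - \theta\big)\, A^{loc}_i(t)\, dt,$$

where $A_{tot} = k\,[\mathrm{Ca}^{2+}]$ is the main-compartment calcium
activity, and the learning threshold $\theta$ is the moving average (window
3 presentations, current presentation included) of the mean total activity
times the homeostatic gain Syn\_EQ — a dual-slope linear function of the
total excitatory weight, equal to 1 at the set point of 10, with slope 0.12
above and 0.04 below. Total activity above the threshold defines the
potentiation zone, below it the depression zone; the local calcium activity
gates which synapses feel the drive. The weight-compensation factor $K$ is
a complementary sigmoid pair in the current weight (midpoint 0.5, steepness
0.1 on the weight axis): insertion of receptors becomes harder the more are
present, removal harder the fewer remain. The printed steepness constant
0.005 for a unit-interval argument is a near-step and is accepted via
configuration but not used as the default.

The lumped inhibitory weight adapts once per presentation by a dual-slope
rule in the calcium spike rate: zero at the set point (default 20 Hz),
$-0.01$ at 0 Hz and $+0.01$ at 200 Hz, driven by a 3-presentation moving
average. The calcium spike rate is operationalized as the number of upward
crossings of $A_{tot}$ above `ca_rate_threshold` (default $2\times10^{-7}$,
just below the CAP sigmoid midpoint) per second — one counted "calcium
spike" is one burst-level calcium transient.

Two constants the architecture needs but the rule set does not pin down:

* **$\eta$** (default $1.2\times10^{8}$ weight units per molar-second)
  maps the drive integral onto weight units. It was calibrated once, by a
  one-dimensional sweep, so that a default diversified run shows monotone
  sparseness growth and reliable winner selection within a few hundred
  presentations; roughly twofold higher values make selection unreliable
  and ~fourfold higher values drive the weight vector into chaotic
  saturation/floor oscillations.
* **Initial inhibitory weight** (default 0.5). The homeostat has an
  inverted-U response: too little inhibition leaves the cell tonically
  depolarized (calcium-silent), too much clamps it. Starting inside the
  stable basin (net synaptic reversal below rest) lets the controller find
  its equilibrium at $w_{inh} \approx 0.35$–0.5; starting at 0.125 (the
  value quoted for the original architecture) is below the basin in this
  implementation and collapses into the calcium-silent trap.

At the resulting operating point the total excitatory weight equilibrates
about 50% above its set point. This offset is structural: the learning
drive weights $A_{tot}$ by the local activity, which concentrates on burst
periods where $A_{tot}$ exceeds its time average, so the threshold must
sit correspondingly above the mean before net drive vanishes, and with the
0.12 upper Syn\_EQ slope that equilibrium lies near $\sum w \approx 15$.
The acceptance tests therefore assert *bounded* homeostasis (totals within
a factor-of-two band around the set point, calcium rates within
[0.5×, 4×] of theirs with the median in [0.5×, 2×]) rather than exact
set-point tracking.

## The synthetic fingertip

`make_stimulus_set()` builds the five training stimuli (three
texture-slides, two dynamic indentations) and five non-training analogues.
Each stimulus is four analog sensor waveforms at 1 kHz for 1 s:

* *texture-slide*: a contact ramp and hold plus, during the slide phase, a
  ridge oscillation at the texture frequency (15/22/32 Hz for training,
  18/26/38 Hz for non-training), carried by each sensor with its own
  amplitude, phase and a slow (2–5 Hz) sensor-specific contact envelope —
  as a sliding fingertip loads its sensors on their own schedules;
* *indentation*: a trapezoidal force profile with shape-specific rise time
  and loading gains, modulated by a dynamic indentation oscillation (7/11
  Hz training, 8/13 Hz non-training) reaching each sensor with its own
  phase and depth.

Each sensor is "presented" five times with fresh seeded noise (repetitions
are treated as distinct sensors), kept raw (slowly-adapting-like) and
differentiated (fast-adapting-like), and encoded with two Izhikevich
regular-spiking presets (canonical constants; the second preset halves the
input gain): $4 \times 5 \times 2 \times 2 = 80$ channels, with channels of
sensor $k$ occupying block $(k-1)\cdot20 + 1..k\cdot20$. Mean PA rates are
~11 Hz (max ~25 Hz), well below the 200 Hz bound that justifies omitting
synaptic rate adaptation. During learning every spike receives independent
Gaussian jitter ($\sigma = 5$ ms).

The slow per-sensor envelopes are what make *sensor identity* the dominant
correlation axis among channels (verified by a test: within-sensor mean
Victor–Purpura distance is far below the across-sensor distance). Without
them all sensors share one oscillation and the strongest correlation axis
is the encoder preset/signal-type cohort instead. What the generator does
*not* emulate: skin mechanics (no finite-element skin model — waveforms are
phenomenological), receptive-field geometry, overlapping afferent
innervation, and natural scene statistics. Passing tests show the learning
architecture behaves as described *given* inputs with block-structured
correlations; they do not certify performance on real fingertip
recordings.

## Protocols and their scale

`run_learning()` presents the stimulus set in a balanced pseudo-random
order (a seeded shuffle), resets the neuron, synaptic and local-calcium
state to rest between presentations (weights, the inhibitory weight, and
the moving averages carry over), and records the full weight trajectory.
The package's routine problem size is 300 presentations of the five
training stimuli — the scaled-down protocol used throughout the tests; the
full 1500-presentation setting is a configuration change
(`n_presentations = 1500`). `run_monotypic()` drives explicit schedules
(e.g. 300 repetitions of one stimulus, then 300 of another) to probe order
dependence; `sweep_intrinsic()` repeats runs across the intrinsic CN
parameter grid ($g_{max}$, calcium-rate set point, local calcium
time-constant scaling, seed-weight spread) with fresh jitter per repeat.

Seed weights are clipped normal draws (mean 0.125 so that 80 synapses
start at the total-weight set point; sd 0.08, range [0.001, 0.5]);
`seed_id` 1–5 reproduce the five fixed configurations.

The supralinearity ablation (`supralinearity = FALSE`) removes the local
calcium offset and replaces $A_{tot}$ by the plain sum of the local
activities, bypassing the intermediate dynamics as the learning signal. The
ablated signal lives on a different scale (dimensionless activities of
order 10 rather than molar concentrations), so the run uses a rescaled
learning rate (`abl_eta_scale`, chosen so first-presentation weight steps
match the healthy run's) and counting threshold. In the ablated mode the
learning signal is purely presynaptic — the weights no longer feed back on
it through the neuron — and with matched step sizes the rule behaves as an
open-loop drift: the sparseness trajectory shows no sustained growth over
the final third of a run.

## Analysis conventions

The correlation index of a channel group is the mean pairwise
Victor–Purpura distance (q = 10/s) within the group, averaged across the
five stimuli. It is a *distance*: lower index = more correlated. The
winners-versus-losers comparison therefore reports
`index(losers) − index(winners)`, positive when the ten highest-end-weight
channels are mutually more similar than ten high-seed-weight channels that
lost. Reconstructed responses convolve each train with the 6.4 ms EPSP
kernel on a 1 kHz grid, weight and sum; correlations between responses are
zero-lag normalized cross-correlations without mean subtraction (the
convention of MATLAB's `xcorr(...,'coeff')` at lag zero). Weight
landscapes are compared by Euclidean distance and embedded with classical
MDS; sparseness is the l2/l1 norm ratio (1 for one-hot, $1/\sqrt{80}$ for
uniform).

## Fitting

`fit_cn_parameters()` reproduces the two automated stages of the original
three-stage scheme (the first stage, manual initialization, is the
user-supplied starting point): Nelder–Mead on a spike-masked mean-squared
trace discrepancy, then on the spike-timing objective — per current step,
the sum over the larger spike set of squared nearest-neighbour distances,
multiplied on any count mismatch by $\omega_s$ times the summed squared
count differences. Two details are choices, not givens: $\omega_s$
defaults to 1000 (one extra spike then dominates typical timing errors),
and the timing error is floored at $10^{-6}\,s^2$ in the mismatch branch so
that a simulation with wrong spike counts but zero timing error cannot
score a perfect objective. Bounds are enforced by triangular reflection.
The harness is validated by parameter recovery on model-generated traces
(e.g. $g_{Ca}$ perturbed ×1.5 recovers to ≪10% relative error); fitting to
in-vivo recordings is out of scope.

## Known limitations

* The two lowest $g_{max}$ values do *not* reproduce the "no learning"
  outcome reported for the original architecture: with spike-evoked
  calcium (required for global loop stability) a weakly coupled CN still
  fires and slowly reshapes its weights. The corresponding acceptance
  assertion is left failing deliberately rather than weakened.
* The total-weight homeostat equilibrates above its set point (see above).
* Monotypic runs do not reach fixed points at this problem size; their
  endpoint comparisons are made against jitter-repeat variability.
* Single-compartment abstraction: one main compartment plus pointwise
  synaptic spaces; no cable structure, no multi-neuron lateral
  interactions between CNs.
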