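---
title: "Between-area communication in spatially organized spiking networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Between-area communication in spatially organized spiking networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
network model and its assumptions, the analysis battery, the numerical
choices, and what the desk-scale simulations do and do not establish.

## The scientific question

Population recordings from a single brain area cannot tell whether
low-dimensional shared variability is generated locally by recurrent
dynamics or inherited from upstream areas. The package studies this question
in a fully controlled setting: a feedforward chain of two recurrently coupled
spiking networks (a *sender* and a *receiver*) driven by an unstructured
Poisson input layer. Because the only between-area pathway is the
sender-to-receiver projection, any structure in the receiver is either
inherited from the sender or emergent from the receiver's own recurrent
interactions — and the package measures how well linear communication
statistics discriminate the two.

## Network model

**Geometry.** Each layer occupies the periodic unit square. Neurons of one
class sit at the cell centers of a square lattice (`grid_layer()`); at full
scale the input layer has 2,500 Poisson units and each recurrent layer has
40,000 excitatory (E) and 10,000 inhibitory (I) exponential
integrate-and-fire neurons.

**Wiring.** The probability that a presynaptic neuron at `y` contacts a
postsynaptic neuron at `x` falls off with their periodic distance through a
wrapped Gaussian in each coordinate,
`p(x, y) = p_bar * g(x1 - y1, sigma) * g(x2 - y2, sigma)`, with widths
`sigma_ffwd = 0.05` for feedforward and `sigma_E = sigma_I = 0.1` for
recurrent projections, and mean connection probabilities and strengths from
the standard parameter table (`standard_params()`). Two sampling schemes are
implemented (`sample_synapses()`):

* **Fixed out-degree** (default): every presynaptic neuron makes exactly
  `K_out = round(p_bar * N_post)` contacts at wrapped-Gaussian-displaced
  lattice targets; repeated draws are kept as multi-synapses. This is the
  conventional scheme for this family of spatial balanced networks, and it
  is forced here by the parameters themselves: with `p_bar = 0.1` and
  `sigma = 0.05` the pairwise probability formula saturates above 1 near
  zero distance, so Bernoulli sampling with clipping would discard roughly
  half of the feedforward drive and collapse the balanced state.
* **Bernoulli per pair** (option): independent draws with the clipped
  pairwise probability; degree distributions are then binomial and no
  duplicate edges occur.

**Sender-to-receiver projection.** The receiver's feedforward sources are an
input-layer-sized (2,500-neuron) regular sublattice of the sender's E cells,
wired with the feedforward parameters. This keeps the feedforward in-degree
of both recurrent layers identical (250 excitatory contacts per E cell). The
alternative reading — all 40,000 sender E cells projecting at `p_bar = 0.1`
— would give the receiver a feedforward drive dozens of times larger than
the sender's and saturate it at refractory-limited rates, inconsistent with
the observed factor-of-~1.75 rate increase from sender to receiver.

**Dynamics.** Membrane voltages follow exponential integrate-and-fire
dynamics with leak conductances `1/15` (E) and `1/10` (I) (membrane time
constants 15 and 10 ms), leak potential −60 mV, soft threshold −50 mV, spike
sharpness 2 mV (E) and 0.5 mV (I), hard threshold −10 mV, reset −65 mV held
for a refractory period of 1.5 ms (E) and 0.5 ms (I). Synaptic currents are
differences of exponentials (rise 1 ms; decay 5 ms for E synapses, 8 ms for
I synapses in the stable regime) normalized to unit time-integral, summed
over presynaptic spikes, with strengths `j / sqrt(N)` (N the postsynaptic
layer's total size) so that individual postsynaptic potentials stay below
~1 mV.

**Destabilization.** E/I balance is pushed into a pattern-forming regime in
exactly one layer per scenario, either *in space* by broadening recurrent
inhibition (`sigma_I = 0.3`) or *in time* by slowing inhibitory decay
(`tau_I_decay = 24` ms). `scenario_params()` names the five study
conditions: `standard`, `spatialS`, `spatialR`, `temporalS`, `temporalR`.

## Desk-scale simulations

Full-scale trials (100,000 recurrent neurons, 20 s at a 0.05-ms Euler step)
are not desk-scale, so the package defines a scaled mode. Downscaling a
balanced network is not innocuous: if in-degrees `K` and layer sizes `N`
both shrink by a factor `f` while weights follow `1/sqrt(N)`, every mean
synaptic drive falls by `sqrt(f)` and the balanced operating point (the rate
table) collapses — we measured sender rates dropping from ~15 Hz to ~10 Hz at
`f = 0.1` under that literal rule. The default scaled mode
(`scale_rule = "preserve_indegree"`) therefore keeps every neuron's input
statistics at their full-scale values:

* lattice sizes shrink to the nearest perfect square of `n * f`;
* in-degrees stay at full-scale values, realized through multi-synapse
  contacts (weights stay `j / sqrt(N_full)`);
* the Poisson input layer stays at full size (2,500 units), which also keeps
  the feedforward multi-synapse multiplicity at its full-scale value of
  about 3.

Under this rule the layer rates are stable across scales 0.1–0.25
(sender E ≈ 17 Hz, receiver E ≈ 27 Hz for the standard network, versus ~20
and ~35 at full scale per the reference rate table). The residual systematic
reflects the one thing no downscaling can preserve — the *number* of neurons
sharing wiring — which inflates local correlations and their rate
corrections. We report this deviation rather than compensating for it.

Two desk-scale artifacts are worth flagging because they affect the
population statistics more than the rates:

* **Whole-grid correlation means.** Spatial destabilization at desk scale
  forms a near-standing, domain-scale activity pattern. Between-area
  correlations at matched positions are large (≈0.6), but the whole-grid
  mean over random pairs nearly cancels between the pattern's positive
  (short-distance and antipodal) and negative (mid-distance) lobes, giving
  means of order 0.01 where the full-scale study reports 0.08. The coupling
  itself — what the communication subspace measures — is unaffected.
* **Dimensionality ordering.** At desk scale the receiver's locally sampled
  shared dimensionality can exceed the sender's in the stable regime
  (shared wiring makes the receiver's local fluctuations richer), whereas at
  full scale dimensionality decreases along the chain. The communication
  orderings (below) are robust to this.

## Analysis battery

**Rates and correlations.** Instantaneous rates are spike counts in
nonoverlapping 50-ms bins (`bin_counts()`, half-open bins, partial trailing
bin dropped); all statistics discard a 1-s burn-in. Pairwise statistics use
Pearson correlations of raw binned counts of excitatory cells
(`correlations_vs_distance()`, `between_area_correlations()`); zero-variance
neurons are excluded, between-area means subsample random pairs (default cap
10^6), and distance curves use 20 equal bins of the periodic distance over
[0, sqrt(2)/2].

**Shared dimensionality.** `sample_disc()` draws 50 distinct neurons firing
above 2 Hz within a disc of given radius (a radius of 0.5 spans the whole
periodic domain). `fit_fa()` fits the Gaussian factor model
`x ~ N(mu, LL' + Psi)` by expectation-maximization on the count matrix
(diagonal `Psi` unconstrained, unlike probabilistic PCA); the training
log-likelihood is nondecreasing by construction and convergence is declared
at a relative improvement below 1e-6 (at most 500 iterations; random
orthonormal initialization of `L`, seeded). The factor count is chosen by
maximizing held-out log-likelihood over contiguous time-block folds
(`select_q()`, default grid 1–15, 5 folds — the original study does not
state these; they are configurable). Shared dimensionality is the
participation ratio `(sum lambda)^2 / sum lambda^2` of the eigenvalues of
`LL'` (`participation_ratio()`): 1 when one mode dominates, the number of
modes when the spectrum is flat, no arbitrary threshold.

**Communication subspace.** `fit_rrr()` implements reduced-rank regression
of receiver counts on sender counts: `B_RRR = B_OLS Gamma_m Gamma_m'` with
`Gamma_m` the top eigenvectors of the covariance of the OLS-fitted receiver
activity — the optimal rank-constrained least-squares map. Columns are
mean-centered (consistent with the demeaned total sum of squares of the
performance measure); no variance normalization. Prediction performance is
the pooled demeaned `R^2` (reported in percent, floored at 0 on held-out
data). `optimal_rank()` cross-validates over contiguous time blocks (default
20 folds; contiguous rather than shuffled bins to respect temporal
autocorrelation) and selects the smallest rank within one SEM of the peak
mean performance, reporting the mean held-out performance at that rank.
Sender and receiver discs overlap exactly (same center) to maximize
communication strength.

**Superposition linearity test** (`linearity_test()`). Per trial, three
20-s simulations of one destabilized output layer driven by independent
Poisson realizations: 7 Hz in the upper half of the input grid
(`x2 >= 0.5`) and 3 Hz in the lower half; the mirrored pattern; and the
uniform 10-Hz sum. After discarding 1 s, linearity predicts
`nu_1 + nu_2 = nu_homo` per neuron; the statistic is the mean over E cells
of `|nu_sum - nu_homo|`, averaged over trials. Wiring is fixed across
trials; inputs and initial voltages are redrawn. Note that with 19 s of
data per rate estimate, Poisson estimation noise alone contributes ~1 Hz to
this statistic — consistent with the small value expected when the mapping
is effectively linear.

**Frozen-input chaos test** (`chaos_test()`). One input realization is
propagated once through a standard sender; the receiver is simulated twice
with identical wiring, input and I-cell initial voltages, differing *only*
in the E cells' initial voltages. Unreliability at spatial scale `r` is
`Delta(r) = mean_t |nu1_r(t) - nu2_r(t)| / nubar_r` on 50-ms bins, where
`nu_r(t)` averages over all E cells within a disc of radius `r` and
`nubar_r` is the grand-mean rate over both trials (the original figure
caption names these quantities without printing the formula; this is our
documented reading). Identical initial conditions give `Delta = 0` exactly
because the integrator is deterministic.

**Toy signals** (`toy_sender()`, `apply_mapping()`). A sum of six sines
(amplitudes in [0.05, 0.3], frequencies in [0.5, 10] Hz, phases in
[0, 2pi]) stands in for sender activity; receivers are the linear
compression `0.5 s`, the cubic `-0.8 s (s - 0.5)(s - 1)`, or `s` plus an
Ornstein–Uhlenbeck process with `tau = 10` s. The OU "sigma" (0.05) is read
as the *stationary standard deviation* — the caption does not define its
role — and the process is discretized exactly. Defaults: 60 s at 10-ms
sampling.

## Numerical choices

* Forward Euler at `dt = 0.05` ms; halving `dt` changes scaled-network rates
  by under 3% (tested). The spike-initiation exponential's argument is
  capped at 20; any voltage at or above the hard threshold spikes at that
  step. Synaptic kernels are realized exactly (to machine precision at
  spike-event resolution) by two decaying state variables per neuron and
  presynaptic class; a spike at step `s` contributes `eta(k dt)` at step
  `s + k`.
* During the refractory period the voltage is clamped at reset and
  integration is frozen; synaptic states keep evolving.
* The integrator flushes denormal floats to zero (synaptic states decay
  exponentially and underflow during quiet periods; denormal arithmetic
  dominated run time while contributing < 1e-300 mV/ms), and inlines the
  spike-term exponential (argument reduction plus degree-9 Taylor, relative
  error ~1e-12).
* Initial voltages are uniform on [V_reset, V_T] per neuron (seeded); the
  original study varies initial voltages without stating a distribution.
* All randomness derives from one master seed fanned out to named substreams
  (`seed_stream()`), so wiring, inputs, initial conditions and
  cross-validation can be varied independently and every run is
  bit-reproducible.

## Problem sizes used by the tests and the acceptance script

Scenario simulations: scale 0.2 (8,100 E + 2,025 I per layer), 20-s trials
(15 s in the test suite); linearity protocol: scale 0.1, 2 trials; chaos
protocol: scale 0.05, 10-s trials; factor-count grids 1–10 in tests, 1–15
in the analysis scripts. These sizes were chosen so the full battery runs in
minutes on one CPU; rates are insensitive to the scale in 0.1–0.25 under
the in-degree-preserving rule.

## What the synthetic data do and do not establish

The simulator *is* the study's data generator: every analysis consumes its
spike rasters, and the toy-signal module provides fast closed-form fixtures
for the communication measure. Passing tests establish that the analysis
chain recovers known structure (factor models, low-rank maps, OU moments)
and that the network reproduces the qualitative physics — balanced
irregular firing, pattern formation under either destabilization,
propagation of sender patterns, the communication-subspace orderings, the
linearity contrast, and the micro-versus-macro chaos dichotomy. They do not
establish quantitative fidelity to full-scale statistics that depend on
absolute network size (whole-grid correlation means, absolute shared
dimensionality), nor anything about biological tissue: the model has no
conductance-based synapses, no transmission delays, no adaptation, no
feedback (receiver-to-sender) projections, and its input is spatially and
temporally unstructured by design.
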