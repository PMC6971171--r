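---
title: "Simulating descending motor pathways and measuring n:m spectral coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating descending motor pathways and measuring n:m spectral coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

Cortical motor commands reach spinal motoneurons through a direct,
mono-synaptic route (the corticospinal analogue) and through indirect routes
that relay the command across one or more populations of interneurons (the
cortico-reticulospinal analogue).  A beta-band (15–35 Hz) cortical drive that
is transmitted linearly appears in the motoneuron-pool output at the *same*
frequencies (iso-frequency coupling, the basis of corticomuscular coherence).
Every synaptic relay, however, passes the signal through spiking
nonlinearities, which move power across frequencies and create coupling
between an input frequency $f_X$ and output frequencies $f_Y \ne f_X$
(cross-frequency coupling).  `nmcoupling` simulates both kinds of pathway
with conductance-based neuron models and quantifies both kinds of coupling
with a generalized coherence statistic, so that the balance between them can
be studied as a function of the number of synaptic layers and of the mix of
direct versus indirect drive.

# The neuron models

Motoneurons are two-compartment (soma + dendrite) Hodgkin–Huxley style
models in the tradition of Booth, Rinzel & Kiehn (1997), carrying fast sodium
($g_{Na} m^3 h$), delayed-rectifier potassium ($g_K m_K^4$), N-type calcium
($g_{CaN} m^2 h$, both compartments), L-type calcium ($g_{CaL} m$, dendrite),
calcium-dependent potassium ($g_{K(Ca)}\,\mathrm{Ca}/(\mathrm{Ca}+K_d)$, both
compartments), persistent sodium on the dendrite ($g_{NaP} m h$, the
persistent inward current that amplifies synaptic drive), and leak.
Intracellular calcium obeys
$d[\mathrm{Ca}]/dt = -f\,(\alpha I_{Ca} + k_{Ca} [\mathrm{Ca}])$ per
compartment.  The compartments exchange current through a coupling
conductance with surface-ratio weighting ($I_{C(S)} = g_C/p\,(V_D - V_S)$,
$I_{C(D)} = g_C/(1-p)\,(V_S - V_D)$); defined this way $I_C$ is the current
*into* a compartment, so it enters the membrane equation with a positive
sign — the sign convention matters, as the anti-diffusive alternative
diverges within milliseconds.  Interneurons are single-compartment
reductions with only $I_{Na}$, $I_K$, leak and synapses.

Parameter values are shipped in `inst/extdata/neuron_params.yaml` and every
value can be overridden (`neuron_params(..., overrides=)`).  The kinetics
follow the published two-compartment motoneuron literature; a small set of
values could not be pinned to the sources offline and were fixed once, before
any acceptance measurement, by behavioral criteria:

* interneuron `g_L = 0.51` mS/cm² — the smaller value we first tried (0.1)
  destabilizes the resting state (spontaneous firing at the −64 mV leak
  potential), violating the requirement that an undriven pathway is silent;
* the motoneuron calcium subsystem (`alpha_ca = 0.1` µM·cm²/(µA·ms),
  `f_ca = 0.04`, `g_KCa_S = 1.5`, `g_KCa_D = 0.6`, `g_CaL = 0.15`, CaL slope
  −4 mV) — tuned so that (a) there is no tonic CaL-window → Ca → K(Ca)
  clamp at rest, (b) the dendritic persistent inward current amplifies
  without latching into >40 spikes/s plateaus, and (c) near-rheobase
  synaptically driven firing lands in the 16–19 spikes/s band reported for
  active motoneurons.

Excitatory synapses are conductance-based with instantaneous rise,
exponential decay ($\tau_{synE} = 5$ ms) and reversal at −10 mV; a
presynaptic spike increments the conductance by a peak value calibrated so
that a single EPSP depolarizes a resting motoneuron by 100 µV and a resting
interneuron by 500 µV.

## Integration scheme

Gating variables use exponential Euler (exact for frozen voltage); calcium
and synaptic conductances use their exact linear updates; and voltages use
exponential Euler with conductances frozen over the step.  We deviate here
from plain forward Euler on voltage: the total membrane conductance during
the spike upstroke makes $\Delta t\,g_{tot}/C$ approach 1 at the default
$\Delta t = 25$ µs, where forward Euler oscillates and diverges at the noise
levels the calibration requires, while the exponential update is
unconditionally stable.  Accuracy is guarded by convergence tests: halving
$\Delta t$ changes a subthreshold 1-s trajectory by well under 0.5 mV RMS and
a 10-s spike count by under 2%.  Spikes are upward crossings of 0 mV with a
2 ms dead time; the internal step is decimated to the 1 kHz output rate.

# The stated world: drive, heterogeneity, calibration

All signals are generated internally at 1 kHz in 1-s epochs (warm-up epoch
discarded; neuron state is continuous across epochs).  The supraspinal input
is a zero-mean Gaussian signal band-limited to 15–35 Hz by frequency-domain
masking (exact band edges, independent epochs), shared by all first-layer
neurons.  Each neuron also receives an independent band-limited (1–100 Hz)
Gaussian membrane-noise current.  The composed first-layer injected drive is
$DC + s(t) + \nu_i(t)$ with a signal-to-noise ratio of −7.5 dB and a total
stochastic variance that is a calibrated fraction of $DC^2$.

Membrane noise is intrinsic to the neurons, so synaptically driven layers
receive it too, at the magnitude implied by their class's calibration (the
noise component of the first-layer drive for interneurons; of the
mono-synaptic drive for motoneurons).  Without this, a layered pathway
transmits the beta drive almost linearly through any depth and the
iso-frequency coupling never collapses — contradicting the phenomenon the
simulator exists to study.  The noise magnitudes are not free dials: they are
pinned by interspike-interval variability targets (below).

Leak-potential heterogeneity carries all neuron-to-neuron diversity:

* **Interneuron layers** draw $E_L$ from a two-component mixture of
  *downward* shifted exponentials
  ($E_L = \mathrm{offset} - \mathrm{Exp(scale)}$; weights 0.6/0.4, offsets
  −65.5/−59.6 mV, scales 1.6/0.5 mV).  The constants were chosen once so
  that the sample mean is ≈ −64 mV, the firing-rate histogram declines from
  low rates with a secondary mode near 50 spikes/s (the two published
  anchors), and every draw stays below the zero-drive firing boundary.  The
  bulk component makes most interneurons slow, irregular,
  fluctuation-driven units; the second component contributes the regular
  ~50 spikes/s subpopulation.
* **Motoneurons** draw $E_L$ uniformly from an 8-mV band below −53 mV (the
  zero-drive silence cap); the spread is calibrated against the active-unit
  rate target.

The calibration chain (`calibrate_pathway()`) pins, in order: the two EPSP
peak conductances (bisection to 1%); the first-layer DC level and
noise-variance fraction (alternating 1-D searches until the layer mean rate
is in 19–24 spikes/s *and* the mean ISI-CoV is 0.55 ± 0.05 on 60-s runs);
the interneuron fan-in (integer bisection until a synaptically driven layer
fires at 19–24 spikes/s); the mono-synaptic motoneuron DC and noise fraction
(active-unit mean rate 16–19 spikes/s, ISI-CoV in 0.2–0.3); and the
motoneuron leak spread (active-unit mean 16–19 spikes/s under terminal-layer
drive).  All candidate evaluations reuse fixed derived seeds, so calibration
is deterministic given (targets, seed), and results are cached per
parameter/config hash.  Neurons contributing fewer than three spikes are
excluded from CoV averages (with a logged count); because the CoV statistic
depends on how many sparse units clear that bar, all CoV calibrations use
the same 60-s reference duration.

When `neurons_per_layer` differs from the reference 100, synaptic peak
conductances are scaled by `100/neurons_per_layer` — standard network
down-scaling that preserves the mean synaptic drive per neuron (fluctuations
grow by the square root of the scaling; the reduced tier accepts this).

# The n:m coherence analysis

For integer frequencies with reduced ratio $f_X/f_Y = m/n$
($\gcd(n,m) = 1$), the statistic is

$$\mathrm{NMC}(f_X,f_Y) \;=\;
\frac{\bigl|\langle X^n(f_X)\,(Y^m(f_Y))^*\rangle\bigr|}
     {\sqrt{\langle |X^n(f_X)|^2\rangle\,\langle |Y^m(f_Y)|^2\rangle}},$$

with $\langle\cdot\rangle$ averaging over epochs, $X(f)$ the per-epoch DFT
bin (demeaned epochs, rectangular window — forced by the 1-s epochs at 1 Hz
resolution), and $X^n$ the n-th power of the bin value.  It is bounded by 1
(Cauchy–Schwarz), invariant to amplitude scaling, and equals the square root
of classical magnitude-squared coherence when $n=m=1$.  Bins are divided by
their per-frequency RMS before powering, which leaves the statistic
unchanged and keeps moment orders up to ~100 within double range.

The analysis-side input $X$ is the *noisy* supraspinal signal: the common
beta-band drive plus an independent 1–100 Hz noise realization at −7.5 dB,
regenerated for each of the analysis repetitions.  The output $Y$ is the
cumulative spike train (CST) of a population — the per-millisecond count of
spikes summed over the pool.

The grid is 21 input × 100 output frequencies = 2,100 pairs, and the
family-wise error rate of 0.05 is Bonferroni-divided across them
($\alpha \approx 2.4\times10^{-5}$ per pair).  Two significance modes are
implemented:

* **`analytic`** (default): the classical coherence null quantile
  $\sqrt{1-\alpha^{1/(L-1)}}$ applied to every pair.  This is the standard
  practice of the coherence literature this analysis follows and is exact
  for $n=m=1$.  For higher moment orders it is *anticonservative*: the null
  of $|X|^n$-based statistics concentrates (a single large epoch dominates
  the moment), so pairs with reduced order above 12 are excluded from the
  IFC/CFC sums by default (`include_high_order = FALSE`).
* **`permutation`**: a per-pair null from epoch-permutation surrogates.
  Because the Bonferroni quantile is far beyond any feasible surrogate
  count, the upper tail of the squared statistic is fitted with a Weibull
  survival model over the top quintile and extrapolated, floored at the
  largest surrogate.  When the quantile *is* directly estimable
  (`n_surrogates * alpha >= 20`, as in the reduced-design FWER calibration
  test) the empirical quantile is used.  This mode controls the FWER for
  every pair (verified by a 200-run null calibration test) but is strictly
  more conservative.

The summaries are $\mathrm{IFC} = \sum$ significant NMC at $f_X = f_Y$,
$\mathrm{CFC} = \sum$ significant NMC at $f_X \ne f_Y$, and the
cross-over-iso index $\mathrm{COI} = (\mathrm{CFC}-\mathrm{IFC}) /
(\mathrm{CFC}+\mathrm{IFC}) \in [-1,1]$; COI is reported as missing (never
zero) when nothing is significant.

## Why two modes, and what a green test does and does not establish

Under the sound permutation thresholds, this model's cross-frequency values
(≈ 0.1–0.25 for harmonic pairs) never clear the corrected threshold at any
tested scale — a broadband 15–35 Hz input spreads quadratic distortion
products over many frequency pairs, so the per-pair diagonal share that the
NMC sees is intrinsically small.  The published iso-to-cross COI sign flip
*is* reproduced under the analytic mode, where part of the moderate-order
cross-frequency mass rides on the threshold's anticonservatism while the
iso-frequency sum (exactly calibrated) collapses across layers.  We document
this rather than hide it: the package reproduces the published analysis
under the published method's conventions, and also provides the
conservative machinery that shows how much of the cross-frequency sum
survives rigorous per-pair control.  Green headline tests therefore
establish reproduction of the analysis pipeline and its qualitative claims,
not the detectability of cross-frequency coupling under strict FWER control.

# Experiments

Three protocols mirror the simulation study design:

* `run_layer_sweep()`: COI/IFC/CFC between input and motoneuron-pool CST for
  pathways of 0–3 (reduced) or more layers.  One deep chain per repetition
  is shared across depths — the per-layer seed scheme makes the first $l$
  layers of a deep chain bit-identical to an $l$-layer chain, so each entry
  equals a standalone run.
* `run_per_layer()`: coupling against each successive interneuron layer's
  CST of one deep pathway, plus the motoneuron pool.
* `run_dual_drive()`: the pool receives $\sqrt{1-w}\times$ direct injected
  drive plus $\sqrt{w}\times$ synaptic drive from a two-layer chain
  (power-fraction mixing, $w = 0,0.2,\dots,1$).  Membrane noise is intrinsic
  and never scaled, so $w=0$ and $w=1$ are exactly the mono-synaptic and
  2-layer pathways.

The *reduced tier* (50 neurons/layer, 50 epochs, 10 repetitions, depth ≤ 4)
is the testing scale; full scale (100/200/100) only tightens error bars.
Repetitions regenerate every neuron's membrane noise and the analysis-side
input noise; the common beta drive and the topology stay fixed.

# Numerical choices and degenerate inputs

* Integration step 25 µs (must divide 1 ms); blow-up guard at |V| > 200 mV.
* Calibration searches cap the stochastic drive at SD ≤ 3×DC and ≤ 8 µA/cm²
  (beyond that the "percentage of the constant injection" premise is
  meaningless and extreme excursions trip the blow-up guard).
* All-zero spectral bins make a pair "undefined": excluded from sums.
* Ties at threshold are not significant (strict inequality).
* Without-replacement connectivity sampling; a 0-layer config has no
  connectivity and sets the direct-drive flag.

# Known limitations

* The per-compartment exponential voltage update freezes the other
  compartment's potential over the step, which breaks down in the
  (non-physiological) strong-coupling limit $g_C \gg g_{ionic}$: the
  coupling term then swamps the per-step influence of the ionic currents.
  The compartment-fusion property is therefore verified at
  $g_C = 10$ mS/cm² (100× the physiological value), where the fused cell's
  firing rate is within a few percent of the area-weighted
  single-compartment model; the true $g_C \to \infty$ limit would need a
  joint implicit solve of the voltage pair.
* The interneuron kinetics and several motoneuron constants are behavioral
  reconstructions, not line-by-line transcriptions of the sources (offline
  build); all are shipped, versioned and overridable.
* The reduced tier's 50-epoch thresholds are high (≈ 0.44); per-repetition
  IFC can floor at zero for deep pathways, making "strictly decreasing"
  comparisons between nearly-extinguished conditions fragile.
* No synaptic or conduction delays, no inhibition, no plasticity, no
  reticular-neuron biophysics — all exclusions of the simulated design
  itself.
* The dual-drive mixing keeps the *drive* power fractions exact; total
  motoneuron input power varies slightly across the mix because the two
  branches are not orthogonal in their effect on firing.
```
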