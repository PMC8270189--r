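---
title: "Modeling binaural tuning and inhibition loss in the LSO"
author: "lsosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling binaural tuning and inhibition loss in the LSO}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsosim)
```

## The scientific problem

Neurons of the lateral superior olive (LSO) encode the interaural level
difference (ILD) of a sound — the primary azimuth cue at high frequencies —
by combining excitatory input driven by the ipsilateral ear with glycinergic
inhibition driven, via the medial nucleus of the trapezoid body (MNTB), by
the contralateral ear. Their spike rate falls sigmoidally as the
contralateral level rises. For amplitude-modulated (AM) tones, the same
excitatory–inhibitory interaction makes the LSO an *anticoincidence
detector*: the rate is maximal when the two phase-locked input streams
arrive out of phase and minimal when inhibition slightly leads excitation.

Aging selectively removes MNTB fibers while leaving excitation relatively
intact. `lsosim` implements a stochastic single-neuron and population model
to ask how much this loss degrades binaural tuning, and how much a simple
homeostatic rule — scaling up the surviving inhibitory synapses — restores
it.

## The neuron model

The core is a single-compartment integrate-and-fire (IF) neuron in two
variants.

**Active IF** (`activeIFParams()`), the default, adds a small
low-voltage-activated potassium (KLVA) conductance and a stereotyped
spike-associated current:

$$C\frac{dV}{dt} = g_L(E_L - V) + g_{KL}\,d(V)(E_K - V)
 + g_{ex}(E_{ex} - V) + g_{inh}(E_{inh} - V) + I_{spike}(t - T_\theta)$$

with $C = 24$ pF, $g_L = 14.4$ nS, $g_{KL} = 21.6$ nS, $E_L = -56$ mV,
$E_K = -75$ mV, threshold $V_\theta = -45.8$ mV and refractory period
$T_{ref} = 1.6$ ms. The KLVA activation $d(t)$ follows first-order kinetics
with voltage-dependent rates $\alpha_d(V) = 0.5\,e^{(V+50)/16}$ and
$\beta_d(V) = 0.5\,e^{-(V+50)/16}$ (1/ms). On each threshold crossing a
spike is counted, the current
$I_{spike}(s) = 24 e^{-s/0.15} - 12 e^{-s/0.30}$ nA is injected to produce a
spike-like voltage excursion, and threshold testing is suspended for
$T_{ref}$, while the membrane dynamics continue to evolve. Overlapping
spike currents superpose linearly. The KLVA amount is small enough that the
cell keeps sustained (tonic) firing; onset-type LSO responses are outside
the scope of the model.

**Passive IF** (`passiveIFParams()`) drops all active conductances
($g_L = 26.4$ nS, $E_L = V_0 = -60$ mV, $V_\theta = -45.1$ mV); on threshold
the membrane is clamped to $V_0$ for $T_{ref}$. It is used to confirm that
conclusions do not depend on the KLVA conductance.

Each presynaptic spike at $t_i$ evokes a unitary alpha conductance
$\alpha(s) = A\,(s/\tau)\,e^{1 - s/\tau}$ peaking at $A$ a lag $\tau$ after
the spike ($A_{ex} = 3.5$ nS, $\tau_{ex} = 0.16$ ms, $E_{ex} = 0$ mV;
$A_{inh} = 12$ nS, $\tau_{inh} = 0.32$ ms, $E_{inh} = -75$ mV). Conductances
superpose linearly over spikes and over the $M_{ex} = 20$ excitatory and
$M_{inh} = 8$ (healthy default) inhibitory fibers.

## The synthetic input model

There is no external data: all inputs are generated internally, and the
generator defines the study conditions.

*Unmodulated tones.* Every fiber is a homogeneous Poisson process whose
rate follows the sigmoidal rate-level function
$\lambda(\mathrm{SPL}) = 30 + 240/(1 + e^{-(\mathrm{SPL} - 20)/6})$
spikes/s. The ipsilateral level is fixed at +35 dB (excitatory rate
$\approx 252$ spikes/s) and the contralateral level is $35 + \mathrm{ILD}$.

*AM tones.* Every fiber is an inhomogeneous Poisson process whose intensity
over the modulation cycle is a von Mises density with concentration
$\kappa$ chosen so that the vector strength $VS = I_1(\kappa)/I_0(\kappa)$
matches the target $VS(f_m) = 0.65\,(1 - e^{(f_m-2000)/500})/(1 +
e^{(f_m-2000)/500})$, scaled so the cycle-averaged rate equals
$\lambda(f_m) = 180 - 0.03 f_m$. All excitatory fibers lock to one phase
and all inhibitory fibers to another; a positive phase difference means
inhibition arrives earlier in the cycle.

Fibers are mutually independent. Trains start at $t = 0$ with no onset
ramp, and rates are computed over the full 500-ms window, matching the
sustained-response analysis the model targets.

What the generator does *not* emulate: auditory-nerve and bushy-cell
dynamics upstream of the rate functions (adaptation, refractoriness of the
inputs, across-fiber correlations), temporal jitter manipulations, and
onset transients. Passing tests therefore validate the model chain from
Poissonian drive to spike-rate statistics, not those upstream mechanisms.

## Inhibition-loss scenarios

`scenarioSpec(mInh, mode)` resolves the effective unitary inhibitory
amplitude:

* **uncompensated** — $A_{inh} = 12$ nS regardless of `mInh`; the total
  inhibitory conductance $M_{inh} A_{inh}$ falls linearly with fiber loss;
* **compensated** — $A_{inh} = 12 \cdot 8/M_{inh}$; the total is conserved
  at its healthy value (96 nS), e.g. halving the fibers doubles the
  unitary amplitude to 24 nS;
* **overcompensated** — the compensated amplitude is further multiplied by
  $(2 - M_{inh}/8)$, so the total is a linearly *decreasing* function of
  `mInh`: 50% above the healthy total at 4 fibers, zero at 16.

The overcompensation factor is applied on top of the compensated amplitude,
not the default one; this is the only reading under which the total
conductance is linear in the number of inputs and 50% larger at
$M_{inh} = 4$. Compensation modes require at least one surviving fiber.
All other parameters are identical across scenarios.

## Tuning statistics

`runTuning()` repeats 500-ms stimulations per grid point (ILD grid
$-45..+15$ dB in 2-dB steps; phase grid $-180..+180^\circ$ in $10^\circ$
steps) and reports per-point across-trial mean rate, SD, and Fano factor
(count variance over count mean; undefined and reported `NA` at zero-mean
points). Derived statistics:

* **modulation depth** — max minus min mean rate;
* **midpoint** — the ILD where the mean rate crosses half height,
  $(\max + \min)/2$, by linear interpolation; with multiple (noisy)
  crossings the one nearest the steepest-slope segment is used. Half-height
  is the standard midpoint definition for sigmoids; the model was checked
  against the reported midpoints under this definition.
* **neuronal discriminability** —
  $D = (\mu_1 - \mu_2)\big/\sqrt{(\sigma_1^2 + \sigma_2^2)/2}$ for
  neighboring grid points ($\Delta S = 2$ dB or $10^\circ$), related to
  Fisher information by $|D| = \Delta S \sqrt{I_F(S)}$ for Gaussian rates.

When the discriminability is averaged over a stimulus range
(`summarizeDiscriminability()`), the *absolute* value is averaged. Over a
periodic phase-tuning curve $D$ changes sign, so a signed average would be
near zero and could not produce a meaningful robustness summary; $|D|$ is
the only reading consistent with summaries that remain positive and
comparable across scenarios. Normalization to the healthy scenario
($M_{inh} = 8$) is done by the caller (or by `runExperiment()`), which also
removes the dependence on trial counts and population size.

## Population coding

`runPopulation()` builds 22 neurons whose ILD-tuning midpoints are shifted
uniformly from $-26$ to $+16$ dB in 2-dB steps. Shifting is realized at the
input level — the contralateral SPL is offset by $-\mathrm{shift}$ — which
translates the curve exactly along the ILD axis with no interpolation
error. Each neuron is paired with a *mirrored* partner (its tuning curve
reflected about zero ILD), the stand-in for the similarly tuned neuron of
the contralateral LSO. The bilateral rate difference
$\mu(\mathrm{ILD}) - \mu(-\mathrm{ILD})$ is exactly antisymmetric; because
the two sides fire independently, its SD adds the two sides' variances.
The same $D$ formula applied to the difference gives a per-pair
discriminability function; averaging $|D|$ across pairs and over
$\pm 35$ dB, then normalizing to the healthy scenario, gives the population
summary. The population grid ($-44..+44$ dB, 2-dB steps) is symmetric —
required for exact mirroring — and wide enough that the $\pm 35$ dB window
is always covered; it contains 0 so the midline identity
$\mathrm{diff}(0) = 0$ holds on the grid.

## Numerical choices

* **Integration.** Both $V$ and $d$ are conditionally linear in their own
  state, so both are advanced by exponential Euler with coefficients frozen
  at the step start. Synaptic conductances are propagated by an exact
  two-state event-driven update that is algebraically identical to direct
  kernel summation at the grid times (asserted to $10^{-9}$ relative in the
  tests); cost is $O(\mathrm{steps} + \mathrm{spikes})$.
* **Step size.** Default `dt = 0.01` ms. With the synaptic conductances
  handled exactly, only the membrane update depends on `dt`; halving it
  changes tuning-curve rates by well under 1% (a tested invariant), which
  is far below the across-trial sampling error at the trial counts used.
* **Threshold handling.** A spike is assigned to the first grid time with
  $V \ge V_\theta$; no sub-step interpolation (`dt` $\ll \tau_{ex}$).
  Threshold testing resumes exactly at $T_\theta + T_{ref}$; if $V$ is
  still suprathreshold at that grid time a new spike is counted there. The
  alternative (waiting for a fresh crossing from below) is not
  distinguishable in the model's sustained-firing regime, where the spike
  current's hyperpolarizing tail pulls $V$ below threshold within the
  refractory window.
* **Phase-locked sampling.** Thinning against the homogeneous envelope at
  the von Mises intensity peak — exact for bounded intensities; the
  acceptance rate is $I_0(\kappa)e^{-\kappa}$ ($\approx$ 0.24 at 300 Hz).
  The $VS \to \kappa$ inversion brackets the monotone Bessel ratio and is
  cached per target.
* **Random numbers.** One master seed; each (grid point, trial, fiber)
  triple gets its own counter-based splitmix64 substream, so any fiber of
  any trial is bit-reproducible independent of execution order, and common
  random numbers can be shared across scenarios of a sweep.
* **Trial counts.** The published curves use 4000 trials per grid point;
  the package default and the acceptance runs use 500, inflating standard
  errors by $\sqrt{8}\approx 2.8$. Stochastic checks state their
  tolerances accordingly. Problem sizes used by the shipped tests: 31-point
  ILD and 37-point phase grids at 500 trials for the headline statistics;
  coarser grids and 100–300 trials for property checks.

## Worked example

```{r example, eval = FALSE}
library(lsosim)

# healthy neuron: ILD tuning with 500 trials per point
tc <- runTuning("ild", scenario = scenarioSpec(8), nTrials = 500, seed = 1)
midpointIld(tc)        # about -20 dB
modulationDepth(tc)    # about 107 spikes/s

# acute loss of half the inhibitory fibers, no compensation
tc4 <- runTuning("ild", scenario = scenarioSpec(4), nTrials = 500, seed = 1)
midpointIld(tc4)       # shifts towards positive ILDs, about -17.5 dB

# discriminability summary normalized to the healthy scenario
d8 <- summarizeDiscriminability(discriminability(tc), c(-45, 15))
d4 <- summarizeDiscriminability(discriminability(tc4), c(-45, 15))
d4 / d8
```

## Known limitations

* Single compartment; no dendritic placement of synapses, no
  multi-compartment morphology.
* Rate-based statistics only; no spike-timing decoding or ROC analysis.
* The input rate functions stand in for the whole afferent pathway; no
  adaptation or across-fiber correlation.
* Temporal jitter of aged inputs is not modeled, and bilateral changes are
  assumed symmetric.
* The compensation rules are static; no activity-dependent dynamics.
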