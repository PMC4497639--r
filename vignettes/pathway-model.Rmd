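---
title: "Modelling an antennal proprioceptive pathway and its descending coding-space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling an antennal proprioceptive pathway and its descending coding-space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`dinsim` simulates how proprioceptive information about the stick insect's
antennal scape–pedicel (Sc–Pd) joint is encoded by hair-field
mechanoreceptor afferents and re-encoded by a small set of descending
interneuron (DIN) types, and provides the statistics used to place any such
neuron — modelled or recorded — into a two-dimensional *coding-space* of
movement and posture sensitivity.

The pathway has four layers.

## 1. Stimulus

The standard stimulus is a staircase of ramp-and-hold deflections of the
Sc–Pd joint angle: hold at the ventral extreme (−50°), ramp to rest (0°),
on to the dorsal extreme (+50°), and back in the reverse sequence, so each
trial contains two upward and two downward constant-velocity ramps
separated by five holds and is symmetric in space and time. Ramp velocity
is the experimental variable (1–800 °/s of interest; 12–400 °/s for the
quantitative analysis).

Sampling uses a 1 ms grid (`dt = 0.001 s`), the grid on which the spike
generator is defined; samples sit at interval midpoints, which makes the
symmetric trial exactly reversible sample-for-sample and keeps every sample
strictly inside one piecewise-linear segment, so `segment_intervals()`
recovers the generating ramps and holds exactly. The hold duration is not
constrained by the physiology we emulate; the default of 1 s per hold is
long enough to estimate tonic rates at every velocity and short enough to
keep simulations fast. Trials per condition default to `n = 4`.

## 2. Hair-field afferents

Two rows of 20 sensilla each (dorsal and ventral) tile the joint's working
range: hair *i* starts to deflect once the joint has moved
`(i − 1) · 2.5°` onto the row's side, then deflects one-for-one with the
joint (slope 1) up to a shared saturation ceiling of 50°, so only proximal
hairs can saturate and the number of deflected hairs grows linearly with
excursion.

Each hair's deflection drives a lead–lag filter pair — a low-pass
(τ = 10 ms, weight 2) carrying the tonic, position-proportional component
and a high-pass (τ = 30 ms, weight 20) carrying the phasic,
velocity-proportional component — whose weighted sum, minus an offset of
35, divided by 100, is the afferent's activation (an abstraction of its
membrane potential). A sustained 50° deflection settles at
(2·50 − 35)/100 = 0.65; zero deflection sits at −0.35, below the spike
threshold of zero. The offset is subtracted *before* the normalization:
with these constants the reverse order would keep the activation negative
everywhere and silence the model.

Spikes are drawn per 1 ms step with probability
`min(1, max(act, 0) · dt · Rmax)` (Rmax = 300 /s), with an absolute
refractory period of 3 ms: after a spike the next three steps are blocked,
so the minimum inter-spike interval is 4 ms, the attainable rate is capped
at 250 Hz, and constant activation *a* yields the closed-form mean rate
`1/(refractory + dt/p)` with `p = min(1, a·dt·Rmax)` — the oracle the test
suite checks against. All first-order filters use the exact
exponential-integrator update `y += (1 − e^(−dt/τ))(x − y)`, initialized at
steady state for the first stimulus value so protocols that begin mid-hold
start transient-free.

## 3. DIN variants

All DIN types share one input stage: the per-step spike counts of each hair
row are smoothed by the same first-order low-pass primitive (τ = 5 ms),
turning every spike into a decaying postsynaptic potential, and the two row
signals are scaled by weights Wd/Wv and summed. Because this filter has
unit DC gain, afferents firing at total rate R produce a steady input of
about `R·dt`.

* **Simple position-sensitive (SP)** neurons feed `input/4` straight into
  the spike generator (Rmax = 10 /s), firing tonically whenever their hair
  row is deflected.
* **Band-pass variants** pass the input through a series band-pass (LPF
  τ = 50 ms, weight 2, then HPF τ = 40 ms, weight 20), rectify, normalize
  and add an offset. The series cascade has zero DC gain, which is what
  keeps these neurons below threshold during steady holds; a parallel
  lead–lag (the afferent arrangement) would pass DC and make them fire
  tonically at the extremes, contradicting their defining phenotype.
  - **ON-type** (`|b|/20 − 0.2`, Rmax 120): full-wave rectification makes
    both the onset transients (movement away from rest) and the offset
    transients (movement back) excitatory, so the neuron fires during all
    four ramps; the −0.2 offset keeps it silent between movements.
  - **OFF-type** (`1 − |b|/40`, Rmax 30): the same drive inverted, scaled
    by 0.5 and subtracted from a constant offset of 1 — a 30 Hz baseline
    that faster movement suppresses more deeply.
  - **Dynamic position-sensitive (DP)**: the ON architecture fed from one
    hair row only (Wd or Wv zero), movement-sensitive within one half of
    the working range (Rmax 100).
  - **Dynamic extreme position-sensitive (Ex.DP)**: the DP/ON architecture
    without rectification, so only rising afferent activity (movement away
    from rest) excites it.

DIN spike generation uses no refractory period — none is part of the
model's description, and Rmax already bounds the rates.

### Numerical choices with a scientific rationale

**PSP amplitude.** The model's description fixes every filter constant but
not the size of the voltage kick a single afferent spike produces. We use
the low-pass primitive unchanged (impulse peak `1 − e^(−dt/τ)` ≈ 0.18,
unit DC gain). This choice is forced by a signal-to-noise argument: the
band-passed shot noise of sustained afferent firing during extreme holds
scales with the same factor as the movement transients, so no amplitude
rescaling can change their ratio — but the *fixed* thresholds (the ON
offset −0.2 against norm 20) select which of the two regimes dominates.
With amplitudes much above this choice, hold-phase noise crosses the ON
threshold and the movement-selective types fire tonically at the extremes,
which would contradict their defining property (near-perfect motion
selectivity, silence during holds) and collapse the coding-space structure.
The cost is that two softer quantitative anchors come out about a factor
two low: SP neurons fire ~2.5 Hz at the extreme holds (described range:
five to ten spikes per second) and ON-type rates at 400 °/s reach ~55 Hz
rather than Rmax. We consider the selectivity structure the binding
constraint and record the rate shortfall as a known limitation.

**Settle pre-roll.** Afferent filters start at analytic steady state, but
the DIN stage is driven by a point process whose steady state has no closed
form, so pathway simulations prepend 0.5 s of the initial joint angle and
crop it from all outputs; without this the band-pass would see the filter
ramp-up as a spurious movement at t = 0.

**Velocity-tuning window.** `velocity_tuning()` reports the mean rate
during the *movement* (ramp) window for every variant. For OFF-type
neurons a whole-trial mean is intrinsically non-monotone in velocity: the
suppression depth saturates while the ramps occupy an ever smaller fraction
(∝ 1/v) of the trial, so the trial mean rebounds towards the 30 Hz baseline
at high velocity. The movement-window rate is the quantity that declines
monotonically, and the one a declining tuning curve depicts. At the
standard `n = 4` sweeps, the expected suppression difference between 12 and
50 °/s (~1.5 Hz) is comparable to its sampling error, so the package's
tests assert the declining *trend* (slope against log velocity plus the
endpoint contrast) rather than strict ordering of adjacent noisy estimates.

## 4. Selectivity scores and the coding-space

Each neuron is characterized by the signed contrast
`s = (A − B)/(A + B)` of mean spike rates (−1 … 1) for three interval
assignments — **direction** (up- vs down-ramps), **position** (dorsal vs
ventral half of the working range), **motion** (ramps vs holds) — at four
staircase velocities (default 12, 50, 150, 400 °/s, spanning the stated
analysis range; the exact intermediate values are configurable), with
interval rates averaged across `n = 4` trials before scoring. That yields a
12-dimensional selectivity vector per neuron.

Two scoring details matter:

* The position contrast averages its movement and hold component rates
  with equal weight per side (`A = mean(upper-ramp rate, dorsal-hold
  rate)`, likewise for B). The staircase contains two ventral holds but one
  dorsal hold; pooling by time would hand every movement-driven neuron a
  spurious positive position score from the unequal denominators alone,
  which couples the motion and position score blocks and tilts the
  principal axes of the coding-space into each other.
* A score whose contrasted intervals contain fewer than 8 spikes (summed
  across trials) is reported as the neutral value 0 and flagged invalid —
  the same treatment the undefined `A + B = 0` case receives. A signed
  contrast estimated from a handful of spikes is sign-noise (SE ≳ 0.35),
  and at desk scale the weakly driven slow-velocity responses of
  movement-type models would otherwise inject a large incoherent noise
  block into the PCA that has no counterpart in recordings, whose neurons
  fire far more spikes per trial.

`fit_coding_space()` then performs covariance PCA on the centered (not
variance-scaled — all twelve columns already share the [−1, 1] selectivity
scale) neurons × 12 matrix and retains components whose variance fraction
exceeds 1/12 ≈ 8.3%, i.e. more than any single original score
(Kaiser–Guttman). Axis orientation is canonicalized (movement-indifferent
neurons project to positive PC1; dorsal position selectivity is positive on
PC2) so fits are deterministic; PC2 is reported both signed and folded
(`|PC2|`, posture sensitivity regardless of side). Two axis-aligned
separators — a movement threshold on PC1 and a posture threshold on
|PC2| — are fitted as midpoints of the largest inter-group gap and classify
neurons into SP/DP/ON/OFF. `resample_variance()` provides the two
resampling diagnostics (bootstrap of 50; balanced six-per-group then 50).

# The synthetic reference population

The recorded neurons this analysis was designed around are not publicly
available, so `build_reference_population()` generates a *synthetic*
labelled stand-in whose purpose is to reproduce the documented structure of
the recorded sample: a motion-dominated PC1 and position-dominated PC2 with
near-equal variance shares (documented order swaps under resampling), a
tight ON cluster and an OFF stripe each traversed by a single-parameter
model sweep, dispersed SP/DP groups, an unclassifiable movement-indifferent
background group, and ≥ 95% linear separability of the four modelled
groups.

Design choices, fixed once:

* Each modelled group's defining parameter spans the range its
  single-parameter sweep traverses (ON offsets −0.225…0.075; OFF
  normalization 40/divisor, divisor 0.09…1.43), because those sweeps were
  designed to traverse the recorded clusters; a secondary ±10%
  multiplicative jitter perturbs the normalization.
* SP/DP neurons come in exact dorsal/ventral mirror pairs with cross-talk
  weight ratios *stratified* at the midpoints of equal bins of [0, 0.8]
  rather than drawn at random. Bilateral symmetry zeroes the sample
  covariance between the signed position block and the motion block;
  stratification removes the draw-to-draw lottery in position variance.
  Both matter because the two leading eigenvalues are close, so small
  sample covariances otherwise tilt the principal axes into each other and
  degrade the separators.
* Group sizes default to SP 8, DP 8, ON 32, OFF 28, UN 12 (88 neurons).
  The recorded group sizes are not documented; this movement-heavy
  composition is what makes the motion block the leading axis, as
  documented for the recorded sample. The UN ("unspecific") group is an
  input-free constant-rate population (10–40 Hz) mirroring the
  movement-indifferent background group, and gives the balanced resampling
  mode its fifth group.
* The input-free `RANDOM` sweep neuron fires at ~20 Hz (constant
  activation 0.2, Rmax 100); only "random spiking" is specified, not a
  rate.

**What passing tests do and do not show.** The synthetic reference
reproduces group structure, not recorded neurons: variance percentages
(here ≈ 48/33 for PC1/PC2), threshold positions and separator accuracy are
properties of this generator, and agreement with the documented analysis at
the structural level does not validate the model against the actual
recordings, which would require the original data. Real afferents are also
heterogeneous within a hair field, real DINs adapt and fire more regularly
than the Bernoulli generator, and active (self-generated) antennal movement
is outside the model's scope.

# Problem sizes and tolerances

The test suite and the acceptance script run the full pipeline at the study
conditions (1 ms grid, 40 afferents, 4 trials per velocity, four analysis
velocities, 88-neuron reference population, 19-neuron sweep population,
100 resampling repetitions); a complete coding-space analysis takes a few
minutes on one core. Stochastic rate checks use 60 s of simulated time and
3 standard errors. Coding-space geometry checks use a hull dilation of 0.5
(about two standard errors of a single neuron's projection noise for the
lowest-rate group) with at most one of the 19 sweep neurons outside, and an
adjacent-step tolerance of 0.15 on sweep orderings, because two of the ON
sweep's offsets (0 and 0.01) are near-replicates whose expected coordinate
separation lies below single-run resolution.

# Known limitations

* SP extreme-hold rates and ON peak rates sit about a factor two below the
  described values (see the PSP amplitude rationale above).
* Movement-type models are nearly silent below ~25 °/s, so their
  slow-velocity selectivity scores rest on few spikes and are frequently
  neutralized by the evidence floor.
* The 95% separability and the sweep-containment checks sit close to the
  sampling noise of a single 88-neuron realization; some seeds fail them.
* Band-pass transients decay over ~100 ms after each ramp, spilling a few
  spikes into the start of each hold; steady-hold measurements therefore
  exclude the first 0.3 s after movement offset.
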