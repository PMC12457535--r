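---
title: "A forward neuromusculoskeletal model of isometric dorsiflexion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A forward neuromusculoskeletal model of isometric dorsiflexion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`nmspool` simulates the chain from decomposed motor-unit (MU) discharge
times to whole-muscle isometric dorsiflexion force:

1. **Spike trains.** Decomposed MU discharge times are quality-filtered
   (pulse-to-noise ratio above 29 dB; interspike intervals outside
   20–250 ms flagged as decomposition artifacts), merged into the
   cumulative spike train (CST), and smoothed into a neural-drive
   estimate.
2. **Common synaptic input (CSI).** The drive shared by all motoneurons
   is the weighted average of the normalized trapezoidal force target and
   the normalized smoothed CST rate, with weights 0.90 and 0.20.
3. **Motoneuron pool.** 200 reduced compartmental motoneurons with soma
   diameters spanning 48.8–99.7 µm are integrated under the common drive
   plus independent bounded Gaussian noise (±1 nA); recruitment follows
   the size principle.
4. **Muscle activation.** Each motoneuron's spikes drive a calcium
   release/reuptake system; a saturating function of sarcoplasmic calcium
   yields activation in [0, 1], aggregated per fiber type (I/IIa/IIb,
   73/21/6% of fibers).
5. **Force.** A lumped Hill-type muscle (contractile element plus series
   elastic element, isometric) converts fiber-type activation to force in
   newtons, calibrated to the subject's maximal voluntary contraction
   (MVC).
6. **Metrics.** Steadiest-window force STD and CoV, RMSE and R² against a
   reference trace, windowed CST variability, ISI CoV, z-score median
   correlations and variability t tests.

A synthetic-data module emulates the decomposition output of a recording
session so the full pipeline is testable without any experimental data,
and a ±20% perturbation protocol over a 37-parameter registry quantifies
the sensitivity of discharge rates and activation to the physiological
constants.

# The motoneuron model

Each motoneuron is a chain of four compartments: a lumped dendrite, the
soma, the axon hillock and the initial segment. Channel kinetics are
Hodgkin–Huxley-style with parameter values in the range of published
mammalian spinal motoneuron models:

* dendrite: leak, L-type calcium (a persistent inward current) and a
  calcium-dependent potassium current fed by a dendritic calcium pool;
* soma: leak, fast sodium, delayed-rectifier potassium, N-type calcium
  and the calcium-dependent potassium (AHP) current that sets the steady
  discharge rate;
* hillock and initial segment: leak, delayed rectifier, fast and
  persistent sodium, with the highest sodium density in the initial
  segment, which is therefore the spike initiation zone where spikes are
  detected (upward 0 mV crossing, 1 ms lockout).

**Size scaling.** Membrane area grows with the square of the soma
diameter, so total conductance and capacitance scale with `d²`. On top of
this, conductance *densities* are graded with size
(`(d/d_min)^κ`): small motoneurons have a higher specific membrane
resistance, as in real pools where the rheobase range (roughly 10–40×)
far exceeds the input-conductance range (~4×). The default grading
realizes a rheobase span of about 10. Without it, recruitment compresses
into the top quarter of the drive range while twitch amplitudes are
exponentially distributed over a 100-fold range, and the pool's
force–drive curve becomes a steep power law that cannot track a
trapezoidal target. The recruitment-order property (smaller soma first,
Kendall τ = 1 under a slow ramp) holds with or without the grading.

**Numerics.** Voltages use exponential-Euler updates (conductances frozen
over the step), which remain stable at the ~350 mS/cm² sodium density of
the initial segment where the membrane time constant during the spike
upstroke is far below any practical step. Gates use exact exponential
relaxation, arranged as a Strang split around a predictor–corrector
voltage update that re-evaluates instantaneous activations and the
compartment coupling at midpoint voltages. While any excitable
compartment is above −55 mV the step is refined 16-fold, so the spike
shape and the per-spike calcium influx (which sets the AHP charge and
hence the firing phase) are integrated on a fine grid. With the default
macro step of 0.025 ms, halving the step moves spike times by well under
0.5 ms over multi-second simulations at typical discharge rates (phase
drift accumulates with spike count, so very fast units converge more
slowly); this convergence is enforced in the test suite. Voltage-dependent gate factors come from lookup tables (0.05
mV resolution, linear interpolation) that depend only on the step size,
never on the perturbable channel parameters.

**Gain calibration.** The synaptic gain (nA per unit drive) is set by
bisection so the largest motoneuron is recruited exactly at drive 1 —
i.e. at the plateau of the 60 %MVC trapezoid the pool is just fully
recruited. The calibration is deterministic and cached per session.

# Calcium activation and the Hill muscle

Per motor unit, a three-state linear system models excitation–contraction
coupling: a release gate `s` opened by each spike and closing at rate
`k2`, sarcoplasmic calcium `c` fed at rate `k1·s`, cleared by a pump with
time constant `tau_reuptake` and exchanging with a bound buffer pool `b`
at rates `k5` (binding) and `k6` (release). The buffer exchange is fast
(defaults `k5 = 3/s`, `k6 = 10/s`) so the muscle reaches a steady
operating point within a few hundred milliseconds; a slow buffer would
make force creep through the plateau and leave a hysteretic excess on the
down-ramp. Because the system is linear, it is advanced by exact
matrix-exponential steps (spikes binned at 1 ms), and the single-spike
response can be checked against an independent ODE solution to 10⁻⁶.

Activation is a Hill function `c^n / (c^n + K^n)`, clamped to [0, 1].
Fiber types IIa and IIb use time constants scaled by 0.6 and 0.4 relative
to type I, so fast fibers have faster, less fused calcium dynamics.
Fiber-type activation is the twitch-scale-weighted mean over that type's
units; muscle force is

```
F_ce = f_max * sum_type( gain_type * massfrac_type * a_type )
```

passed through a first-order series-elastic stage (10 ms). Mass fractions
default to the fiber-count shares (73/21/6%), i.e. each motoneuron group
drives a muscle-volume share proportional to its type's fiber fraction.

**MVC calibration.** Two constants are closed-loop calibrated from steady
pool simulations: the Hill constant `K` (and exponent `n`, chosen among a
small candidate set) such that the force at drive 1 (the 60 % plateau) is
0.60 of the force at the saturating drive 1/0.6, and `f_max` such that
the saturating force equals the subject's MVC in newtons. Among the
`(n, K)` roots that satisfy the 0.6 ratio, the calibration picks the one
whose force–drive curve is most proportional (checked at drives 0.5 and
0.75): the intact system produces force roughly proportional to its
common drive, which is what lets an open-loop trapezoidal drive reproduce
a trapezoidal force record. With the defaults this yields ramp tracking
with R² ≈ 0.95 against the target-shaped reference while retaining a 40%
force reserve above the 60% plateau.

# The synthetic-data generator

The generator emulates what a decomposition session delivers for one
trial: 11–20 MUs with recruitment thresholds skewed toward low forces
(`0.75 · level · u^1.5`), linear rate coding from 8 pulses/s at
recruitment with 0.4 pulses/s per %MVC, clipped to 4–35 pulses/s, and
gamma-renewal interspike intervals with shape `1/CoV²` (default CoV
20%), resampled into the 20–250 ms band so every generated train passes
the default quality filter. Derecruitment mirrors recruitment on the
down-ramp. The synthetic "experimental" force is the target plus
band-limited (≤3 Hz) multiplicative Gaussian noise with a plateau CoV
dial (default 1.24%). The default MVC force is 170 N, a typical adult
isometric dorsiflexion maximum; at the 60% level this puts the plateau
near 102 N.

**What the generator does not emulate.** The trains of different
synthetic MUs are *independent* renewal processes: their only shared
structure is the common trapezoid-following mean rate. Real decomposed
MUs additionally share low-frequency common-drive fluctuations — their
smoothed rates co-vary, which is precisely why the cumulative spike train
estimates the common input. The consequence is quantitative and worth
stating plainly: for independent renewal trains the smoothed CST-rate
fluctuation scales like `CoV_ISI / sqrt(spikes per filter window)` (about
2% here), enters the CSI with weight 0.2/1.1 ≈ 18%, and is further
attenuated by the calcium and series-elastic low-pass, predicting a
plateau force CoV of a few tenths of a percent — which is what the
pipeline measures on synthetic cohorts. Pipelines driven by real decompositions inherit the
(non-averaging) common fluctuation of the biological drive and show
plateau force CoV severalfold larger, of order 1%. Passing tests on
synthetic cohorts therefore validate the machinery and the noise
cancellation property, not the absolute force-steadiness level of real
recordings.

# The common input and its weights

The CSI applies the weights 0.90 (target shape) and 0.20 (smoothed CST
rate) literally to the two peak-normalized series and rescales the sum to
peak 1, so the weights set relative contributions only. The CST rate is
smoothed with a linear-phase FIR (Hamming design, order
`2·fs/cutoff`, unit DC gain, centered convolution so peaks are not
shifted); the cutoff is not a reported constant, and the package default
is 2 Hz — comfortably above the fluctuation band that drives force
steadiness and below the individual-MU discharge rates. Per-neuron noise
is Gaussian with σ = bound/3, truncated hard at ±1 nA, regenerated at
100 Hz and held between updates (band-limited, like synaptic noise);
each neuron draws an independent substream derived from the global seed,
so adding a neuron never perturbs another's stream.

# Time compression

Simulations compress the trapezoid to 2 s ramps and a 3 s plateau
(ramp-and-hold shape preserved), and the steadiest-window width scales
accordingly: 1 s for simulated records versus 6 s for full-length
experimental records. For agreement metrics between a compressed
simulation and a full-length reference, the ramp start/end landmarks
anchor a piecewise-linear time warp; plain duration normalization would
misalign the segments because compression changes the ramp/plateau
proportions.

# The sensitivity protocol

The registry exposes 37 scalar parameters — membrane capacitance, leak,
sodium, potassium and calcium conductances and reversal potentials per
compartment, plus the five neuromuscular-junction constants (`k1`, `k2`,
`k5`, `k6`, `tau_reuptake`); 16 are flagged as influential on model
outputs. Each sweep multiplies one parameter by `1 + level/100` over
levels −20% to +20% in 5% steps. Reversal potentials are perturbed
multiplicatively on the signed millivolt value (−80 mV at +20% becomes
−96 mV), so a "+20%" potassium-reversal perturbation hyperpolarizes and
slows firing. Every level of a sweep re-simulates the pool with the
*identical* CSI and noise realization (common random numbers), so deltas
reflect the parameter alone; NMJ parameters reuse the baseline pool
spikes and re-run only the calcium stage. Outcomes are percent changes,
versus baseline, of the mean pool discharge rate and the mean fiber-type
activation over the plateau window. A level whose simulation fails is
reported missing, never zero.

Reduced problem sizes are the package's own defaults for this protocol
and for cohort experiments: multi-subject cohort runs use a 0.05-ms macro
step (spike-time shifts of a few tenths of a millisecond are irrelevant
to windowed force statistics), and sweeps use a 50-neuron pool with
proportionally apportioned fiber types and a
1 s–2 s–1 s trapezoid, keeping a full soma + NMJ sweep set within minutes
while preserving every direction the full pool shows (conductance up →
discharge down; sodium reversal up → discharge up; NMJ rate constants
moving type I/IIa activation almost linearly, type IIb with visibly
larger dispersion because only a handful of neurons drive it).

# Numerical and design choices, in brief

* Population STD (`ddof = 0`) everywhere a variability statistic is
  computed; fixed for reproducibility.
* CST windows: contiguous, non-overlapping, anchored at the region
  start; trailing partial windows dropped.
* ISI CoV is computed per MU over a region by default; out-of-range ISIs
  are excluded from statistics rather than discarding the whole train
  unless fewer than 10 valid ISIs remain.
* Steadiest-window search: one-sample stride, earliest tie wins, O(n)
  via cumulative sums.
* t tests on variability metrics default to one-tailed Welch
  (simulated < experimental), the convention consistent with reporting a
  negative t statistic for steadier simulations; two-tailed and paired
  variants are exposed.
* Correlation of CST variability across subjects: condition-wise
  z-scoring, per-subject medians, Pearson (Spearman exposed).
* The whole pipeline is deterministic given the config seed; with the
  noise bound set to zero it is bit-reproducible by construction.

# Known limitations

* The reduced four-compartment morphology reproduces recruitment order,
  rate coding and the sensitivity directions, but absolute discharge
  rates differ from detailed-morphology motoneuron models; small units
  can exceed 35 pulses/s near maximal drive.
* Isometric only: no force–velocity effects, pennation, tendon geometry
  or fatigue.
* The plateau force variability of synthetic cohorts reflects only
  independent-renewal fluctuation (see the generator section); absolute
  force-steadiness comparisons against real recordings require real
  decomposed inputs.
* Persistent-inward-current hysteresis leaves a modest force excess on
  the down-ramp relative to a symmetric target; this is physiological
  (derecruitment thresholds are lower than recruitment thresholds) but
  slightly lowers R² against a perfectly symmetric reference.
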