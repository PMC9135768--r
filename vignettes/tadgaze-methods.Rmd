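---
title: "Models and methods behind tadgaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tadgaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tadgaze)
```

This vignette is the package's own account of what it computes: the
circuit model and the choices behind its parameters, the trace-analysis
conventions, the synthetic-data generator, and the limitations of each.
Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The circuit model

### Architecture

Fourteen single-compartment neurons, seven per side: the swim CPG (dIN,
cIN, spMN), the efference-copy relay (EC), the vestibular inputs (VO,
VS) and the extraocular output (Abd MN).  Wiring (per side, mirror
symmetric):

* dIN → ipsilateral cIN and spMN (AMPA-like), dIN → dIN recurrent AMPA
  and NMDA (Jahr–Stevens magnesium block at 1 mM);
* cIN → contralateral dIN, cIN, spMN (GABA/glycine-like, reversal
  −75 mV);
* spMN → ipsilateral EC; EC → contralateral Abd MN;
* VO → contralateral Abd MN; VS → ipsilateral spMN and EC;
* a rhythmic inhibitory event train (10 Hz, two-exponential conductance
  with tau1 = 0.5 ms, tau2 = 100 ms) onto each VO whose maximal
  conductance is scaled by the logistic gate
  `gGABA_max = num_syn_inh · unitary_gGABA · sigmAmp · logistic(sigmSteep · (iCPG − iTrans))`,
  with `iCPG` the mean step current into the two dINs and `iTrans =
  0.16 nA`.  The gate acts only through this synapse; VS is untouched.

### Membrane dynamics

All neurons use classic squid-axon Hodgkin–Huxley kinetics (resting
near −65 mV) with template-specific scaling of capacitance and
conductances: `dIN` (8 pF), `MN` (10 pF; spMN, cIN, EC, Abd MN) and
`vest_spin` (5 pF; VO, VS).  The small vestibular template makes the
default 0.1 nA sinusoidal drive fire VO/VS only during its depolarizing
half-cycle, the phase-coupled discharge expected of a vestibular
afferent relay.  Spike detection is the upward crossing of 0 mV with a
2 ms refractory period — unambiguous on HH waveforms.

### How the rhythm is generated, and why these dials

The published description of this circuit names the ingredients (HH
templates, recurrent dIN excitation, commissural inhibition) but not the
parameter values, so the rhythm-generating mechanism is this package's
own design, calibrated to the printed current-to-frequency anchors
(0 nA → no rhythm, 0.13 → 6 Hz, 0.15 → 7 Hz, 0.16 → 8 Hz, 0.3 → 12 Hz,
each within ±0.5 Hz; `scripts/calibrate_model.R`):

* **Burst termination** comes from spike-triggered adaptation in dIN (a
  potassium-like conductance incremented at each spike).  Two components
  are used: a fast one (5 nS, tau 70 ms) whose recovery time sets the
  concave low end of the frequency–current curve, and a slow one
  (0.52 nS, tau 500 ms) whose firing-rate-proportional accumulation
  linearizes and caps the high end near 12 Hz.  A single-timescale
  adaptation could not reproduce both the steep rise above rheobase and
  the shallow approach to 12 Hz.
* **Side switching** is post-inhibitory rebound: the commissural
  inhibition decays quickly (tau2 = 15 ms), so when the active side
  stalls on its adaptation the released side rebounds and takes over.
  Slow inhibition (≥ 20 ms) produced winner-take-all or period-doubled
  regimes at high drive.
* **A tonic dIN background drive** (66 pA) positions the curve on the
  current axis so that rheobase sits just below 0.13 nA.  Classic HH
  membranes are bistable near rheobase; the background drive is the
  clean way to place the oscillation threshold without distorting the
  spike shape.
* Recurrent dIN AMPA (3 nS) and NMDA (2 nS) support burst depolarization
  but are deliberately weak: strong recurrent excitation produced
  runaway tonic firing that no adaptation could terminate.
* dIN → spMN uses a slower EPSP (tau2 = 30 ms) so each dIN impulse
  drives a ~3-spike motoneuron burst.  Multi-spike bursts are what makes
  burst *amplitude* a graded quantity that the VS input (0.25 nS,
  tau2 = 15 ms, deliberately subthreshold) can modulate; single-spike
  bursts are all-or-none.

### Integration

Fixed-step semi-implicit update at 0.025 ms: gating variables advance by
their exact exponential relaxation at frozen voltage, the membrane
equation is implicit in the conductances.  Non-finite state aborts with
an error naming the step size.  The simulation is fully deterministic
for a fixed configuration (the optional jitter of the 10 Hz inhibitory
train is off by default); identical runs give bit-identical spike times.
A 5 s simulation of the full network takes on the order of a second.

### Measurement conventions on simulated traces

Motoneuron output is quantified the way nerve recordings are: the
membrane potential above its sub-threshold floor is rectified and
integrated (15 ms moving average, two iterations), burst peaks are
detected at mean + 1 SD with a 55 ms minimum separation, and the swim
frequency is the mean reciprocal inter-burst interval.  The 55 ms
separation merges the two envelope maxima that a ~3-spike burst can
produce while still resolving rhythms up to ~15 Hz.  Abducens modulation
depths across vestibular cycles are measured against a rolling
lower-decile envelope floor (0.25 s window): the baseline modulation is
the range of that floor, the burst-amplitude modulation the range of
peak heights above it.  A per-burst flanking-trough baseline breaks down
when bursts crowd at 10–12 Hz; the rolling floor does not.

## 2. Trace analysis

* **Filtering.** Angular traces are low-passed at 20 Hz (4th-order
  Butterworth, zero-phase `filtfilt`).  Nerve discharge is rectified and
  integrated with a 25 ms boxcar (one iteration); "time constant" is
  read as the boxcar window width, matching a moving-average tool, not
  an RC filter.  Boxcar edges use reflect padding.
* **Cycle segmentation.** A swim cycle starts at a hysteresis-qualified
  departure from the null (head-axis) angle: the trace must first fall
  below −1° and then rise above +1° (Schmitt trigger).  The 1° default
  absorbs frame noise; it is a parameter.
* **Angle and phase conventions.** Eyes are conjugate and counter-rotate
  with respect to the tail, so the compensatory eye signal is `−eye`
  when correlated with the tail (configurable sign).  Spino-ocular phase
  is the cross-correlation lag between compensatory eye and tail within
  ±half a cycle, in degrees of the swim cycle, lags positive.  For
  sinusoidal reflex fits (`sinusoid_response_fit`), a response equal to
  the recorded stimulus trace has gain 1 and phase 0°, leads positive —
  the convention that makes "phase lead of the response re stimulus"
  directly readable.  Gains are full peak-to-peak ratios, so the
  half-range/full-range ambiguity cancels.
* **Eccentricity.** Per-cycle mean eye positions (cycle-mean, not
  mid-excursion; the alternative is one line to change) interpolated by
  monotone cubic splines (`monoH.FC`) onto the full time base, clamped
  at the boundary cycles.  Removing it from the eye trace leaves the
  fast swim-locked component.
* **Modulation depths.** Δeccentricity is the range of the slow
  component; Δmagnitude is the peak-to-peak swing of the
  vestibular-locked variation of the per-cycle eye amplitude, obtained
  from a sinusoid fit at the stimulus frequency to the per-cycle
  amplitude series.  The fit, rather than a raw max − min, keeps the
  estimate unbiased by frame noise (a raw range is inflated by the
  noisiest cycle) and by the episode on/offset ramps; cycles overlapping
  the first and last 0.3 s are excluded.  Both require ≥ 4 vestibular
  cycles.  With the default 0.5° noise, zero-depth traces report a
  noise floor below ~1° on both metrics (asserted in the tests).
* **Drift screen.** A trace fails when the linear trend exceeds 2°/s or
  more than half the (mean-removed) spectral power lies below a quarter
  of the stimulus frequency; both thresholds are parameters.  This
  operationalizes the exclusion of traces with obvious
  stimulus-unrelated positional drift.
* **Down-sampling** to 500 Hz uses linear interpolation after a
  protective low-pass at 0.45 of the target rate, mirroring the
  interpolation-based rate reduction used for spike recordings before
  spectral analysis.

## 3. Spectral analysis

The FFT stage ranks local maxima of the amplitude spectrum in
0.5–16 Hz, requiring 4× the median in-band amplitude (so white noise
yields no candidates).  The wavelet stage is a continuous Morlet
transform (center frequency 6, scale step 1/20 octave, FFT convolution
with zero padding); no wavelet package ships with standard R
environments, so the transform is implemented here in the standard
Torrence–Compo formulation.  The cone of influence (e-folding time
√2·scale) is excluded from all significance decisions.

Significance uses white-noise surrogates matched in length and variance
(the variance-matched white-noise null of the wavelet packages used for
this kind of analysis; an AR(1) null would be the natural extension).
Because wavelet power of white noise is stationary in time, the per-cell
null at each frequency pools surrogate cells across time (30
surrogates), giving a calibrated per-cell false-positive rate; the
periodogram peak test uses the distribution of surrogate *time-averaged*
power (all `n_surrogates`).  Periodogram peaks are local maxima of mean
power exceeding that quantile.  Fixed seeds make masks reproducible.

## 4. Circular statistics

`mean_vector` is the first trigonometric moment; `rayleigh_test` uses
`Z = n r²` with the standard series approximation of the p-value (its
type-I error at α = 0.05 is verified at 5% ± 1.5% over 2000 seeded
uniform replicates).  Moore's Modified Rayleigh statistic ranks the
per-animal vector lengths and weights their directions by rank
(`R* = |Σ rankᵢ·(cos θᵢ, sin θᵢ)| / n^{3/2}`); since the exact published
critical-value tabulation in circular-statistics software varies, the
p-value is computed by seeded Monte Carlo under the uniform-direction
null with the observed lengths held fixed — reproducible and accurate to
the table's printed precision.  The Hotelling two-sample test compares
group mean Cartesian components with the pooled-covariance T² mapped to
an F(2, n₁+n₂−3); a degenerate pooled covariance raises an explicit
"inconclusive" error instead of returning a silent p-value.  Angles are
degrees externally, radians internally.

## 5. The synthetic-data generator

The generators produce what the analyses assume and nothing more: an
enveloped sinusoidal tail oscillation (raised-cosine 200 ms on/offset
ramps — a synthetic-only choice that avoids spectral edge artifacts),
conjugate counter-rotating eye traces with configurable gain, phase lag
and eye-amplitude mode, a vestibular-frequency amplitude modulation
(peak-to-peak range = the configured Δmagnitude) and eccentricity
carrier (range = Δeccentricity), Gaussian frame noise (0.5° default),
and Poisson-burst nerve discharge convolved with a biphasic waveform.
Stage presets encode printed quantities only — swim frequencies (13, 10,
6, 6 Hz for stages 48, 49, 52, 58), gains (0.74 invariant at stage 49,
0.4 proportional at stage 58), modulation depths (e.g. Δeccentricity
12.09° at stage 58), the 1 Hz ± 10° vestibular stimulus — anything else
(noise, envelope, tail amplitude ramp) is labelled synthetic-only.  All
randomness flows from explicit seeds.

What the generator does **not** emulate: saccade-like quick phases,
directional asymmetries, amplitude drift within episodes beyond the
linear ramp option, non-stationary swim frequency, torsional eye
components, or realistic tail biomechanics.  Passing parameter-recovery
tests therefore demonstrates the estimators' correctness on data
matching their assumptions, not robustness to every artifact of video
tracking.

## 6. Problem sizes and tolerances

The shipped tests run the network for 5 s per protocol (deterministic;
anchors checked at ±0.5 Hz), a 10-point current grid for the gating
scan, 10 s / 500 Hz synthetic episodes for kinematics (gain ±0.05,
phase ±5°, modulation depths ±15%), 100 surrogates for spectral
significance with the false-positive rate averaged over four noise
realizations (±2 percentage points), and 2000 replicates for the
Rayleigh calibration.  These sizes keep the full suite under two
minutes on a single core while leaving every tolerance comfortably
slack relative to the estimators' observed spread.

## 7. Known limitations

* One spinal segment, one neuron per population: no axial phase lags,
  no population variability; the model reproduces the printed
  input–output mapping, not biophysical detail.
* The frequency–current calibration is specific to the shipped
  membrane/synapse configuration; changing any rhythm-relevant
  parameter requires re-running `scripts/calibrate_model.R`.
* VO silencing begins slightly below `iTrans` (the partially open gate
  already suppresses the small vestibular cells); above `iTrans` it is
  complete, as specified.
* The Morlet scale quantization (1/20 octave) limits frequency readouts
  to ~3.5% relative precision; periodogram peak frequencies inherit it.
* The surrogate null is white noise; strongly autocorrelated background
  (e.g. slow drift that survives the screen) inflates low-frequency
  significance and should be handled with the AR(1) extension.
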