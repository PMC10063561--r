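---
title: "Methods: simulating and analysing ring bioimpedance for cuffless blood pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing ring bioimpedance for cuffless blood pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biozbp)
```

## The measurement problem

Finger bioimpedance plethysmography senses the arterial pulse electrically:
a tetrapolar electrode set injects a small 10 kHz current and measures the
voltage across a sensing pair. Each systole pushes blood into the digital
artery, the conducting cross-section grows, and the tissue impedance drops
by a fraction of an ohm; during diastole it recovers. The impedance beat
has four phases: a fall from the diastolic peak to the systolic bottom, a
rise as blood leaves the sensing volume, a secondary dip when the reflected
pressure wave arrives, and a final recovery. Features of this waveform
correlate with systolic (SBP) and diastolic (DBP) pressure through the
arterial pressure–volume relation, which this package models as the
exponential compliance law

$$dV = C_0\, e^{-\alpha P}\, dP,$$

i.e. instantaneous compliance $C(P) = C_0 e^{-\alpha P}$ falls as the
stretched wall stiffens. The closed-form antiderivative
(`compliance_transform()`) is

$$V(P) = V_{\mathrm{ref}} + \frac{C_0}{\alpha}
  \left(e^{-\alpha P_{\mathrm{ref}}} - e^{-\alpha P}\right),$$

with the linear limit $V = V_{\mathrm{ref}} + C_0 (P - P_{\mathrm{ref}})$
at $\alpha = 0$. Defaults are $C_0 = 0.05$ mL/mmHg and
$\alpha = 0.02$ /mmHg — physiologically plausible placeholder magnitudes,
deliberately configurable because no canonical values exist for the digital
artery at this scale.

## The synthetic generator and what it does (not) emulate

All tests run against a forward simulator with known ground truth:

* **Pressure trajectories** (`generate_bp_trajectory()`): ordered protocol
  segments (baseline, cold-pressor rise, recovery) with per-segment SBP/DBP
  targets. Rises are sigmoidal, recoveries exponential
  ($\approx 95\%$ settled by segment end); beats get Gaussian pressure noise
  (default SD 1.5 mmHg). Inter-beat intervals are $60/\mathrm{HR}$
  modulated by a respiratory sinusoid (depth 3%, 0.25 Hz) plus Gaussian
  jitter (default SD 20 ms). Defaults span roughly 120–165 mmHg SBP, the
  range a cold-pressor protocol elicits.
* **Beat morphology** (`pressure_waveform()`): a raised-cosine systolic
  upstroke peaking at 15% of the beat, a raised-cosine decay, and an
  additive raised-cosine reflection wave (centre 45% of the beat, width
  30%, amplitude 15% of pulse pressure). The decay is deliberately
  *incomplete* (`decay_completeness = 0.85`): the next upstroke truncates a
  still-falling diastolic tail, producing the sharp "foot corner" of real
  arterial pulses. A fully completed raised cosine would leave the pressure
  minimum with zero slope on both sides, making the diastolic impedance
  peak physically ill-localized under any band-limited acquisition; real
  pulses do not look like that. The waveform is rescaled so its minimum and
  maximum are exactly DBP and SBP, and construction errors out if the
  reflection wave would overtop the systolic peak.
* **Sensor model** (`modulate()`): impedance couples linearly and
  negatively to arterial volume ($z = z_0 - g\,V$, first-order
  conductor-volume model), rides on a slow sinusoidal drift (default period
  60 s, below the 0.05 Hz band edge so the band-pass provably removes it),
  is multiplied onto the 10 kHz carrier, and is sampled at 93,750 Hz with
  white voltage noise. The reference-pressure beat stream is emitted with
  an injected integer beat offset (and optional dropout) so the
  synchronization stage has something real to do.

The generator does **not** emulate motion artifacts, electrode-contact
changes, arrhythmias, multi-artery geometry, or PPG optics. Passing tests
therefore demonstrate correctness of the algorithms under the stated model,
not clinical performance on human recordings.

### Ground-truth fiducials and the acquisition band

Ground-truth fiducial times are located on a fine (1 kHz) noise-free grid
of the generator's impedance waveform **after** zero-phase filtering to the
canonical 0.05–6 Hz pulsatile band (`ground_truth_fiducials()`). The
unfiltered waveform's diastolic plateau is flat enough that its argmax
moves by tens of milliseconds under any band-limited acquisition, so
"truth" for a detector that, by design, operates after the conditioning
chain is the band-limited clean waveform. This separates two questions the
tests answer independently: how faithfully the chain reproduces the
waveform (bounded as envelope RMSE), and how accurately the detector reads
the waveform it is given (bounded in working-rate samples).

## Signal conditioning

`iq_demodulate()` multiplies the record by in-phase and quadrature carrier
copies, low-passes both, and returns $2\sqrt{I^2+Q^2}$ — phase-invariant,
so carrier phase never needs to be known. The low-pass/decimation chain
runs in stages (factor ≤ 25 each, 4th-order Butterworth per stage, final
cutoff 20 Hz, output 250 Hz): a single 4th-order filter at 20 Hz relative
to 93,750 Hz would have poles too close to the unit circle for reliable
transfer-function arithmetic. The demodulator clamps its first/last few
settling samples (6 time constants of the final stage) to the adjacent
settled value so downstream filters never see the startup transient.

`bandpass_waveform()` applies the canonical 2nd-order Butterworth band-pass
(0.05–6 Hz) forward–backward (zero phase, so fiducial timings are not
skewed) with odd-reflection end padding — the standard remedy for the
long transient of the 0.05 Hz pole. The first and last 10 s are flagged as
settle regions and excluded from beat analysis. Design choices the
acquisition convention leaves open (demodulation cutoff, decimation,
padding, settle length) are explicit parameters with these defaults.

## Beat analysis

`segment_beats()` estimates the dominant period from the autocorrelation
(first prominent peak, threshold 0.2 — below it the record is declared
beatless rather than erroring), detrends with a one-period running mean so
residual drift cannot bias the peak threshold, picks local maxima at least
0.4 periods apart (greedy by amplitude, threshold 0.3 of the upper-decile
peak height), and refines each peak on the undetrended waveform. Beats are
the half-open intervals between successive diastolic peaks.

`normalize_beat()` resamples each beat to L = 100 points (time
normalization by the beat's own IBI), subtracts the first sample (diastolic
peak at the origin) and scales by peak-to-foot depth. The ensemble metrics
(`ensemble_stats()`) are: mean positionwise across-beat SD; spectral SNR
(largest periodogram peak in 0.5–3 Hz, signal power within ±0.05 Hz of it,
noise floor = median bin power elsewhere in 0.05–6 Hz); and mean dynamic
time warping distance of each beat to the ensemble mean.
`ensemble_stats(amplitude = FALSE)` computes the SD on time-normalized but
amplitude-preserved beats, since either convention is defensible for
configuration comparisons. DTW (`dtw_distance()`) is the classic dynamic
program with absolute-difference cost and steps {(1,0), (0,1), (1,1)}; the
tests verify it against an exhaustive-path shortest-path oracle.

`synchronize_beats()` matches the bioimpedance and reference IBI series by
the integer lag maximizing their Pearson correlation (lags ±20, minimum
overlap 8 beats); pairs with relative IBI mismatch above 10% are dropped
and a best correlation below 0.5 is reported as unsynchronizable rather
than guessed.

## Features

`detect_fiducials()` uses the canonical definitions: diastolic peak at the
segment start; systolic foot = global minimum within the first 60% of the
beat (a deeper minimum later in the cycle flags the beat as malformed);
maximum-slope point = most negative derivative between peak and foot;
inflection point = first second-derivative zero crossing after the foot.
Derivatives are taken on a 5-point moving-average smoothed copy.

`extract_features()` returns the 15-feature descriptor: amplitudes of the
peak, foot and inflection point relative to the maximum-slope-point value;
slope transit time STT = (peak + foot amplitude)/|max slope| (the standard
pulse-wave-velocity proxy); the five fiducial-interval times plus total
beat duration; the derivative at the maximum-slope and inflection points;
and trapezoidal areas (peak→foot, foot→next peak, whole beat) referenced to
the foot value so all areas are non-negative. The total pulse excursion
(peak + foot amplitude) is exposed as a 16th, non-counted column
`delta_bioz`. `smooth_windows()` averages features and reference pressures
over 10-beat windows advancing 5 beats (50% overlap). The order of
operations is synchronize → extract → smooth.

## Pressure regression and evaluation

`adaboost_r2()` implements AdaBoost.R2 with linear loss over `rpart`
regression trees (squared-error splits, depth 5, `cp = 0`,
`minsplit = 2`, `minbucket = 1`; 50 rounds). Case weights enter the tree
fit directly — the deterministic weighted-fit variant — so training needs
no random stream and repeated fits are identical; the only randomness is
the seeded shuffle before the 5-fold split (`fit_predict_kfold()`).
Predictions aggregate by the stage-weighted median. Boosting stops early on
a perfect round or when the weighted loss reaches 0.5.

`loso_evaluate()` trains on all-but-one subject and, with
`bp_calibration_spec("single_value_offset")`, shifts all of the held-out
subject's predictions by the reference-minus-prediction offset at one
designated sample, which is then excluded from scoring. The calibration
sample defaults to the *first* sample (an enrolment reading is the
clinically realistic choice); `calibration_beat = "last"` is also
supported. `grade_bp_errors()` applies AAMI (|ME| ≤ 5 mmHg and error
SD ≤ 8 mmHg) and the BHS cumulative fractions within 5/10/15 mmHg
(A ≥ 60/85/95%, B ≥ 50/75/90%, C ≥ 40/65/85%).

## Electrode sensitivity by reciprocity

For point electrodes on a homogeneous half-space the current density is
analytic, $J(r) = (I/2\pi)\,[(r-a)/|r-a|^3 - (r-b)/|r-b|^3]$, and the
volume impedance density follows from reciprocity:
$\mathrm{VID} = \rho\,(J_v \cdot J_s)/I^2$ with the sensing pair driven
reciprocally. Its half-space integral equals the tetrapolar transfer
impedance, for which the closed form
$Z = (\rho/2\pi)[1/d_{AM} - 1/d_{AN} - 1/d_{BM} + 1/d_{BN}]$ is the
independent oracle (Wenner spacing 10 mm, $\rho = 1\ \Omega$m:
15.915 $\Omega$).

`vid_volume_integral()` uses a midpoint rule on tan-mapped coordinates
($x = s\tan u$ per axis), which covers the infinite half-space with
resolution concentrated near the array; 0.5 mm exclusion balls skip the
electrode singularities (the excluded contribution is $O(\varepsilon^2)$
because the reciprocal lead field is tangential at the surface, where the
injected field is radial). Grid scales are tied to the array extent (0.4
and 0.2 of the maximum separation for xy and z), which keeps single-level
error well below 1% at n = 140 cells/axis across spacings; Richardson
extrapolation was evaluated and rejected because the exclusion-ball
quantization makes level errors non-monotone.

The three ring configurations (`ring_configuration()`) place the sensing
pair over the artery in line with the injection pair (Config 1), split the
pairs to either side of the artery (Config 2, ±3 mm lateral), or orient
both pairs across the artery (Config 3); within-pair spacing is 2 mm and
the pair separation is the swept parameter. Exact lateral offsets are
package assumptions, exposed as arguments. On this planar surrogate the
in-line configuration dominates and sensitivity decays monotonically with
separation over 2–18 mm; the non-monotonic behaviour of a full cylindrical
finger model at large separations (electrodes wrapping around toward each
other) is intentionally out of scope. `cole_cole_conductivity()` evaluates
multi-dispersion Cole-Cole permittivity; the packaged blood parameters are
labelled synthetic placeholders of realistic magnitude, not a fitted
tissue database.

## Numerical choices and degenerate inputs

* Working rate 250 Hz: one sample = 4 ms, comfortably resolving fiducials
  while keeping minute-scale simulations cheap.
* Flat or aperiodic records yield an empty beat table, never an error;
  flat beats are rejected from normalization; monotone or reversed beats
  are flagged unusable with a reason string.
* Fiducial conventions are fixed once (derivative at midpoints, inflection
  = last positively curved sample before the crossing) and mirrored exactly
  between detector and ground-truth generator.
* Problem sizes in the test-suite and acceptance runs: 40–50 s records at
  full carrier rate for chain checks, ~470-beat cold-pressor protocols at
  working rate (~110 smoothed windows) for regression checks, and a 140³
  mapped grid for the Geselowitz integral.

## Known limitations

Synthetic-only validation (no shipped human data; the regression fidelity
numbers characterise algorithmic recovery, not clinical accuracy); a
single-template beat morphology without arrhythmia or artifact models; a
planar homogeneous sensitivity surrogate instead of a multi-tissue finger
geometry; and point electrodes rather than finite patches.
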