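---
title: "Measuring respiration volume and rate from skin strain: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring respiration volume and rate from skin strain: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respstrain)
```

# The measurement problem

Two small piezo-resistive strain sensors — one over the lower ribcage, one on
the abdomen — stretch with the skin as the torso expands during breathing,
and their electrical resistance rises with strain. Breathing has two dominant
mechanical degrees of freedom, ribcage and abdominal displacement, and for
healthy subjects each is roughly proportional to the volume of air moved;
a linear combination of the two therefore tracks lung volume change. This
package turns that principle into a per-subject calibration against a
continuous spirometer and a full analysis pipeline around it.

Two physical effects shape the model:

* **Skin-mediated nonlinearity.** The skin must deform before the sensor
  stretches, so at small tidal volumes the resistance excursion per litre is
  small and grows with depth. We model the per-breath relationship between
  exhaled volume $V$ and resistance excursion $\Delta R$ as a power law
  $V = a\,\Delta R^{b}$, fitted per sensor.
* **Viscoelastic hysteresis.** After a large, fast stretch the elastomer
  relaxes slowly, so the resistance does not return to baseline in time
  during forced maneuvers. The measured $\Delta R$ is then too small and the
  calculated volume under-reads — a directional error the pipeline
  reproduces and tests for, rather than corrects.

# The calibration model

For each breath we take $\Delta R = \max(R) - \min(R)$ over the breath
window (extended by a 0.25 s guard on each side to absorb the strain–flow
phase lag; whether the field's $\Delta R$ is max − min or an
end-inspiration minus end-expiration reading is not settled — the two
coincide for clean signals, and we document max − min as our definition).

Stage one fits $V = a\,\Delta R^b$ per sensor by ordinary least squares on
log–log coordinates. A nonlinear least-squares fit on the original scale is
the obvious alternative; we chose the log–log fit because it is convex,
needs no initialization, and is exactly reproducible. Goodness of fit is
reported both ways: `r2` on the original volume scale (from back-transformed
predictions, what a reader of per-subject tables expects) and `r2_log` on
the fitting scale, since which of the two conventions such tables use is
ambiguous.

Stage two *linearizes* each sensor's excursion through its own power model
and regresses measured volume on the pair:

$$\hat V = \beta_0 + \beta_{rib}\, a_r \Delta R_{rib}^{b_r}
                 + \beta_{abd}\, a_a \Delta R_{abd}^{b_a}.$$

Design choices here, all configurable:

* **The transform is $a\,\Delta R^b$, not $\Delta R^b$.** Both are defensible
  readings of "linearize through the power model"; with the scale included
  the regression weights are near-unity mixing fractions, which makes the
  fitted plane directly interpretable (`transform = "exponent"` switches).
* **An intercept is included** (`intercept = TRUE`): the best-fit plane is
  not forced through the origin, matching how such planes are fitted and
  displayed in practice.
* **Exhalation and inhalation are calibrated separately** (`direction`
  label); agreement is conventionally reported per direction.
* **Collinearity.** With noiseless synthetic data both linearized channels
  equal the volume and the design is numerically collinear; ordinary least
  squares then splits the weight arbitrarily between them, but predictions
  remain exact, which is what the recovery tests assert. Exactly duplicated
  or constant predictors are rejected with an error naming them.

Prediction floors $\hat V$ at zero: a negative breath volume is physically
meaningless.

# Signal processing choices

The acquisition chain this pipeline emulates samples all channels at
1000 Hz: spirometer voltage (× 2.04 L/(s·V) gives airflow), two strain
resistances read through a Wheatstone quarter bridge with 4.7 kΩ completion
resistors, and a 3-axis accelerometer.

* **Spike removal**: sliding median (default 50 ms window) with replacement
  beyond 6 × the median absolute deviation of the residuals. No specific
  despiking method is canonical; 6 MAD is conservative enough to pass smooth
  physiological signals untouched (verified to < 1 % distortion in tests).
* **Low-pass**: 4th-order Butterworth at 20 Hz, applied forward–backward so
  breath timing is not shifted. Filtering is preceded by demeaning and
  odd-reflection padding of 3 time constants, because a zero-state IIR
  filter started on a ~4.7 kΩ baseline otherwise rings for seconds at both
  ends.
* **Breath segmentation**: zero-crossings detected on sign changes without
  sub-sample interpolation (at 1000 Hz the timing error is ≤ 1 ms). An
  inhalation (negative) lobe and the following exhalation (positive) lobe
  form one breath. Lobes integrating below the 0.01 L noise cutoff are
  discarded; same-signed lobes that become adjacent after a discard are
  merged, so total volume bookkeeping stays exact.
* **Hysteresis jump correction**: the end-expiratory baseline is estimated
  as a running minimum over ~1.5 breath periods (6 s default, computed on a
  50 Hz decimated grid); step changes of the baseline beyond
  `jump_threshold` (1 Ω default) are located at the raw signal's largest
  local increment nearby and subtracted cumulatively. This removes the
  discrete baseline jumps large amplitude changes leave behind while
  preserving within-breath morphology.
* **Motion filtering**: the step cadence is the dominant non-DC spectral
  peak of an accelerometer channel (a peak must exceed 10 × the median
  spectral amplitude, else "no locomotion detected"). The strain channels
  are then low-passed at `0.5 × cadence`, floored at 0.5 Hz and capped at
  `cadence − 0.2 Hz`. The rule assumes respiration is slower than
  locomotion; the 0.5 factor keeps the half-cadence torsion artifact seen
  during running near or above the cutoff while leaving the respiration
  band (< 0.7 Hz) attenuated by < 2 %. All three constants are arguments.
* **Rate estimation**: peaks are detected by topographic prominence with a
  default threshold of 25 % of the signal's interquartile range — scale-free
  across subjects and depths. Ties at flat tops take the last sample.
  The spectral estimate takes the dominant FFT bin in 0.05–1.2 Hz
  (3–72 breaths/min); resolution is one bin, 1/duration.
* **Spirometry**: FEV1 is the exhaled volume 1 s after the exhale start;
  FVC is taken at the end of the required 6 s sustain rather than by
  asymptote extrapolation — simpler, and exact for any maneuver that has
  plateaued. The exhale start is the last at-threshold sample before the
  first sustained (≥ 0.2 s) run of flow above 0.1 L/s. Of 5 maneuvers the
  top 3 by FVC + FEV1 are selected (the usual acceptability-and-best-test
  convention). Cross-correlation alignment of strain to spirometer channels
  is not asserted anywhere; on synthetic data the channels are synchronous
  by construction.

# Agreement statistics

Differences are fixed as *calculated − measured*, so a negative bias means
the wearable under-reads the spirometer. Limits of agreement are
bias ± 1.96 × SD (sample SD). Lin's concordance correlation coefficient uses
population (1/n) moments, Lin's original definition; a sample-moment variant
is available behind `moments = "sample"` since both circulate. The one-way
ANOVA on paced periods is the classical F computation, with the degenerate
zero-within-variance case returned explicitly as F = ∞, p = 0 (the stock
test returns NaN there).

# What the synthetic generator emulates — and what it does not

`generate_recording()` produces the protocol sessions: calibration (30 s
tidal, 1 min each shallow/medium/deep, 30 s tidal), paced breathing at
10/20/40 breaths/min for 2 min/1 min/30 s, a free-order test session, five
forced maneuvers with rests, and paced walking. Defaults were chosen once as
the study conditions:

| parameter | default | rationale |
|---|---|---|
| sampling rate | 1000 Hz | acquisition-hardware rate |
| tidal volumes shallow/medium/deep | 0.5 / 1.0 / 2.0 L | plausible adult depths spanning the calibration range |
| resting tidal volume / rate | 0.8 L, 15 bpm | typical adult resting breathing |
| breath-to-breath amplitude jitter | 5 % CV | natural variability |
| rib fraction | 0.4 | abdomen-dominant quiet breathing |
| forward power law | a = 2 Ω·L⁻ᵇ, b = 1.4 (rib) / 1.2 (abd) | initially-flat response; exponents differ per site |
| baseline resistance | 4700 Ω | matches the bridge completion resistor |
| resistance noise SD | 0.03 Ω | small relative to the ~0.4–1.7 Ω breath excursions |
| baseline drift | 0.01 Ω/s random walk | slow thermal/adhesion drift |
| hysteresis τ | 0 (off); 3 s for forced-maneuver studies | quiet breathing shows minimal hysteresis |
| walking cadence | 2.09 Hz; artifact 0.3 Ω + 0.1 Ω at half cadence | step frequency with torso-torsion subharmonic |
| forced maneuver | 4 L depth, exponential exhale τ = 0.5 s | gives FEV1% ≈ 86 %, a healthy ratio |

Breaths are half-sine inhale/exhale cycles (no canonical waveform exists for
this purpose; half-sines give exact volume integrals and clean
zero-crossings). Rest periods between forced maneuvers are generated as
breath-holds so maneuver windows stay trivially separable. The hysteresis
emulation is a peak-hold envelope decaying with time constant τ, engaged
when the stretch exceeds half the recent excursion range — a stand-in for
the real viscoelastic behaviour, which is known only qualitatively (fast
stretch, slow return). Real recordings additionally contain cardiac
artifacts, sensor placement variability, posture shifts, electrode-cable
motion, and non-sinusoidal flow shapes; passing the synthetic suite
therefore demonstrates the pipeline's correctness, not field performance.
The concordance near 1.0 on synthetic test sessions should be read as an
upper bound: the generator's noise is well inside what the calibration can
absorb, while real skin-mounted data sit lower.

# Problem sizes and determinism

Every stochastic component draws from an explicit seed, and identical
configurations reproduce recordings bit for bit (the RNG state of the caller
is left untouched). The validation suite runs the protocol sessions at full
1000 Hz where the quantity under test depends on it (rate recovery, motion
filtering, cohort calibration: 90 calibration breaths over 6 min, 60-breath
test sessions over 4 min) and at 100–500 Hz for structural unit tests. The
acceptance script repeats the cohort calibration over 10 seeds and reports
the worst run.

# Known limitations

* The power-law fit requires strictly positive excursions and volumes;
  breaths below the noise cutoff never reach it, but a pathological sensor
  with zero response will error rather than fit.
* The motion filter removes, it does not reconstruct: respiration components
  above the cutoff (very fast breathing while running slowly) would be
  attenuated.
* The hysteresis correction targets discrete baseline jumps; continuous
  creep is handled only insofar as the power fit absorbs it.
* Spirometry from strain inherits the hysteresis under-reading by design;
  the pipeline quantifies it and tests its direction, but no correction is
  attempted.
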