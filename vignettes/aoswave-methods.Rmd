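---
title: "Detecting aortic valve stenosis from non-invasive pressure waveforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting aortic valve stenosis from non-invasive pressure waveforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Aortic valve stenosis (AoS) narrows the valve orifice, adds a valvular
resistance in series with the systemic circulation, and thereby reshapes
the arterial pressure pulse: the systolic upstroke is blunted and delayed,
ejection is prolonged, and peak dP/dt falls. Because these changes travel
down the arterial tree, a continuous non-invasive blood-pressure recording
at the finger/brachial level carries diagnostic information about the
valve. `aoswave` implements a complete analysis chain that turns a 200 Hz
arterial pressure recording (at least 3 minutes long) into a binary
AoS/no-AoS prediction, plus a calibrated synthetic cohort generator that
makes every stage testable end to end without clinical data.

## Pipeline

1. **Segment selection** (`select_segment`): the longest artefact-free
   window, truncated to its first 600 s. An artefact is a sample outside
   20–300 mmHg or an adjacent-sample jump above 60 mmHg (sized to catch
   cuff-recalibration steps). Windows shorter than 180 s are rejected —
   the 3-minute admission rule.
2. **Smoothing** (`smooth_pressure`): Savitzky–Golay least-squares
   polynomial smoothing, default window 15 samples (75 ms at 200 Hz),
   order 3. This preserves the systolic upstroke slope (exact on cubic
   segments) while suppressing sensor noise.
3. **Beat segmentation** (`detect_beats`): steep-upstroke events are
   first-derivative samples above an adaptive threshold (40% of the 95th
   percentile of dP/dt over a rolling 10 s window — robust to slow
   pressure drift), debounced by a 0.3 s refractory period. Each event's
   onset is the pressure foot: the last local minimum before the event,
   located on an extra-smoothed copy of the trace and centred within the
   ±0.4 mmHg flat diastolic valley (the valley floor is nearly flat, so
   without centring the estimate scatters by tens of milliseconds). Events whose
   following segment rises by less than 40% of the recording's median
   pulse amplitude are rejected as secondary (dicrotic) events and merged
   back into their beat. Beats
   shorter than 0.3 s or longer than 2.0 s are excluded, as is a beat
   starting inside the filter's startup transient. All timing features
   are onset-referenced; their published magnitudes (0.06–0.36 s) are
   consistent with foot-referenced timing.
4. **Landmarks** (`extract_landmarks`, `locate_dicrotic_notch`): systolic
   peak (maximum pressure, first occurrence on ties), diastolic pressure
   (onset sample), and the dicrotic notch. The notch is the average of the
   times of the *second* local maximum of the first and of the second
   pressure derivative — counting from beat onset, the first maximum of
   each derivative belongs to the systolic upstroke, so the second is
   found as the earliest positive local maximum after the point of
   steepest systolic decline, searched within 0.35 s of the peak (covering
   published notch times up to 0.38 s with margin). The first derivative
   is computed by centred differences on the smoothed beat; the second by
   a Savitzky–Golay differentiating filter (window 21, order 3), because
   centred second differences at 200 Hz amplify residual noise above the
   notch-curvature signal. Maximum up- and down-stroke slopes are the
   extrema of dP/dt restricted to the systolic part (onset to notch),
   ties resolved to the earliest time.
5. **Per-beat features** (`compute_beat_features`): the hemodynamic panel
   of 25 per-beat quantities — IBI, HR, LVET (defined as onset-to-notch
   time; published LVET and notch-time medians are numerically adjacent,
   confirming that reading), SAP/DAP/MAP (true time average, not the
   1/3-rule, since the source device integrates the waveform), pulse
   pressure, area fractions before/after the notch and above the notch
   pressure, dP/dt, and the pulse-contour block. Stroke volume is a
   *surrogate*: `sv = k · ∫ (P − DAP) dt` over systole, with a single
   global `k` calibrated once so the control reference beat yields 77 mL
   (`calibrate_sv_constant`). It is a documented stand-in for the
   proprietary pulse-contour method of the source device, not a
   reimplementation. Downstream: `co = sv·hr/1000`, `sw = sv·map`,
   `svr = 80·map/co` (dyn·s·cm⁻⁵ — the published magnitudes match this
   formula even though the printed unit differs), and Du Bois
   BSA-indexed variants. All integrals are trapezoidal.
6. **Baroreflex sensitivity** (`xbrs_windows`): beat-to-beat SAP and IBI
   series are step-resampled to 1 Hz. For this stage the inter-beat
   interval is measured between consecutive steepest-upstroke instants —
   a sharp fiducial; the pressure foot sits in a flat valley whose
   localisation error follows the slow baseline slope and would
   masquerade as zero-delay SAP-IBI coupling (foot-based IBI remains the
   per-beat feature). For every 10 s window (1 s steps)
   IBI is shifted later than SAP by each integer delay 0–5 s; the delay
   maximising the positive correlation is kept, and windows whose
   correlation is two-sidedly significant at α = 0.01 emit a gain
   (regression slope of IBI on SAP, ms/mmHg) and the delay τ. The
   unstated constants (window, step, delay range, resampling, α) follow
   the original cross-correlation method the clinical description
   summarises; IBI is shifted later than SAP (the physiological
   direction).
7. **Summaries** (`summarize_features`): each of the 27 base series
   (25 per-beat + xBRS gain and τ) is collapsed to five statistics —
   median, IQR (q75 − q25), variance (n − 1), and the 10th/90th
   percentiles of the beat-to-beat first difference ("the change";
   deciles of the level distribution are available via
   `deciles_of = "level"`, since either reading is compatible with the
   published feature labels). Quantiles use linear interpolation between
   order statistics (type 7), fixed for bit-reproducibility. Series with
   fewer than 10 valid entries yield explicit `NA`s, never silent zeros.
8. **Age adjustment** (`age_adjust`): every statistic is divided by the
   patient's age, before the split, reproducing the published order of
   operations. Plain division (not regression) is deliberate.
9. **Detection model** (`train_detection_model`): stratified 75/25 split
   (largest-remainder per-class allocation: 101 + 48 patients give
   75 + 36 training and 38 test patients); SMOTE oversampling of the
   training minority to parity (synthetic points interpolate between
   k = 5 minority nearest neighbours; applied once before
   cross-validation, as the published order states — the optimistic-bias
   caveat of that order is inherited knowingly, and a leakage-conservative
   scale-then-SMOTE variant can be run alongside it with
   `paranoid = TRUE` / `--paranoid`, reporting both); min–max normalisation
   fitted after SMOTE on training data only and applied unchanged to the
   test set; grid search over five classifier families (logistic
   regression C ∈ {0.01,…,100} — containing the published optimum C = 10
   with L2 penalty and intercept —, KNN k ∈ {3,5,7,11}, decision tree
   depth ∈ {2,3,5,30}, SVM C × {linear, radial}, random forest
   ntree ∈ {100,300}) by 4-fold stratified cross-validated mean AUROC,
   ties broken toward the simpler family/setting. Evaluation uses the
   Mann–Whitney AUROC (ties counted ½) and a 0.5 probability threshold —
   the conventional operating point for a balanced training distribution;
   the published operating point is unstated, so the threshold is
   configurable.

## The synthetic cohort generator

`simulate_cohort` draws two groups whose morphology, demographics and
recording lengths reproduce the published group contrasts; it is the
package's test bed and defines the study conditions for all end-to-end
checks.

**Beat morphology.** Each cycle is a composite of smooth basis functions
("velocity lobes"): a systolic rise equal to a scaled Beta CDF whose mode
and peak density are solved so the steepest upstroke lands exactly at
`t_max_up` with slope `dpdt`, and whose support ends at `t_peak`; a small
Gaussian cap (3 mmHg, σ = 30 ms) that gives the summit a definite,
rounded maximum exactly at `t_peak`; a Beta-CDF decline to the notch
pressure at `lvet` with steepest descent at `t_max_down`; a dicrotic wave
whose peak offset mirrors the downstroke inflection about the notch — a
morphological convention that makes the derivative-averaging notch
estimator unbiased at `lvet` by construction; and a rational-exponential
diastolic relaxation reaching DAP exactly at the cycle end (so
concatenated beats join continuously). A Windkessel ODE was rejected
deliberately: the lobe construction gives direct, invertible control of
exactly the landmarks the extraction stage measures, which an ODE would
obscure. Two guards keep the extreme corners of parameter space
well-posed: the rise lobe keeps at least quadratic contact at the peak
(`b ≥ 2.5`; an extremely low requested dP/dt renders slightly steeper
than asked instead of smearing the peak), and the dicrotic upslope is
kept gentle (~150 mmHg/s) so it cannot cross the adaptive upstroke
threshold of low-dP/dt patients and split beats.

**Beat-to-beat dynamics.** Systolic pressure fluctuates with a
respiratory sinusoid (3 mmHg at 0.25 Hz) plus an AR(1) component
(2 mmHg, 2.5 s correlation time); the baseline is continuous across beat
joints — a per-beat constant offset would create a pressure step at the
foot whose detection error correlates with SAP at zero delay and
measurably inflates recovered baroreflex gain. Pulse amplitude and the
timing set jitter log-normally per beat (CV 3% and 2%); amplitude jitter
scales all amplitude parameters together and timing jitter scales all
timing parameters together, so orderings are preserved and the per-beat
peak slope co-varies realistically. The baroreflex coupling lengthens the
interbeat interval by `G` ms per mmHg of systolic-pressure deviation a
delay `d` earlier (positive gain: higher pressure, longer interval).
The default delay is 2.6 s so that the *estimated* τ — true delay plus
the ~0.4 s within-beat smear of beat-level coupling — centres on the
published median of 3.0 s. Observation noise is white, SD 1 mmHg (no
waveform-level noise figure is published; this is a generator choice).

**Cohort draws.** Per-patient parameters are sampled log-normally,
matched to the published medians and interquartile ranges (positive-
valued and skew-tolerant), with rejection resampling for feasibility
(landmark ordering, notch depth within the pulse, attainable dP/dt) and
physiological plausibility (systolic pressure below the 300 mmHg artefact
ceiling, heart period under 1.7 s — the unbounded log-normal tails would
otherwise occasionally produce a recording the artefact rules reject
wholesale).
Demographics (age, height, weight, sex ratio) and per-group recording
lengths (AoS drawn toward 600 s, controls toward 400 s, clamped to
180–600 s) follow the published group tables, exercising unequal-length
handling. `n = 1` per group is valid.

**What the generator does not emulate** — and hence what passing tests do
not certify about clinical data: the finger-to-brachial transfer
function, arrhythmias (an exclusion criterion of the source population),
low-flow-low-gradient subphysiology, measurement drift and
recalibration artefacts beyond the simple step model, and any
morphological feature outside the lobe family. End-to-end results on this
cohort demonstrate that the pipeline recovers what the generator encodes
at realistic noise levels; they are not clinical validation.

## Numerical and design choices

- Savitzky–Golay parameters are unpublished; window 15 / order 3 is the
  package default and configurable. Edge samples use the standard
  truncated-window polynomial fits.
- Derivative source: smoothed beat (config `use_smoothed = FALSE` gives
  raw), and the second derivative uses a least-squares differentiating
  filter as justified above.
- The notch-area feature follows the literal reading — area above the
  horizontal line at the notch pressure as a percentage of total beat
  area. The published percentages (≈39/42%) are hard to reconcile with
  any literal area reading but are numerically close to the notch-time
  fraction of the beat, so `notch_auc = "time"` offers that variant; the
  feature is not used as a calibration anchor.
- Decision threshold 0.5; largest-remainder stratified rounding; all
  randomness (cohort draws, split, SMOTE, folds, stochastic fits) funnels
  through one integer seed; identical invocations are byte-identical.
- `default_feature_subset()` carries the published 41-item best-feature
  list (its printed count says 40; the list as printed has 41 names).
- Degenerate inputs: flat beats, monotone decays (no notch), all-artefact
  recordings, single-class test sets, zero-variance windows, and
  constant normaliser columns all raise typed errors or logged,
  explicitly-missing values rather than silent results.

## Problem sizes used by the packaged checks

The test suite and the acceptance script regenerate everything from code:
single recordings of 300–600 s for landmark/beat checks, and ten
full-size cohorts (101 + 48 recordings, 180–600 s each at 200 Hz) for the
end-to-end detection check, whose held-out AUROC is averaged over the ten
cohort seeds. On one CPU a full cohort pipeline takes roughly 45 s.

## Known limitations

- The stroke-volume surrogate is linear in the systolic pressure–time
  integral; absolute SV/CO/SVR levels are only as good as the single
  calibration constant, though group *contrasts* are preserved.
- SMOTE before cross-validation (the published order) leaks synthetic
  neighbours across folds; the reported cross-validated AUROC is
  therefore optimistic relative to a nested design.
- The xBRS estimator attenuates gain by ~10–15% under beat-level coupling
  with a fractional-beat delay smear; estimates remain within the
  published interquartile band.
- Age division assumes a proportional age effect on every feature; no
  regression-based adjustment is offered by design.
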