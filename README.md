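# aoswave

Detection of aortic valve stenosis (AoS) from continuous non-invasive
arterial blood-pressure waveforms.

Aortic stenosis adds a valvular resistance that blunts and delays the
systolic upstroke, prolongs ejection and lowers peak dP/dt — changes that
persist in the pressure pulse measured at the periphery. `aoswave` turns a
200 Hz arterial pressure recording (≥ 3 min) into a per-recording feature
vector and a binary AoS prediction:

1. artefact-free segment selection and Savitzky–Golay smoothing;
2. beat segmentation at the pressure foot (adaptive first-derivative
   threshold, 0.3 s refractory, low-amplitude event rejection);
3. per-beat landmarks — systolic peak, diastolic pressure, maximum up- and
   down-stroke of the systolic part, and the dicrotic notch located as the
   mean of the times of the second local maxima of the first and second
   pressure derivatives;
4. 27 hemodynamic features per recording: IBI, HR, LVET (onset→notch),
   SAP/DAP/MAP, pulse pressure, pulse-contour surrogates
   (SV = k·∫(P−DAP)dt over systole, CO, SW = SV·MAP, SVR = 80·MAP/CO and
   BSA-indexed forms), dP/dt, beat-area fractions around the notch, the
   landmark timings/pressures, and cross-correlation baroreflex
   sensitivity (xBRS gain, ms/mmHg, and delay τ over 10-s windows);
5. five summary statistics per feature (median, IQR, variance, 1st/9th
   decile of the beat-to-beat change), divided by patient age → 135
   columns;
6. model stage: stratified 75/25 split, SMOTE oversampling of the training
   minority to parity, min–max normalisation, grid search over logistic
   regression / KNN / decision tree / SVM / random forest by 4-fold
   cross-validated AUROC, Mann–Whitney AUROC evaluation on the held-out
   test set.

A calibrated synthetic cohort generator (`simulate_cohort`) reproduces the
two clinical groups' waveform morphology, demographics and recording-length
profiles with full ground truth, so the whole chain is testable without
patient data.

## Worked example

```r
library(aoswave)

## simulate the default two-group cohort (101 AoS / 48 controls)
cohort <- simulate_cohort(cohort_params(), seed = 1)

## one recording end to end
ex <- extract_recording_features(cohort$recordings[[1]],
                                 meta = cohort$meta[1, ])
vf <- ex$features[ex$features$valid == TRUE, ]
nrow(vf)                        # valid beats
median(vf$lvet)                 # ejection time, s
median(ex$xbrs$gain)            # baroreflex gain, ms/mmHg

## whole cohort: features -> age-adjusted summaries -> model
fit <- run_detection_pipeline(cohort, seed = 1)
fit$model
fit$report
```

Output of that run:

```
#> nrow(vf)
[1] 682
#> median(vf$lvet)
[1] 0.3475
#> median(ex$xbrs$gain)
[1] 4.2796
#> fit$model
<aos_model> rf (ntree=100); CV AUROC 0.932 (SD 0.008)
#> fit$report
<evaluation_report> AUROC 0.772 | tp 21 fp 6 tn 6 fn 4 | sens 0.84 spec 0.50 acc 0.73 ppv 0.78 npv 0.60
```

The first recording belongs to a stenosis patient: its median ejection time
(0.348 s) sits in the stenotic range and its baroreflex gain (4.3 ms/mmHg,
delay 3 s) is physiological. On the held-out quarter of the cohort
(38 patients) the selected model separates the groups with AUROC 0.77;
with so small a test set the AUROC swings considerably between cohort
seeds (roughly 0.64–0.98), and its ten-seed mean is 0.80. Sensitivity,
specificity, accuracy, PPV and NPV are reported at the 0.5 probability
threshold together with the confusion-matrix counts they derive from.

A command-line interface wraps the same stages
(`exec/aoswave simulate|extract|features|train|evaluate|all`); every run
logs its seed and configuration hash, and identical invocations produce
byte-identical outputs.

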