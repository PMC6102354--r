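# hdstate

Identifying the *cause* of a hazardous driver state — cell-phone
distraction, sleep deprivation, dense town traffic, or snowy weather —
from multimodal measurements: physiological signals (ECG, respiration,
skin conductance, skin temperature at 512 Hz), eight vehicle-kinematics
channels (60 Hz), and questionnaire scores.

The package is written for researchers in psychophysiology and driver
monitoring who want a fully tested, end-to-end re-implementation of this
classification pipeline that runs without access to any human recordings:
a built-in synthetic-study generator emulates the within-subject factorial
protocol (21 participants × 4 sessions × 1 baseline + 8 scenarios, the 8
scenarios enumerating all combinations of traffic × weather × phone), so
every stage — filtering, feature extraction, normalization, selection,
cross-validation — is testable by parameter recovery.

## The pipeline

1. **Simulation** (`simulate_study`): raw channels with controlled
   condition effects. Inter-beat intervals follow
   `IBI_k = 60/HR + A_LF sin(2π·0.10·t_k) + A_HF sin(2π·0.25·t_k) + ε`;
   skin conductance is a tonic trend plus bi-exponential responses; lane
   number is a telegraph process whose switching rate scales with traffic
   density; tire slip rises as the snow friction factor (default 0.60)
   falls.
2. **Preprocessing** (`filter_lowband`, `filter_ecg`, `epoch_segments`):
   zero-phase 30 Hz low-pass for the slow channels; 5 Hz high-pass plus
   60 Hz notch (Q = 30) for ECG; epoching into baseline/scenario segments.
3. **Features** (`extract_features`): 17 physiological + 24 kinematics
   (mean, SD, fluctuation = mean |Δx| per channel) + 20 driver
   characteristics = 61 features per scenario; 672 scenario rows at the
   default design.
4. **Normalization** (`normalize_features`): per session, physiological
   features are baseline-subtracted then min-max scaled to [0, 1];
   kinematics features are min-max scaled without baseline; the
   session-constant characteristics are z-scored across the study.
5. **Classification** (`stepwise_select`, `run_matrix`): stepwise forward
   selection by partial F-test (entry p < 0.05, fallback 0.1),
   leave-one-out cross-validation with fold-internal selection, over a
   menu of SVMs (linear/quadratic/medium-Gaussian), logistic regression,
   decision trees (simple/medium/complex) and a boosted tree ensemble;
   independent and augmented (other-cause indicators appended) schemes.
6. **Workload validation** (`rm_main_effect`, `tlx_effect_table`):
   repeated-measures main effects of each cause on the NASA-TLX subscales
   (for a two-level within factor, F = t² of the paired t-test).

## Worked example

```r
library(hdstate)

design <- study_design(n_participants = 6, scenario_duration = 60,
                       baseline_duration = 60, seed = 5)
study  <- simulate_study(design, effect_config())
feats  <- extract_features(study)            # 192 scenario + 24 baseline rows
norm   <- normalize_features(feats)

res <- run_matrix(norm,
                  menu   = default_classifier_menu()[c("logistic", "svm_linear")],
                  combos = feature_set_combinations()[c("physio",
                                                        "characteristics",
                                                        "kinematics")])
accuracy_table(res)
```

```
                phone drowsy town snowy
physio           96.4   60.4 76.0  68.8
characteristics    NA  100.0   NA    NA
kinematics       69.3   26.0 84.4  99.5
```

Read: each entry is the best leave-one-out accuracy (%) for classifying
that cause from that feature set alone. The pattern is the scientifically
expected one — phone use is carried by physiology (respiration rate, ECG
artifact power), drowsiness by the session-level characteristics (mood
scores, start hour; `NA` marks cells where no session-varying feature was
selected, so a within-session cause is not classifiable), and traffic
density / snowy weather by vehicle kinematics (lane-number variability,
tire slip). Cells with no usable signal can fall *below* 50% (here
drowsy/kinematics): leave-one-out with fold-internal selection is
systematically pessimistic on uninformative data — see the methods
vignette. Workload validation:

```r
tlx_effect_table(study$questionnaires$tlx)   # 7 outcomes x 4 causes of p-values
```

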