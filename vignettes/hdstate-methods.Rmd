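---
title: "Methods: simulating and classifying the causes of hazardous driver states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and classifying the causes of hazardous driver states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hdstate)
```

# The problem and the pipeline

A *hazardous driver state* (HDS) is any condition — distraction, fatigue,
overload — that degrades driving. This package classifies the **cause**
of the state rather than its mere presence, distinguishing four causes
that a within-subject driving-simulator protocol manipulates factorially:
cell-phone use, sleep deprivation (drowsy vs. alert sessions), traffic
density (town vs. highway), and weather (snowy vs. clear).

The pipeline runs from raw signals to cross-validated accuracy:
simulation → filtering → epoching → feature extraction (61 features) →
per-session normalization → stepwise selection → classification with
leave-one-out cross-validation → reporting, plus an independent workload
validation on NASA-TLX questionnaire scores.

# The synthetic study generator

No public raw recordings exist for this protocol, so the package ships a
generator whose **defaults are the study conditions**: 21 participants ×
4 sessions (exactly 2 drowsy) × (one 4-min baseline + eight 4-min
scenarios); the eight scenarios enumerate all 2×2×2 combinations of
(town, snowy, phone) in seeded random order; physiology at 512 Hz,
kinematics at 60 Hz. With these defaults the study yields exactly
672 scenario rows (21 × 4 × 8).

The waveform models are deliberately schematic plumbing — the protocol's
source recorded humans and specifies no signal model — chosen so that
*every extractor is testable by parameter recovery*:

* **ECG**: narrow Gaussian QRS-like pulses placed at inter-beat intervals
  `IBI_k = 60/HR + A_LF·sin(2π·0.10·t_k) + A_HF·sin(2π·f_resp·t_k) + ε`.
  The 0.10 Hz component populates the LF band (0.04–0.15 Hz) of the
  heart-rate-variability spectrum, the breathing-frequency component the
  HF band (0.15–0.4 Hz). Broadband bursts (~6/min, 0.3–0.8 s) emulate
  motion artifacts; the protocol deliberately retains them.
* **Respiration**: one sinusoidal cycle per breath with per-breath period
  jitter, so cycle counts and period statistics are known exactly.
* **Skin conductance**: linear tonic trend plus bi-exponential responses
  (rise τ ≈ 0.7 s, decay τ ≈ 4 s); spontaneous response rate 3/min in
  neutral scenarios, a typical electrodermal value.
* **Kinematics**: mean-reverting (Ornstein–Uhlenbeck) processes for
  throttle, lateral position, road offset and velocities; lane number as
  a 0/1 telegraph process (base switching rate 0.0875/min); tire slip
  near zero in clear weather, clipped to [0, 1].

**Condition effects** (all exposed in `effect_config()`): phone raises
respiration rate (+3 breaths/min), ECG artifact power and mean lateral
lane position, and all six TLX subscales; drowsiness shifts the STAQ
affect scores, the session start hour (early morning) and adds a slow
tonic skin-conductance drift; town multiplies the lane switching rate and
adds 0.1 Hz IBI modulation and wider skin-conductance-response
amplitudes; snow elevates rear-tire slip and throttle variability
(scaled by how far the friction factor, default 0.60, falls below 1) and
the tonic conductance level, and mildly raises the TLX scores with
mental demand strongest. Magnitudes are not printed by the protocol's
source (only directions), so the defaults were chosen once to produce
the qualitative pattern a practitioner would expect and are stated in
the configuration, not claimed as measured values.

The town effect on the lane channel deserves a note: the observed
standard deviation of a telegraph process over a 4-min window is
approximately linear in the switching rate only when switches are rare,
and saturates at 0.5. Scaling the switching rate by the *square* of the
multiplier (default 4² = 16) reproduces the target ratio of standard
deviations (≈ 4, "almost four times") at the default base rate; this
mapping was calibrated against simulation before any tests were written.

**Between-segment wander.** Real physiological state drifts from scenario
to scenario independent of condition. The generator therefore adds
condition-independent per-segment wander (heart rate ±2 bpm, breathing
±1.2 breaths/min, conductance level ±0.3 µS, lane-keeping offset
±0.12 m, and an idiosyncratic scaling of each driver's snow response).
Without it, single condition effects are trivially separable and every
cell saturates at 100%. The wander is retained under the null
configuration because it carries no label information.

**The null configuration** (`effect_config(null = TRUE)`) removes every
coupling between labels and signals or questionnaires — including the
session start-hour distribution, which must have identical mean *and*
variance across drowsy and alert sessions, otherwise the hour leaks the
label. This configuration underlies the chance-calibration tests.

**What the generator does not emulate**: PQRST morphology, vehicle
dynamics, participant attrition, electrode drift and artifacts other than
broadband ECG bursts, and learning/fatigue across sessions. Passing tests
therefore demonstrate the *pipeline's* correctness and calibration, not
performance on real recordings; in particular the absolute accuracies on
synthetic data are not comparable to accuracies on human data.

# Preprocessing

The stated filters are: 0–30 Hz band for respiration, conductance and
temperature, and 5 Hz high-pass plus 60 Hz notch for ECG. The filter
family and order are not stated; the package uses 4th-order Butterworth
filters applied forward–backward (zero-phase, so event timings do not
shift), realizing the "0–30 Hz band-pass" as a 30 Hz low-pass (a true DC
corner is a low-pass, and the tonic conductance level must survive). The
notch is a second-order IIR biquad with quality factor 30. Long filters
ring at epoch edges, so filtering uses even reflection padding, and the
first/last second of each epoch is excluded from gradient-based features.
Whether the source filtered before or after epoching is unstated; this
package filters each continuous session recording, then epochs.

# Feature extraction

* **Respiration (3)**: breath cycles are delimited by upward zero
  crossings of the smoothed (1 Hz low-pass) centred signal, refined on
  the raw signal — crossings measure each breath period itself, whereas
  peak-to-peak intervals mix adjacent periods and bias RMSSD. `rr_std` is
  computed across 1-min windowed rates (an epoch otherwise has a single
  rate), an interpretation choice the 4-min epochs support.
* **Skin temperature (2)**: mean, and last-second minus first-second.
* **Skin conductance (5)**: the tonic component is a 0.05 Hz zero-phase
  smoother computed on a *de-pulsed* copy of the signal (3 iterations of
  subtracting positive excursions before re-smoothing). A plain 0.05 Hz
  low-pass absorbs nearly half of each response pulse into the tonic
  estimate because a ~15 s bi-exponential pulse has substantial spectral
  mass below 0.05 Hz; de-pulsing retains ≈96 % of pulse amplitude in the
  phasic residual while leaving the reconstruction identity
  (tonic + phasic = input) exact. Responses are scored trough-to-peak on
  the phasic component, minimum amplitude 0.05 µS (configurable; the
  source cites a methods reference without printing a threshold), rise
  time ≤ 5 s.
* **ECG (7)**: R peaks from a derivative–square–moving-average energy
  envelope with a median-based adaptive threshold (robust to both the
  noise floor and artifact bursts) and 250 ms refractory period; mean HR
  and IBI standard deviation; median and mean-absolute first difference
  of the filtered ECG in mV/s (the "gradient" features, two features per
  the absolute-value reading that makes the physiological set total 17);
  LF/HF band powers from a Hann-windowed periodogram of the IBI series
  cubic-interpolated to 4 Hz, integrated by trapezoid.
* **Kinematics (24)**: mean, SD and fluctuation (mean |first difference|)
  of each of the 8 channels.
* **Characteristics (20)**: the composition is under-documented in the
  source (only the count is printed); the default is 6 demographics +
  5 IPIP + 1 PSS-10 + 4 STAQ + 4 extras (BMI, glasses flag, session start
  hour, session ordinal), honoring the printed totals of 20 and 61.

Features that cannot be computed (no beats, no responses, zero HF power)
are flagged `NA` and imputed to the session median before selection.

# Normalization

Per session: physiological features have the session's baseline value
subtracted, then are min-max scaled with the session's own scenario
minimum and maximum; kinematics features are min-max scaled without
baseline subtraction. A degenerate (constant) session range maps to 0.5 —
the centre of the contract range — with a warning. Baseline rows are
excluded from the min/max (an unstated detail; scenarios-only is the
default here). The characteristics block is session-constant and is
z-scored across the whole study instead, a choice the source leaves open.

An important consequence: session-wise min-max removes *between-session*
differences, so session-level causes (drowsiness) are nearly invisible in
normalized physiology and kinematics — which is exactly why the
characteristics set dominates drowsy classification.

# Selection, classification, validation

**Stepwise forward selection** adds, at each step, the candidate whose
partial F-test (nested linear models on the 0/1 outcome) has the smallest
p-value, while it is below 0.05; if the first step admits nothing, the
whole selection reruns at 0.1. Ties break toward the lower column index.
The partial F is computed from partial correlations after projecting out
the current model — algebraically identical to the nested-model test (the
unit tests verify the full path against an explicit `lm()`/`anova()`
brute force) but vectorized over candidates.

**Classifiers**: SVMs with linear, quadratic (degree 2, offset 1) and
medium-Gaussian kernels (kernel scale √p, i.e. γ = 1/p); logistic
regression with the documented decision rule (output ≥ 0.5 → positive
class, the boundary itself going to the positive class); decision trees
grown with `rpart` and pruned back to at most 4/20/100 splits
(simple/medium/complex); and a 30-round adaptively reweighted
(AdaBoost.M1) ensemble of depth-limited trees — reweighting, not
resampling, so it is deterministic. Unstated hyperparameters (SVM cost 1,
ensemble size 30, depth limit 3) are package defaults.

**Cross-validation** is leave-one-*sample*-out by default (k = n = 672),
matching the generic k-subset description, with feature selection refit
inside every training fold so no selection information leaks from the
held-out sample. Leave-one-participant-out (`cv = "loso"`) and
full-data selection (`selection = "outside"`, the variant the source most
likely used given that it reports selection p-values as a by-product of
validation) are available as options. Reported per-cell feature lists and
p-values always come from the full-data selection path.

## Two properties of leave-one-out worth knowing

Both are visible in the chance-calibration tests and neither is a bug:

1. **Below-chance pessimism with fold-internal selection.** On data with
   no signal, whether a borderline feature passes the entry threshold
   flickers from fold to fold, and it passes precisely in the folds whose
   held-out sample *contradicts* the feature — so those folds predict
   wrong more often than chance. Together with the exact within-session
   balance of the factorial design (removing one sample makes its class
   the training minority), leave-one-out estimates of null cells land
   systematically below 50 %. The guarded property is therefore the
   absence of *optimism* (no null cell above the upper chance bound);
   the two-sided binomial chance band applies to the fixed-model
   (`selection = "outside"`) estimator. An empty per-fold selection
   predicts the positive class — a neutral constant; predicting the
   training majority would be anti-correlated with the held-out label.
2. **Session identification for session-constant labels.** The drowsy
   label is constant within a session while characteristics features
   identify the session; with sample-wise leave-one-out, the 7 remaining
   rows of the held-out sample's session sit in the training data, so
   near-perfect drowsy accuracy is attainable from session identity
   alone. This reproduces (deliberately) the mechanism behind the
   protocol's near-100 % drowsy results; chance calibration for drowsy is
   therefore asserted under leave-one-participant-out folds, at the
   session-level chance band.

**Workload validation**: for each cause and each NASA-TLX outcome, each
participant's scores are averaged within the two factor levels and the
main-effect F(1, n−1) is computed; for a two-level within factor this is
exactly the squared paired t statistic (asserted to 10⁻⁹). Sessions are
collapsed by averaging within level; participants missing a level are
excluded with a warning; interactions are out of scope (the protocol
reports none).

# Problem sizes used by the tests and the acceptance script

Counts and contracts do not depend on epoch length, so the test suite
shortens epochs (30–60 s) and shrinks participant counts where the full
factorial is not needed; the chance-calibration test keeps the full
21 × 4 × 8 = 672-row factorial at 30-s epochs, and the direction-of-effect
check runs 10 seeded replicates of a 4-participant study. The acceptance
script (`scripts/acceptance.R`) runs the complete 672-scenario factorial
with 120-s epochs. These sizes are the package's reproduction settings;
condition-effect magnitudes, thresholds and tolerances are never adjusted
per run.

# Known limitations

* Synthetic waveforms are schematic; absolute accuracies are properties
  of the chosen effect sizes, not predictions for human data. Only
  directions of effects (which feature set carries which cause) are
  treated as reproduction targets.
* The R-peak detector is tuned for the synthetic morphology; on real ECG
  a validated QRS detector should replace it behind `detect_r_peaks()`.
* Sample-wise leave-one-out inflates session-level causes (see above);
  leave-one-participant-out is the honest generalization estimate and is
  one flag away.
* The boosted ensemble is a fixed-depth AdaBoost; it is not a tuned
  gradient-boosting implementation.
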