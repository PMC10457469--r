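---
title: "Brain age from anaesthesia EEG: models, generator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain age from anaesthesia EEG: models, generator, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During general anaesthesia, frontal EEG is routinely recorded to monitor
anaesthetic depth. Those recordings can be repurposed: a model trained to
predict chronological age from EEG features in a healthy reference group
defines a *brain age*, and the discrepancy between predicted and
chronological age (the brain-age delta) is a candidate marker of atypical
brain ageing and perioperative risk. `eegbrainage` implements this
analysis end to end for four-channel frontal montages (Fp1, Fp2, F7, F8
referenced to Cz, 63 Hz): stable-segment selection, spectral and spatial
feature extraction, nested stacked ridge age-prediction models compared
under Monte Carlo cross-validation, and the two clinical statistical
models — a mixed-effects model of log EEG power across age and frequency,
and a logistic model of intraoperative burst suppression as a function of
age, brain age and ASA physical status.

Because clinical anaesthesia EEG is not freely available, the package
ships a synthetic cohort generator with fully known ground truth. All
tests and the acceptance analyses run against this generator, so every
claim the test suite makes is a claim about the pipeline's behaviour on
data whose generating process is known exactly.

## The synthetic generator

The generator realises, by construction, the statistical structure the
analysis assumes. Its noiseless channel spectrum in dB (re 1 uV^2/Hz) is

S(f) = b0 − 10·chi·log10(max(f, knee)) + A·exp(−(f − p(a))² / 2σ²)
     + β_age·(a − a_ref) + drug·[β_sevo + β_sevo:f·(log f − mean log f)]

with an aperiodic 1/f^chi background, a Gaussian alpha peak whose centre
p(a) decreases with age, a broadband ageing slope, and a sevoflurane
offset with a log-frequency interaction. The *effective* age a is the
chronological age plus a latent Gaussian brain-age offset (sd 8 yr); that
offset is what makes brain age differ from age and gives the
burst-suppression model something to detect. Key values, with why they
were chosen:

| parameter | default | rationale |
|---|---|---|
| broadband age slope | −0.10 dB/yr | the ageing effect the power model must recover |
| sevoflurane offset | +3.6 dB at the reference log-frequency | the drug effect the two-drug model must recover |
| sevoflurane × log-frequency | −1.00 dB per unit log f | negative tilt of the drug effect with frequency |
| aperiodic exponent | 2 | steep 1/f typical of anaesthesia EEG; calibrated so the analytic SEF95 lies in 8–13 Hz at every age 18–90 |
| low-frequency knee | 0.5 Hz | the monitor's high-pass; without it unbounded 1/f power floods the record with slow drift |
| alpha peak | 12 dB, σ = 1.5 Hz, 11.5 Hz at age 18, −0.04 Hz/yr, clamped to 8.5–12.5 Hz | prominent frontal anaesthesia alpha whose slowing encodes age in the spectrum's *shape* |
| level / alpha-amplitude noise | 1.5 dB each | realistic between-patient power variability; keeps single power features from being a perfect age readout |
| alpha peak jitter | 0.3 Hz | between-patient peak variability |
| spatial mixing | two latent sources, channel angles 0.3/0.5/1.1/1.3 rad with age slopes +0.006/−0.002/+0.002/−0.006 rad/yr, jitter 0.05 rad, 10% independent sensor noise | differential rotation makes cross-channel correlations an age readout beyond the spectrum, so the spatial-pattern model has something genuinely extra to find; the noise floor keeps every band covariance positive definite |
| burst-suppression logistic | intercept −3.2, β_age 0.4 (per 20.8 yr), β_brainage 0.85 (per 16 yr), β_ASA 0.5, β_brainage×ASA −0.99, logit noise sd 0.3 | the two printed coefficients are the effects the clinical model must recover; intercept and companions keep proportions in a clinically plausible 0–0.4 range; the logit-scale noise is the unexplained patient variability any real cohort has |
| suppression bouts | one contiguous bout of alternating suppression (2–10 s, attenuation ×0.02) and bursts (2–6 s), 0.1-s cosine ramps | burst suppression occurs during over-deep periods, not as isolated scattered episodes; a contiguous bout also leaves a clean stable segment to model |
| artifacts | 0.3/min, biphasic, 320–600 uV ptp, 0.2–1 s | must trip the 250 uV high-amplitude rejection rule |

Two calibrations were done analytically before any code ran: (i) the
aperiodic exponent and alpha-peak geometry were chosen so the analytic
SEF95 over 0.5–30 Hz stays inside the 8–13 Hz stability band for all ages
18–90 (the cohort is, by design, under stable anaesthesia), and (ii) the
projection of the noiseless spectrum onto the mixed model's design
(intercept, age, centred log frequency, interaction) returns an age
coefficient of exactly −0.10 dB/yr — the symmetric Gaussian peak's
movement loads onto the age × log-frequency interaction, not the age main
effect.

What the generator does *not* emulate: volume conduction from realistic
sources (mixing is a fixed two-source rotation, not a head model),
drug-dose dynamics and opioid confounding, non-stationary anaesthetic
depth drift, line noise, and real artifact morphology beyond "large and
brief". Passing tests therefore demonstrate that the pipeline implements
its stated mathematics and recovers known structure — not that it is
robust to everything clinical data can do.

## Preprocessing

Recordings are cut into 60-s epochs with a 10-s shift
(`n = floor((T−60)/10)+1`). An epoch is retained only if every channel's
peak-to-peak amplitude lies strictly inside (0.1, 250) uV: the lower
bound catches flat/dropped channels and isoelectric stretches, the upper
bound high-voltage artifacts. Clinical monitoring archives of this kind
have burst suppression removed upstream, before any modelling; since
the generator injects it into raw records, that cleaning is reproduced
here by an amplitude-envelope detector (all-channel envelope < 5 uV
sustained >= 0.5 s, 0.1-s windows) — a simple declared rule standing in
for a clinical annotation procedure — and epochs overlapping detected
suppression are excluded from modelling. The full recording is still
used to *quantify* the suppressed fraction for the clinical model.

SEF95 (the frequency below which 95% of the 0.5–30 Hz Welch power lies)
is computed per epoch and channel; the stable-anaesthesia segment is the
longest run of consecutive retained epochs whose channel-mean SEF95 is
in 8–13 Hz, earliest run on ties, and a rejected epoch breaks a run
(strictest reading of consecutiveness). Patients without such a run are
excluded with a logged reason. The 0.5 Hz lower integration bound
excludes DC drift; 30 Hz matches the PSD range.

## Features

All spectral quantities share one Welch configuration: 4-s Hann
segments, 50% overlap, per-segment mean removal — a 0.25 Hz grid with at
least 29 averages per epoch. Because sliding epochs overlap, segment
FFTs are computed once per record and shared (numerically identical to
per-epoch computation).

Band covariances (low 0.1–1.5, delta 1.5–4, theta 4–8, alpha 8–15, beta
15–30 Hz) are obtained by integrating the Welch co-spectra over each
band — the covariance of the ideally band-filtered signal — and
averaging across the segment's epochs. This replaces literal zero-phase
FIR filtering: at 63 Hz a filter with a usable transition at the 0.1 Hz
band edge would need thousands of taps, while co-spectral integration is
exact for the ideal band and makes the band-power/PSD consistency
identity hold by construction.

The four nested feature sets are: total power (1; log channel-mean power
summed over 1–30 Hz), alpha power (1; log power over 8–13 Hz — the
monitoring definition for the scalar feature, while the covariance alpha
band uses 8–15 Hz, each the convention of its context), the power spectrum
(16; log channel-mean PSD at 16 uniformly spaced frequencies from 1 to
30 Hz snapped to the 0.25 Hz grid), and spatial patterns (50; per band,
the covariance shrunk toward scaled identity with the
oracle-approximating (OAS) intensity, mapped to the tangent space at the
training group's log-Euclidean geometric mean, vectorised as the 4
diagonal entries plus sqrt(2)-weighted upper off-diagonals). Log
transforms are natural logs internally; dB appears only in reporting and
in the power mixed model.

## Age-prediction models and their comparison

Each model is a two-level stack: one ridge regression per feature set
(level 1), whose internal 10-fold out-of-fold predictions feed a level-2
ridge with one input per set. Stacking balances comparisons between sets
of dimension 1 and 50: a richer model can only beat a simpler one through
genuinely complementary information, because every set is summarised by
a single input. Ridge penalties (both levels) are selected per fit by
generalised cross-validation over a log-spaced grid 1e-3–1e5; features
are standardised within the training data inside each fit. The tangent
reference for covariance features is fitted on the training patients of
each outer split and shared across that fit's internal folds — the outer
test fold never informs it.

Models are compared over 100 Monte Carlo shuffle-splits (10% test
fraction — chosen so that 100 splits sample many test sets while keeping training
folds large at n = 170) shared across all models, with paired per-split
MAE differences summarised by P2.5/P25/P75/P97.5 percentiles
(linear-interpolation convention, R type 7) and a superiority count
(strictly better splits; ties are "not better"). Chance level is a dummy
regressor predicting the training-mean age; per-split R² is
1 − SS_res/SS_tot on the test fold. Cross-validated brain-age
predictions for the reference group are out-of-fold (10-fold); patients
outside the reference group (ASA 3) are predicted by a model refitted on
all reference patients, and the two prediction sources are concatenated
for the clinical analysis. The drug-generalization experiment evaluates,
on each shared split of the pooled two-drug cohort: within-drug fits,
cross-drug fits (train on one drug's training patients, score on the
other drug's test patients), and a pooled fit scored overall and on each
drug's test subset — the sub-scores partition the pooled test fold
exactly.

## Clinical models

*Log-power model.* Channel-mean stable-segment PSDs are converted to dB
(10·log10 re 1 uV²/Hz) into a long table (patient × 0.25 Hz bin,
1–30 Hz; 117 bins per patient), and log power is regressed on age,
centred natural-log frequency and their interaction with
patient-varying intercepts (lme4, REML, Wald 95% CIs). Centring log
frequency at its sample mean makes the age and drug main effects
interpretable at a mid-spectrum reference frequency. The two-drug
variant adds drug and all interactions; its drug main effect is the
sevoflurane–propofol offset at that reference. A singular random-effect
fit falls back to fixed intercepts with a loud warning.

*Burst-suppression model.* The suppressed proportion is modelled with a
logit link as a weighted sum of scaled age, scaled brain age, binarised
ASA (1–2 vs 3) and the interactions of age and brain age with ASA.
Because age is in the model, the brain-age coefficient is conditional on
age — it captures the age-prediction error. The estimator is a
quasi-binomial GLM; inference uses HC1 sandwich standard errors because
between-patient variability of suppression acts multiplicatively on the
odds (logit-scale noise), under which model-based quasi-binomial
standard errors under-cover. An empirical-logit OLS is available behind
a flag, with the caveat that its epsilon adjustment compresses the logit
near zero and attenuates coefficients when many proportions are small —
on design-stage simulations the attenuation reached ~25% of the
brain-age effect, which is why it is not the default. "Scaled" means
z-scored within the analysis sample by default; recovery analyses
against the generator instead pass the generator's own centring (age 54,
scale 20.8 yr; brain age 54, scale 16 yr) so coefficients are on the
scale of the ground-truth logistic.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation between order statistics (R type 7),
  fixed so P25/P75 are reproducible.
* Ridge with all-constant features, or constant training ages, degrades
  to the training-mean prediction.
* SEF95 of a zero-power epoch is undefined; the channel is marked
  invalid and the epoch rejected.
* Band covariances are shrunk with the OAS intensity before any matrix
  logarithm; the generator's independent-noise floor keeps them positive
  definite in the first place.
* EDF I/O uses 1-s records, 16-bit samples, and a per-file symmetric
  physical range, so round-trips are exact to half a quantisation step.
* All randomness fans out deterministically from one base seed (cohort,
  patient, split, fold); regenerating with the same seed is
  bit-identical.

## Problem sizes in the tests and acceptance analyses

The test suite runs the study-shaped analyses at sizes chosen to give
stable statistics at interactive runtimes: the reference cohort for
skill/nesting checks uses n = 170 propofol ASA 1–2 patients (plus 79
sevoflurane) at 600-s recordings with 25 CV splits; the
drug-generalization direction check uses 100 splits; parameter-recovery
suites use 20 seeded replicates with 100-patient (mixed-drug, 300 s) and
204-patient (120 s, generation-only) cohorts. The acceptance script
regenerates a full 317-patient cohort at the study's 1200-s recording
length and 100 CV splits. Between-patient structure, not recording
length, limits model accuracy, so shorter records mainly trade off
spectral estimation noise.

## Known limitations

Brain-age deltas are not bias-corrected for regression toward the mean
(none is applied here); the generator's spatial model is
a two-source rotation rather than a physiological forward model; the
burst-suppression detector is a declared stand-in for the study's
annotation procedure; and accuracies obtained on synthetic cohorts
characterise the pipeline, not clinical performance.
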