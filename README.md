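# capox

Biophysical estimation of the cerebral **oxygen extraction fraction (OEF)**
from perfusion-derived capillary transit time statistics, with calibration
against PET oxygen measurements.

## The problem

Oxygen delivery to brain tissue depends not only on how much blood flows
through the capillary bed, but on *how long* blood spends there and on how
*heterogeneous* those transit times are. Bolus-tracking perfusion MRI
(DSC-MRI) yields voxelwise estimates of the mean transit time (MTT) and the
capillary transit time heterogeneity (CTH, the standard deviation of transit
times). `capox` turns those two hemodynamic statistics into an OEF estimate
through a biophysical model of oxygen transport, and provides the machinery
to calibrate and validate that model against gold-standard
<sup>15</sup>O-PET, the way a quantitative-neuroimaging group would in a
cohort study.

Intended users are researchers in perfusion MRI and cerebrovascular
physiology who want a tested, reproducible implementation of the
transit-time OEF model — not an image-processing pipeline (deconvolution,
segmentation and PET reconstruction are out of scope).

## The model

For a single capillary with transit time τ, the hemoglobin-bound oxygen
concentration C(x) along the normalized capillary axis x ∈ [0, 1] obeys

    dC/dx = −kτ · α_H · ( P50 · (C/(B−C))^(1/h) − P_tO2 ),   C(0) = S_a · B

where the bracket is the plasma–tissue oxygen tension gradient obtained by
inverting the Hill saturation curve S(P) = P^h / (P^h + P50^h). The single
capillary extracts Q(τ) = 1 − C(1)/C(0), and the tissue OEF averages Q over
a gamma distribution h(τ; α, β) of transit times with moments
MTT = αβ and CTH = √α·β:

    OEF = ∫₀^∞ h(τ) Q(τ) dτ

Constants (P50 = 26 mmHg, h = 2.8, B = 0.1943 mL O₂/mL, α_H = 3.1×10⁻⁵
mL O₂/mL/mmHg, S_a = 0.95) are standard literature values. The two free
parameters are calibrated in two steps:

1. **Tissue oxygen tension P_tO2** — as k → ∞ the transit-time distribution
   becomes irrelevant and OEF reaches the closed-form ceiling
   1 − S(P_tO2)/S_a. Requiring a ceiling of 0.6 (the upper limit reported
   for non-ischemic human brain) gives P_tO2 ≈ 21.8 mmHg.
2. **Transfer rate constant k** — with P_tO2 fixed, k is solved per subject
   so the model OEF in normal-appearing white matter matches that subject's
   PET OEF (OEF = K1(O₂)/CBF from one-tissue-compartment kinetics), and the
   cohort mean is adopted.

Agreement between model and PET OEF is then summarized by Pearson
correlation and Bland–Altman bias/limits of agreement.

## Worked example

```r
library(capox)

## the two calibration anchors
calibrate_pto2(0.6)                        # 21.83 mmHg
limit_extraction(25, oef_constants())      # 0.503 (the original 0.5 ceiling)

## OEF at cohort-mean hemodynamics, calibrated operating point
cst <- oef_constants(PtO2 = 21.8, k = 68)
oef(4.52, 5.45, cst)                       # 0.382  white matter
oef(3.40, 4.08, cst)                       # 0.350  gray matter

## full synthetic-cohort analysis
coh <- generate_cohort(n_subjects = 68, seed = 1)
fit <- oefcal(coh)        # calibrate PtO2 and k, estimate, compare
summary(fit)
```

The summary prints (abridged):

```
Two-step OEF model calibration
  Step 1: PtO2 = 21.829 mmHg (OEF ceiling 0.6, region 'NAWM')
  Step 2: k calibrated in 68 subject(s): mean 79.7, median 73.3, range [23.8, 283.4] 1/s

Agreement (model - PET), NAWM: n = 68
  Pearson r = 0.496 (p = 1.67e-05)
  Bland-Altman bias = 0.0154, limits [-0.0809, 0.1116]

OEF by region (mean [min; max]):
  GM     model 0.360 [0.313; 0.418]   PET 0.336 [0.179; 0.487]
  NAWM   model 0.398 [0.327; 0.454]   PET 0.383 [0.273; 0.522]
```

Read this as a miniature of the real study: the calibrated tension pins the
extraction ceiling at 0.6; per-subject rate constants scatter widely around
their cohort mean; the model correlates positively with PET but — because a
single common k is applied to everyone — compresses the between-subject OEF
range relative to PET (model 0.33–0.45 vs PET 0.27–0.52 in white matter).
`plot(fit)` draws the correlation and Bland–Altman panels;
`predict(fit, newdata, k = "subject")` switches to per-subject rate
constants; `run_pipeline()` wraps the same analysis around CSV/JSON file
I/O, and `oef_map()`/`oef_nifti()` apply the fitted model voxelwise.

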