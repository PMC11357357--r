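---
title: "Models and methods: hippocampal subfield change, diurnal cortisol, and their coupling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippostress)
```

## The scientific problem

Contemplative mental-training interventions are candidate tools for stress
reduction, and the hippocampus — the main inhibitory node of the
hypothalamic–pituitary–adrenal (HPA) axis — is the natural place to look
for stress-related structural plasticity. `hippostress` implements the
analysis chain of a longitudinal training design in which four cohorts
(two 9-month training cohorts of ~80 participants that practise three
3-month modules in counterbalanced order, one single-module active-control
cohort, and a retest control cohort of 90) are measured at four timepoints
(T0–T3, three months apart). At each timepoint the design yields
hippocampal subfield volumes (subiculum, CA1–3, CA4/DG, per hemisphere),
resting-state parcel time series for seed connectivity, two days of
diurnal saliva sampling, and a hair steroid segment.

The package's stages are: (1) a synthetic cohort generator with known
ground truth, (2) diurnal cortisol summary indices, (3) seed-connectivity
profiles and baseline functional networks, (4) module-labelled change
scores with mixed-model contrasts and univariate brain–cortisol
associations, and (5) behavioral partial least squares (PLS) linking the
brain-change matrix to the cortisol-change matrix. A single seed drives a
fully deterministic pipeline (`run_pipeline()`).

## Diurnal cortisol indices

Raw saliva concentrations (nmol/l; 7 occasions per day at 0, 30, 60, 240,
360, 480, 600 minutes after awakening, on two days) are processed in a
fixed order: natural log transform; winsorization of values diverging more
than 3 SD from the mean; averaging of the two days per occasion; then
index computation.

* **CAR** (cortisol awakening response): `S_peak − S_0` where the peak is
  the larger of the 30- and 60-minute samples. If the awakening sample
  already exceeds both, the 30-minute sample operationalizes the inverse
  response (it is the closer of the two post-awakening probes).
* **Diurnal slope**: `S_600 − S_0`; negative values are the normative
  decline.
* **AUCg** (area under the curve with respect to ground): trapezoidal area
  over the occasions {0, 240, 360, 480, 600}; the two CAR samples are
  excluded by design so the morning surge does not dominate the total
  output measure.

Decisions where the operationalization was genuinely open:

* **Winsorization domain.** "Across the full sample" does not say whether
  the reference distribution pools occasions. We compute mean/SD *per
  sampling occasion* (pooling subjects, timepoints and days), because
  occasions differ systematically in level — a 3-SD rule on the pooled
  distribution would almost never flag an implausible evening value. A
  `winsorize_scope = "global"` mode retains the pooled alternative. The
  pass is single and outliers are included in the estimate; re-running is
  only idempotent if the first-pass mean/SD are frozen
  (`winsorize_3sd(center=, scale=)`).
* **AUCg missingness.** All five included occasions are required; no
  interpolation. The trapezoid weights are time-gap dependent, so imputing
  a missing occasion silently rescales the index.
* **Abscissae.** Nominal design offsets are used for the trapezoid, not
  the jittered actual sampling times (non-morning probes are jittered ±15
  minutes to avoid predictability); `use_actual_times = TRUE` switches.
* **Hair.** Hair segments (pg/mg per 3-month segment) are natural-log
  transformed before differencing, consistent with the saliva handling; a
  flag disables the log.

## Connectivity

Inputs are *cleaned* parcel time series (T × 400, left parcels 1–200,
right 201–400) plus subfield seed series and six motion parameters;
upstream image processing is out of scope. Framewise displacement uses the
Power convention (sum of absolute translation changes plus 50 mm × sum of
absolute rotation changes). Scans with mean FD above 0.3 mm are excluded;
frames with FD ≥ 0.5 mm are censored together with their immediate
neighbours (frame deletion — equivalent to spike regression for a plain
correlation). Seed profiles are Pearson correlations to all 400 parcels,
Fisher r-to-z transformed (r clipped at 1 − 10⁻⁷ to keep z finite) and
min-max rescaled to [0, 1] per profile. Each subfield's functional network
is the top decile (ceiling(0.10 × 200) = 20) of *ipsilateral* parcels by
group-mean baseline profile, frozen for all later timepoints; ties break
toward the lower parcel index. Network-level change is the change in the
mean profile value over network parcels; region-level change is per-parcel
within the network with FDR across parcels.

Open choices: the rescale domain is the full 400-vector per
subject–timepoint–subfield (network selection uses only ipsilateral ranks,
which min-max preserves); "top 10%" is read as 10% of the 200 ipsilateral
candidates, with `ipsilateral = FALSE` available; group-mean selection
uses rescaled values rather than raw z (rank order within hemisphere is
what matters).

## Change-score models

Every measure (subfield volume, network connectivity, cortisol index) is
differenced over each consecutive 3-month interval with both endpoints
present and labelled by the module trained in that interval
(`module_schedule()`): the first training cohort runs
Presence–Affect–Perspective, the second Presence–Perspective–Affect, the
active-control cohort a single Affect module, and the retest cohort
nothing. Contrasts (`fit_contrast()`) model the change score on an arm
indicator plus age and sex, with a random intercept per subject when
subjects contribute several intervals (the within-subject
Affect-vs-Perspective contrast), degenerating to OLS — and, without
covariates, exactly to the classical two-sample t — when each subject
contributes once.

* **Degrees of freedom.** Wald t with a residual-df approximation
  (n − rank of the fixed design). A Satterthwaite correction would need
  machinery outside our dependency set; at the design's sizes (hundreds of
  records, df in the hundreds) the difference is negligible.
* **Cohen's D.** The source analyses report D without a formula. We define
  it from the t statistic: between subjects `d = t·√(1/n1+1/n2)`; within
  subjects `d = t/√n`. This is documented prominently because reported D
  values cannot disambiguate the convention.
* **Multiplicity.** Default Benjamini–Hochberg FDR per family (the six
  subfield × hemisphere tests of a contrast, or the parcels of a network),
  matching the q-value reporting style; Bonferroni is available. The
  source's Methods name Bonferroni while its Results report FDR q — we
  follow the Results convention by default.
* **Associations.** `associate_change()` regresses the brain change on the
  cortisol change plus age and sex within a module (OLS), adding a random
  subject intercept when modules are pooled.

## Behavioral PLS

Brain-change columns are residualized on age, sex and subject indicator
variables (fixed-effect absorption of the random subject effect; the
projection tolerates the inherent collinearity of subject dummies with
subject-constant covariates). Both matrices are z-scored within training
groups, which removes group mean offsets before a *whole-sample* row
permutation. The cross-covariance `t(Y) X/(n−1)` is decomposed by SVD;
components are oriented so the dominant behavior salience is positive.
Percent cross-covariance explained is `s_i²/Σs²` — reported percentages of
this kind are interpreted as covariance explained, which we document as an
interpretation rather than assert. Significance: 1000 row permutations of
Y by default, add-one p-values on same-rank singular values (no Procrustes
rotation; inference focuses on the first component), BH-FDR across
components. Stability: 100 bootstrap resamples of subject blocks,
sign-aligned to the original solution by salience congruence, percentile
CIs on loading correlations.

A caveat the calibration tests make visible: change scores of the same
subject are *negatively* dependent across consecutive intervals (they
share the middle measurement, and subject absorption centres each
subject's brain rows), which whole-sample row permutation ignores. The
permutation p-value for the first component is therefore mildly liberal
(null FDR rejections run at ~6–7% rather than 5% in our null
calibration). Within-group permutation (`within_group_perm = TRUE`) does
not remove this; a subject-block permutation scheme would, but the
standard procedure permutes rows and we keep it.

## The synthetic cohort generator

`simulate_cohort()` emulates the design so every downstream stage is
testable without access to the original (non-shareable) data. The
generator is a *stated world*, not a tuning dial; its defaults are fixed
at the design's published scale:

* Cohort sizes 80/81/81/90; age 40.7 ± 9.2 years truncated to 20–55; 59%
  women (197/332). Age and sex are generated independently of all effects
  by default, so covariate adjustment is exercised against a known-null
  confounding structure.
* Volumes per subfield are a subject-level baseline (e.g. CA1–3
  2200 ± 250 mm³) plus per-interval increments with SD `volume_change_sd`
  (CA1–3: 170 mm³, on the scale of the observed change SDs). A module
  effect is a standardized shift of the increment: the default
  `Affect:CA1–3 = 0.35` on both hemispheres reproduces the reported
  effect-size scale of the socio-affective module. A stable subject
  "plasticity" trait carries 20% of increment variance, giving change
  scores a realistic within-person correlation.
* Saliva follows the log-scale diurnal curve: awakening level 2.7
  log-nmol/l (≈15 nmol/l), awakening-response bump 0.4 at 30 min (60% of
  it left at 60 min), log-linear decline 1/300 per minute (≈2 log units
  over the day), per-sample noise SD 0.15, subject level SD 0.25, and a
  per-timepoint diurnal state offset whose increments (SD 0.3) are what
  the brain coupling acts on. Concentrations are exponentiated, hence
  strictly positive.
* **Coupling.** A shared latent factor per subject-interval mixes into the
  CA1–3 volume increment and the diurnal state increment so that the
  correlation between volume change and *measured* AUCg change equals the
  configured `coupling_r = −0.23` (back-computed from the reported
  association t = −2.283 at n = 92 via `r = t/√(t²+n−2)`). The generator
  compensates analytically for attenuation by saliva measurement noise
  (trapezoid-weighted noise variance of the AUCg); recovery at n = 10⁴ is
  within ±0.05 by test. Hair coupling defaults to −0.37 (same
  back-computation from t = −2.574 at n = 44).
* **Connectivity ground truth.** Disjoint 20-parcel ipsilateral blocks per
  subfield receive the seed's latent signal with mixing weight 0.5
  (high-SNR regime; test: top-decile selection recovers planted membership
  with Jaccard ≥ 0.9). Motion is constructed so the Power FD of the series
  equals a drawn per-frame target, with ~3% of scans drawn from a
  high-motion regime that trips the 0.3 mm exclusion — mirroring the <5%
  exclusion rate of the emulated study. Scans default to 205 frames (210
  acquired minus 5 dummy volumes).
* **Missingness** is MCAR deletion of whole subject-timepoints (the
  attrition tables of the emulated study give causes but no mechanism;
  MAR variants would be a config extension), never orphaning a subject.

What a green test does *not* establish: the generator has no fMRI
autocorrelation (frames are i.i.d.), no adherence artefacts in saliva
sampling, no assay batch effects, no covariate confounding by default, and
volumes are generated directly (the upstream segmentation algorithm is out
of scope). Conclusions from the synthetic world are about the *analysis
code*, not about the biology.

## Numerical choices and degenerate inputs

Correlations are clipped at 1 − 10⁻⁷ before `atanh`; a degenerate profile
(all z equal) errors rather than rescaling 0/0; zero-variance parcels are
excluded from rescale extrema and imputed at the profile minimum with a
warning; a constant cortisol regressor errors; zero within-group SD in PLS
normalization leaves the column centered with a warning; degenerate
bootstrap resamples are redrawn at most 10 times; permutation p-values use
the add-one convention so they are never zero. All randomness is derived
from one root seed via per-stage seeds, so reports are byte-identical
across runs (timestamps are deliberately absent, and the output path is
excluded from the echoed config).

## Runtime scaling in the tests

The acceptance suite states its scale inline: null calibration uses 500
replicate cohorts of 40 subjects per training cohort (type-I error does
not depend on n) with 200 permutations per PLS (only the q < 0.05 decision
is consumed); parameter recovery uses 100 replicates at the full design
size. The end-to-end smoke configuration (20 training subjects, 40–60
frames, ≤200 permutations) completes in seconds.

## Known limitations

* No Satterthwaite/Kenward–Roger df; no ICV covariate beyond an optional
  extra column; no vertex- or voxel-wise statistics; no hippocampal
  long-axis models.
* The permutation scheme's mild liberality under within-subject dependence
  (above).
* YAML run configs are not supported in this environment; configs are
  JSON (`--config` files and the echoed `config.json`).
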