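# hippostress

Longitudinal analysis of hippocampal subfield volume, seed functional
connectivity and cortisol in mental-training intervention designs — plus a
synthetic cohort generator with known ground truth so the whole chain is
testable end to end.

## Who this is for

Biostatisticians and imaging researchers analysing longitudinal
intervention studies in which four cohorts (two 9-month training cohorts,
a single-module active-control cohort and a retest control cohort) are
measured at four 3-month timepoints (T0–T3), yielding per timepoint:
hippocampal subfield volumes (L/R × subiculum, CA1–3, CA4/DG, mm³),
resting-state parcel time series (T × 400, Schaefer-400 order) with
subfield seed series and motion parameters, two-day diurnal saliva
profiles (7 samples/day at 0, 30, 60, 240, 360, 480, 600 min after
awakening), and hair steroid segments (pg/mg per 3 months).

## What it computes

* **Diurnal cortisol indices** (`diurnal_indices()`), after natural-log
  transform, per-occasion 3-SD winsorization and two-day averaging:
  - CAR `= S_peak − S_0`, peak the larger of the 30/60-min samples (the
    30-min sample operationalizes an inverse response);
  - slope `= S_600 − S_0`;
  - AUCg: trapezoidal area over {0, 240, 360, 480, 600} min — the two CAR
    samples are excluded from total output.
* **Connectivity** (`connectivity_stage()`): Power framewise displacement,
  mean-FD > 0.3 mm scan exclusion, ±1-frame scrubbing at FD ≥ 0.5 mm,
  seed–parcel Pearson r → Fisher z → per-profile min-max rescale to
  [0, 1], baseline top-10% ipsilateral networks (20 of 200 parcels,
  frozen), network-mean and per-parcel change.
* **Contrasts** (`fit_contrast()`): change scores Δ = value(Tb) −
  value(Ta) per consecutive interval, labelled by the trained module;
  linear mixed model `Δ ~ arm + age + sex + (1 | subject)` (OLS when
  subjects contribute once), Cohen's D (`t·√(1/n1+1/n2)` between,
  `t/√n` within), BH-FDR or Bonferroni families; univariate brain–cortisol
  change associations (`associate_change()`).
* **Behavioral PLS** (`behavioral_pls()`): brain-change matrix
  residualized on age/sex/subject, within-group z-scoring, SVD of
  `t(Y)X/(n−1)`, 1000 row permutations (add-one p, FDR across
  components), 100 subject-block bootstraps with percentile CIs on loading
  correlations, per-module latent score correlations.
* **Synthetic cohorts** (`sim_config()`, `simulate_cohort()`): the design
  above with planted effects — standardized module effects on subfield
  change (default: Affect d = 0.35 on bilateral CA1–3), latent coupling
  between CA1–3 volume change and measured AUCg change (default
  r = −0.23; hair r = −0.37), planted 20-parcel seed networks, MCAR
  attrition. See the methods vignette for every default and its
  rationale.

## Worked example

```r
library(hippostress)

cfg <- sim_config(n_per_cohort = c(TC1 = 60L, TC2 = 60L, TC3 = 20L,
                                   RCC = 20L), seed = 42L)
ds  <- simulate_cohort(cfg, include = c("volumes", "saliva"))
idx <- diurnal_indices(ds$saliva)
changes <- build_change_records(
  rbind(measures_from_volumes(ds$volumes), measures_from_indices(idx)),
  ds$subjects)

fit_contrast(changes[measure == "volume:R_CA13"], "Affect_vs_Perspective")
#> <contrast_result> Affect_vs_Perspective (within)
#>   t = 4.291, df = 236, p = 2.595e-05, Cohen's D = 0.392
#>   arm A: n = 120, mean = 65.002 (sd 165.090)
#>   arm B: n = 120, mean = -24.874 (sd 186.765)
```

Right CA1–3 grew by 65 mm³ on average during Affect intervals and shrank
during Perspective intervals; the within-subject contrast standardizes to
D ≈ 0.39 here (the generator plants d = 0.35 plus sampling noise).

```r
associate_change(changes[measure == "volume:R_CA13"],
                 changes[measure == "cortisol:aucg"], modules = "Affect")
#> $t      -2.460
#> $p       0.015   # slope sign -1
```

Subjects whose CA1–3 grew more during Affect reduced their total diurnal
cortisol output more (the planted coupling of r = −0.23).

```r
pin <- assemble_pls_input(changes, model = "all")
behavioral_pls(pin$X, pin$Y, pin$groups, pin$age, pin$sex, pin$subject,
               n_perm = 1000, n_boot = 100, seed = 1L)
#> <pls_result> 380 rows, 6 brain x 3 behavior variables
#>  LC singular_value covexp_pct   perm_p  fdr_q
#>   1         0.3639       73.4 0.000999 0.0015
#>   2         0.2142       25.4 0.000999 0.0015
#>   3         0.0462        1.2 0.618000 0.6180
```

LC1 (73% of cross-covariance, permutation p ≈ 0.001) pairs bilateral
CA1–3 volume increases with AUCg decreases — the planted structure.
Inference focuses on LC1: raw-singular-value permutation is known to be
liberal for later components when the first is strong (see the methods
vignette).

A full deterministic run (simulate → cortisol → connectivity → contrasts
→ associations → PLS, with per-stage accounting and `report.json`):

```r
report <- run_pipeline(run_config(seed = 1L, out = "run"))
```

or from the shell (`inst/cli/hippostress` is an executable Rscript):

```sh
hippostress run --seed 1 --out run
hippostress simulate --seed 1 --out cohort
hippostress cortisol --saliva cohort/saliva.tsv --out indices.tsv
```

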