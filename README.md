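# ventmech2g

Two-geometry (2G) patient-specific right-ventricle mechanics and the cohort
statistics used to predict post pulmonary-valve-replacement (PVR) outcome in
repaired Tetralogy of Fallot.

Conventional image-based ventricle models use a single zero-load reference
geometry for the whole cardiac cycle (1G). Because diastolic filling and
systolic ejection start from different unloaded states of the muscle, a 1G
model aliases end-filling onto begin-ejection and end-ejection onto
begin-filling, and misstates wall stress and strain at those time points. The
2G approach calibrates **two** zero-load geometries — one for the diastolic
phase, one for the systolic phase — by iteratively pre-shrinking the imaged
minimum-volume geometry until a finite-element inflation reproduces the
measured pressure–volume points of each phase.

The package provides:

- **Constitutive law** — anisotropic modified Mooney–Rivlin strain energy with
  an exponential fiber term, analytic PK2/Cauchy stress, the five-ratio planar
  biaxial protocol, and linear least-squares parameter fitting
  (`material_params`, `stress_from_energy`, `biaxial_response`, `fit_biaxial`).
- **Mechanics solver** — total-Lagrangian 8-node hexahedral FE inflation with
  selective reduced integration, follower pressure on the endocardium, Newton
  iteration with line search and adaptive load ramping; element kernels in
  Rcpp (`solve_inflation`, `thick_sphere_inflation` as a semi-analytic
  verification oracle).
- **Geometry** — idealized slice-stack ventricles, hexahedral meshing between
  stacked short-axis contours, rule-based fiber angles (+40° endo / −45° epi),
  the wall-volume-conserving pre-shrink map (`make_idealized_ventricle`,
  `mesh_from_slices`, `preshrink`).
- **2G calibration** — zero-load geometry search (regula falsi on the shrink
  rate), material stiffness-scale calibration, and the alternating two-phase
  2G construction with cycle-periodicity checking (`calibrate_zero_load`,
  `calibrate_material`, `calibrate_twog`, `run_cardiac_cycle_2g`,
  `run_cardiac_cycle_1g`).
- **Extraction** — maximum principal stress/strain sampled at equal-arclength
  points on mid-wall slice contours, per-time-point summaries, and a
  mesh-independence study driver (`sample_slice_points`, `summarize_cycle`,
  `mesh_independence`).
- **Cohort statistics** — the bundled published per-participant fixture
  (`load_cohort`), exact mid-rank Wilcoxon rank-sum and signed-rank tests,
  exact-permutation Spearman correlation, gradient-descent logistic
  regression, and repeated stratified 5-fold cross-validation
  (`wilcoxon_rank_sum`, `spearman_rank`, `fit_logistic_gd`, `cross_validate`,
  `group_report`).

## Worked example

```r
library(ventmech2g)

## 1. Cohort statistics on the bundled per-participant fixture --------------
co <- load_cohort()
rep <- group_report(co)
subset(rep$means, group == "ALL" & generation == "2G" & quantity == "stress")
#> end-ejection row reproduces the published 14.54 +/- 7.41 kPa

rep$spearman[rep$spearman$against == "delta_ef_pct", c("variable", "rho", "p_value")]
#> rho(delta EF, 2G EF stress) = -0.650, rho(delta EF, 2G BE stress) = -0.608

## Outcome prediction: better vs worse post-PVR EF recovery
cv <- cross_validate("stress_2g_ef", co, k = 5, repeats = 200, seed = 1)
cv$accuracy   # ~0.82
cv$auc

## 2. A 2G model of an idealized ventricle -----------------------------------
iv <- make_idealized_ventricle()
v0 <- stack_cavity_volume(iv$stack)
targets <- list(BF = v0, EF = 1.25 * v0, BE = 1.25 * v0, EE = v0)
profile <- make_pressure_profile(30, p_min = 2, p_ed = 8, p_es = 12)  # mmHg

m2g <- calibrate_twog(iv$stack, targets, profile,
                      params_diastole = material_params(),
                      params_systole = scale_stiffness(material_params(), 4))
states <- run_cardiac_cycle_2g(m2g)

sm <- summarize_cycle(states, stacks = list(
  BF = m2g$diastole_geom$stack, EF = m2g$diastole_geom$stack,
  BE = m2g$systole_geom$stack,  EE = m2g$systole_geom$stack),
  generation = "2G")
sm   # mean max-principal stress/strain at BF, EF, BE, EE:
     # stress(BE) > stress(EF) and stress(EE) > stress(BF), the 2G signature

## 3. Constitutive fitting from biaxial data ---------------------------------
truth <- material_params(c1 = 0.8, D1 = 0.6, K1 = 1.2)
dat <- do.call(rbind, lapply(c("10:10", "7.5:10", "5:10", "10:7.5", "10:5"),
                             function(r) biaxial_response(truth, ratio = r)))
coef(fit_biaxial(dat))  # recovers c1, D1, K1
```

Units: mm (length), mmHg (pressure input), kPa (stress and material
parameters), cm³ (cavity volume).

## Verification

`tests/testthat/` contains the unit and property suite plus
`test-acceptance.R`, one test per acceptance criterion (published-table
reproduction, Spearman and Wilcoxon agreement, repeated-CV prediction,
analytic mechanics oracles, 2G calibration tolerances, biaxial recovery).
`scripts/acceptance.R` recomputes the headline numeric targets and writes
them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

The methods vignette (`vignettes/methods.Rmd`) documents the model equations,
the calibration algorithms, and the reproduction conventions used for the
published tables.
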