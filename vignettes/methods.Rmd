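---
title: "Two-geometry ventricle mechanics: methods and reproduction conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-geometry ventricle mechanics: methods and reproduction conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ventmech2g)
```

## 1. The two-geometry (2G) idea

A ventricle's wall stress and strain are only defined relative to a zero-load
(zero-stress) reference configuration, which is never observed in vivo: even
the minimum-volume image frame carries a begin-diastole pressure. Conventional
single-geometry (1G) models estimate one zero-load state and use it for the
whole cycle. But the muscle that fills during diastole is materially different
from the muscle that ejects during systole (active contraction stiffens it),
so the two phases have *different* unloaded states. A 1G model therefore
aliases end-filling (EF) onto begin-ejection (BE) and end-ejection (EE) onto
begin-filling (BF): it has only two native states for four cardiac time
points, and `run_cardiac_cycle_1g()` records that aliasing explicitly.

The 2G construction calibrates two zero-load geometries from the same imaged
minimum-volume slice stack:

- the **diastolic** geometry, loaded from begin-filling pressure to
  end-diastole pressure with the passive material;
- the **systolic** geometry, loaded from end-systole pressure to peak pressure
  with the stiffer contracted material.

Each phase then reproduces its own two pressure–volume points, and the four
time points BF, EF, BE, EE get genuinely distinct mechanical states.

## 2. Constitutive model

The strain energy is an anisotropic modified Mooney–Rivlin law,

$$W = c_1 (I_1 - 3) + c_2 (I_2 - 3) + D_1\left[e^{D_2 (I_1 - 3)} - 1\right]
      + \frac{K_1}{K_2}\left[e^{K_2 (I_4 - 1)^2} - 1\right],$$

with $I_1, I_2$ the isotropic invariants of $C = F^\top F$ and
$I_4 = \mathbf{n}_f^\top C\, \mathbf{n}_f$ the squared fiber stretch. Two
implementation details:

- A $-\beta \ln J$ compensation term with $\beta = 2c_1 + 4c_2 + 2 D_1 D_2$ is
  added so that the stress vanishes exactly at $F = I$ (the straight invariant
  terms alone carry a rest hydrostatic stress). The term vanishes identically
  on incompressible ($J = 1$) paths.
- Near-incompressibility is enforced by a volumetric penalty
  $\tfrac{1}{2}\kappa (J-1)^2$ with $\kappa = 100\,(c_1 + D_1 + K_1)$ by
  default.

The published exponential fiber term is garbled in the source table
(dimensionally unusable as printed); the form above is the standard one from
the authors' prior formulation, with $K_2$ dimensionless. `stress_from_energy()`
returns the analytic PK2 and Cauchy stresses; the test suite verifies
$S = \partial W / \partial E$ against central finite differences to $10^{-5}$.

Default passive parameters ($c_1 = 0.8$, $c_2 = 0$, $D_1 = 0.6$, $D_2 = 3$,
$K_1 = 1.2$, $K_2 = 3$; kPa where dimensional) freeze $c_2, D_2, K_2$ at their
published values and place $c_1, D_1, K_1$ in the soft passive-myocardium
range. Fiber angles are rule-based: $+40^\circ$ at the endocardium to
$-45^\circ$ at the epicardium, interpolated through the wall.

### Biaxial protocol and fitting

`biaxial_response()` emulates the five-ratio planar biaxial protocol
(stress ratios 10:10, 7.5:10, 5:10, 10:7.5, 10:5, fiber : cross-fiber) on an
incompressible thin sheet; the ratio labels are *equal-stress* protocols, so
anisotropy shows up as the cross-fiber direction stretching further at the
same stress. With $c_2, D_2, K_2$ frozen the predicted stresses are linear in
$(c_1, D_1, K_1)$ and `fit_biaxial()` is an exact linear least-squares solve.
Residuals are weighted by inverse stress magnitude (floored at 1% of the
largest stress): biaxial stresses span orders of magnitude across the stretch
range and rig noise is predominantly multiplicative, and the relative-error
fit conditions the nearly collinear $c_1$/$D_1$ pair far better than an
absolute-error fit.

## 3. Finite-element inflation solver

`solve_inflation()` is a total-Lagrangian 8-node hexahedral solver with
selective reduced integration (full $2^3$ quadrature on the deviatoric part,
single-point on the volumetric penalty, preventing locking), follower
pressure on the endocardial surface (load stiffness included in the tangent),
and Newton iteration with backtracking line search under adaptive load
ramping. Rigid modes are removed by tangential point pins that exert zero
reaction on radially symmetric fields. Pressures are supplied in mmHg and
converted internally (`mmHg_to_kPa`, 1 mmHg = 0.1333224 kPa); lengths are mm,
stresses kPa, cavity volumes cm³.

When a previous displacement field is supplied (`init_disp`), the solver first
attempts a single Newton solve at the full load and only falls back to
ramping on failure; this keeps repeated cardiac cycles bit-stable (period
difference exactly zero) instead of wandering along the near-rigid-mode
valley on every re-ramp.

Verification oracles, all asserted in the test suite:

- `thick_sphere_inflation()`: semi-analytic incompressible thick-sphere
  quadrature; the FE solver matches its cavity volume within 2% at the
  converged mesh (`sphere_shell_mesh`, cubed-sphere hexahedra).
- The neo-Hookean limit ($D_1 = 0$) of the sphere oracle against the textbook
  closed form to $10^{-6}$.
- Small-pressure linear elasticity (Lamé thick-sphere solution).
- Internal force = gradient of assembled energy, by finite differences.

## 4. Calibration

**Zero-load geometry** (`calibrate_zero_load`). The imaged minimum-volume
stack is pre-shrunk by a rate $s$: inner contours scale by $1-s$ about the
long axis, slice spacing by $1 - s_{\text{long}}$ about the base plane, and
each slice's outer contour is solved so that wall volume is conserved.
The inflated cavity volume at begin-diastole pressure is monotone in $s$, and
an Illinois regula-falsi iteration finds the $s$ whose inflation reproduces
the target volume within 0.5% (the published tolerance).

**Material scale** (`calibrate_material`). With the geometry fixed, a single
stiffness scale multiplying $(c_1, c_2, D_1, K_1)$ (exponents frozen) is
calibrated so the model reproduces a prescribed pressure–volume target within
0.2%: a log-scale secant iteration for one target, golden-section on the
summed error for several.

**2G construction** (`calibrate_twog`). Geometry and material calibration
alternate per phase until both tolerances hold simultaneously, then the
systolic phase repeats on the stiffer contracted material. An important
degeneracy, documented here because it constrains experiment design: the
inflation map satisfies $V(p;\, s\theta) = V(p/s;\, \theta)$ exactly for a
stiffness scale $s$, so each phase's two pressure–volume targets constrain
the (shrink, scale) pair only through the *pressure ratio*
$p_{\text{high}}/p_{\text{low}}$. If diastole and systole are given equal
pressure ratios, their calibrated zero-load geometries coincide up to noise
and the 2G model degenerates to 1G. Physiological profiles avoid this: the
default profile (`make_pressure_profile`) uses right-ventricular values where
ejection ends at the pulmonary-artery diastolic pressure, about 40% of peak.

## 5. Extraction and summaries

Stress and strain are reported as the maximum principal value of the Cauchy
stress and the Green–Lagrange strain, sampled at `n_per_slice` equal-arclength
points on the mid-wall contour of every short-axis slice
(`sample_slice_points`, inverse-distance weighting over the nearest
quadrature points), then averaged per time point (`summarize_cycle`).
`mesh_independence()` runs the refinement sequence and selects the first
density whose slice-sampled fields change less than the tolerance.

## 6. Cohort fixture and reproduction conventions

`load_cohort()` returns the bundled per-participant table: 6 healthy controls
(HG) and 12 Tetralogy of Fallot patients (TG), the latter split at the median
post-PVR ejection-fraction change into better-outcome (BG) and worse-outcome
(WG) groups, with 1G and 2G maximum principal stress (kPa) and strain at the
four time points. `group_report()` reproduces the published summary tables
from it. Conventions adopted (each verified in `test-acceptance.R` and
recorded in the fixture header):

- **Percent differences** in the published narrative were computed from the
  *rounded* table means (e.g. $321.4\% = 14.54/3.45 - 1$, while full-precision
  means give $320.2\%$). `group_report()` reports both (`pct_full`,
  `pct_printed`).
- The published "57.4%" begin-ejection group gap contradicts its own quoted
  means (86.94 vs 52.93 kPa gives 64.3%) and is excluded from reproduction.
- The healthy-group begin-filling strain prints "0.308" in one table and
  "0.031" in another; 0.031 is consistent with the per-participant values.
- **Degenerate predictor rows** (sensitivity 1.0000, specificity 0.0000,
  accuracy 0.5000) are the signature of a null logistic model predicting
  every case positive at threshold 0.5 — on the exactly balanced sex
  predictor the full-data fit is $\beta = (0, 0)$ and every prediction is
  exactly 0.5.

Statistics are exact where feasible: mid-rank Wilcoxon rank-sum and
signed-rank tests via the shift/convolution algorithm (brute-force
enumeration is the independent test oracle), exact-permutation Spearman
p-values for $n \le 8$, and a t-approximation above. The prediction protocol
is gradient-descent logistic regression (standardized predictor, separation
detection with a coefficient cap) under stratified 5-fold cross-validation
repeated 200 times with pooled per-repeat confusion and ROC
(`cross_validate`).

## 7. Headline reproduction

```{r headline}
co <- load_cohort()
rep <- group_report(co)

# published table cells, e.g. all-18 2G end-ejection stress 14.54 +/- 7.41 kPa
subset(rep$means, group == "ALL" & generation == "2G" & quantity == "stress")

# Spearman: rho(delta EF, 2G EF stress) = -0.650; rho(delta EF, 2G BE) = -0.608
subset(rep$spearman, against == "delta_ef_pct")

# repeated-CV outcome prediction, accuracy ~0.82 (EF stress), AUC ~0.81 (EE)
cross_validate("stress_2g_ef", co, repeats = 200, seed = 1)$accuracy
cross_validate("stress_2g_ee", co, repeats = 200, seed = 1)$auc
```
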