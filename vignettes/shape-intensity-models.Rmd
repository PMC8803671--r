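---
title: "Statistical shape-and-intensity modelling of the proximal femur for fracture risk classification"
author: "ssimfem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape-and-intensity modelling of the proximal femur}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssimfem)
```

## The problem

Areal bone mineral density (aBMD), the clinical gold standard for hip
fracture risk, is a single projected average: it cannot see how bone mass is
distributed through the proximal femur, nor how femoral geometry modulates
load. Statistical models built from quantitative CT capture both. This
package implements a supervised pipeline of that kind: each femur is encoded
by (i) a *moment-vector field* describing the deformation that carries a
population template onto the subject's surface, and (ii) an *element-wise
bone mineral density vector* sampled on a template tetrahedral mesh morphed
onto the subject (iso-topological meshes, so element $k$ corresponds across
subjects). Partial least squares (PLS) against the binary fracture status
extracts, from each representation, the modes that covary most with
fracture; logistic regression on the leading components classifies, and
balanced cross-validation measures discrimination.

Three statistical models are compared, plus the clinical baseline:

* **SSM** — shape only: PLS on the $N \times 3q$ moment matrix $X_\beta$;
* **SIM** — intensity only: PLS on the $N \times n$ element density matrix $G$;
* **SSIM** — two-level fusion: PLS on the concatenation of the leading SSM
  and SIM *component* columns;
* **aBMD analogue** — logistic regression on a single areal-projection
  scalar.

## Shape representation: kernel deformations on a control grid

A subject's shape is parameterised by moment vectors $\beta_k \in
\mathbb{R}^3$ attached to a shared regular control grid $c_1,\dots,c_q$. A
point $x$ of the template is carried to

$$x \;\mapsto\; x + \sum_{k=1}^{q} \exp\!\left(-\|x - c_k\|^2 / w^2\right)\beta_k,$$

a single-step Gaussian-kernel *small-deformation* model. This is a
deliberate modelling departure from geodesic (LDDMM-style) atlas estimation:
it preserves the data structure the statistics consume — moments on a
control grid, flattened row-major as
$(\beta_{x1}, \beta_{y1}, \beta_{z1}, \ldots)$ into the rows of $X_\beta$ —
while remaining a closed-form linear operator. Linearity in $\beta$ is
exact and is tested to machine precision.

Subjects are first aligned rigidly: head centres are superposed and
neck-shaft axes aligned, with the residual roll about the neck axis resolved
by aligning shaft axes (anti-parallel axes flip about the component of the
reference shaft axis perpendicular to the neck axis); then point-to-point
ICP (Kabsch updates with the SVD determinant correction) refines the pose.
Moments are fitted by alternating nearest-neighbour correspondence with a
ridge-regularised least-squares solve; the ridge default is
$10^{-6}\,\mathrm{tr}(K_{\mathrm{grid}}) = 10^{-6}q$, a scale-free
conditioning floor.

**Identifiability caveat.** Gaussian-kernel systems are famously
ill-conditioned: with the default kernel width (twice the grid spacing) the
surface-to-grid kernel matrix has a fast-decaying spectrum, so only
*spatially smooth* moment fields are identifiable from surface
displacements. The registration-recovery tests therefore draw ground-truth
moments from the kernel-smoothed (identifiable) range and scale them so the
maximum surface displacement stays well under the surface point spacing
(the small-deformation regime, where nearest-neighbour correspondence is
exact). Recovery there is at the 0.1% level, far inside the 5% contract.
Rough, high-frequency moment patterns are *not* recoverable by any method
under this kernel — a property of the model, not of the implementation.

## Intensity representation

Image intensities are calibrated to density by an ordinary least-squares
line fitted to a five-sample hydroxyapatite phantom (0–200 mg/cm³ range in
standard use). One density value is sampled per tetrahedral element on the
morphed mesh, by default at the element centroid (a mean over the four
nodes and centroid is available); Bonemat-style volume-weighted HU
integration is intentionally replaced by this configurable sampling rule,
which is all the SIM requires. Negative calibrated densities are clamped to
zero and the clamp count logged. The aBMD analogue divides total mineral
mass $\sum_e \rho_e V_e$ by the area of the mesh shadow on the frontal
plane (exact for the box-decomposed synthetic meshes), converted to g/cm².

## PLS mode extraction

All three models use NIPALS PLS1 on column-centered data against the
centered 0/1 status array. For mode $j$:

$$w_j = \frac{X_j^\top y_j}{\|X_j^\top y_j\|}, \quad t_j = X_j w_j, \quad
p_j = \frac{X_j^\top t_j}{t_j^\top t_j}, \quad q_j = \frac{y_j^\top t_j}{t_j^\top t_j},$$

with deflation $X_{j+1} = X_j - t_j p_j^\top$, $y_{j+1} = y_j - q_j t_j$.
Any representation is reconstructed as $x^i = \bar{x} + \sum_j t_j^i p_j$;
with all extractable modes this reproduces the training data to $10^{-8}$
relative Frobenius error, and successive components are orthogonal
(both tested). Columns are **not** variance-scaled by default: each block
has homogeneous units (a `scale` flag exists). Mode signs follow a
reproducibility convention — the largest-magnitude entry of each weight
vector is made positive. "Mode variance" $\sigma_j^2$ is defined as
$\mathrm{var}(t_j)$, and modes are visualised by exporting
$\bar{x} \pm \sigma_j p_j$ decoded back to a deformed surface (PLY) or an
element field (legacy VTK).

New subjects are projected by the sequential deflating projection
($t_j = e^\top w_j$, $e \leftarrow e - t_j p_j$), which returns stored
training components exactly.

### Two-level SSIM and its block sizes

The SSIM concatenates the leading SSM and SIM component columns and runs a
second PLS against status. How many columns to concatenate is genuinely
open. We default to **two components per block**, matching the number of
predictors used downstream, for a reason specific to *supervised*
decompositions: every PLS mode is extracted to covary with the status
array, so trailing modes chase residual noise that correlates with $y$ only
in-sample. Concatenating the full set needed to explain 90% of the data
variance (often dozens of columns at $N \approx 100$) demonstrably overfits
the second level — in our experiments it pushed the cross-validated SSIM
below the SIM it is built from. The block sizes remain configurable
(`m_shape`, `m_int`), and the observation that very few fused modes carry
nearly all the status-related variation supports the small default. The
blocks are not rescaled relative to each other (component variances already
carry the within-block scale).

## Outlier screening

Before model fitting, subjects are screened by Cook's distance within a
leave-one-out approach, applied to the regression of status on the leading
PLS components (raw matrices have $p \gg N$, so the classical OLS influence
formulation applies to the component regression, with the PLS decomposition
fitted once on the full cohort). Each $D_i$ is computed by the literal
refit route — drop subject $i$, refit the component regression, measure the
shift of all fitted values — normalised by $p_\mathrm{eff} s^2$ with
$p_\mathrm{eff} = m + 1$ and $s^2$ the full-model residual mean square;
this equals the textbook hat-matrix formula, which the tests use as an
independent oracle.

The flagging threshold defaults to the classical $D_i > 1$ rule rather than
the $4/N$ convention: on clean cohorts of this size $4/N$ flags a handful
of benign subjects on every run (as it does for any OLS fit), which would
contradict both the intended use (screening gross errors) and the behaviour
expected of clean data. Injected six-sigma, label-inconsistent subjects
score $D \approx 1.3$–$2.4$ against benign maxima of $\approx 0.4$, so the
rule separates cleanly; $4/N$ remains available via the `threshold`
argument. Note that an outlier displaced *toward its own class* is
low-influence by construction and is correctly not flagged — influence is a
property of the fit, not of geometric extremity.

## Classification and validation

Logistic regression (IRLS on internally standardised predictors, converged
when the largest coefficient update is below $10^{-8}$; quasi-separation
triggers a ridge ($10^{-4}$) refit with a flag) uses the first two PLS
components as predictors. Validation is stratified balanced $k$-fold
($k = 10$): each class is shuffled and dealt round-robin, each class
starting where the previous left off, so fold sizes and per-fold class
counts deviate from perfect stratification by at most one. **Within every
fold the entire statistical model — including both SSIM levels — is refitted
on training subjects only**; test subjects are only ever projected (a
leakage guard asserted in the tests). Test-fold scores are pooled into a
single ROC curve; AUC uses the Mann–Whitney pair statistic with ties
counted one half; the 95% CI is a class-stratified bootstrap percentile
interval (2000 resamples by default — the CI method is a package choice, as
none is standard for pooled CV scores); confusion matrices use a fixed 0.5
threshold.

## The synthetic cohort generator

No imaging data accompany the package; a seeded generator stands in for the
study cohort and *defines the reference conditions* for every statistical
test. Defaults: $N = 93$ subjects, 46 fractured / 47 non-fractured, $q=27$
control points, ~800 tetrahedral elements on a stylized femur (shaft and
neck cylinders plus an offset head sphere, voxel-meshed by six-tetrahedron
cube decomposition — the pipeline is geometry-agnostic, and every
acceptance property is statistical, not anatomical).

The statistical structure, drawn from a single documented RNG stream:

* a **shape latent** with class-conditional shift $d_s = 0.3$ (weak, per
  the field's consistent finding that geometry alone discriminates
  modestly) along a fixed unit direction in moment space;
* an **intensity latent** with shift $d_i = 1.0$ (strong) along a direction
  blending the overall bone-mass direction (element volumes, weight 0.5)
  with a random direction — overall mass dominates real density variation,
  but an areal projection sees only its mass component;
* an **interaction** of strength $d_{si} = 1.0$: subjects whose shape *and*
  intensity latent scores are both low (the fracture-prone tail of each)
  receive an *added* density contribution along the intensity direction.
  This masks part of the marginal density signal — an intensity-only model
  cannot tell a genuinely denser femur from a doubly-at-risk one with
  compensatory local sclerosis — while the shape channel explains the
  masking away. This is what makes the combined representation separate
  the classes better than either alone, robustly rather than by a
  hair's breadth;
* three status-independent **nuisance latents** per space. The first
  intensity nuisance is itself mass-dominated, emulating the large
  status-independent overall-mass variation that limits areal BMD in real
  cohorts (and places the aBMD analogue between SSM and SIM, as published
  orderings show); shape nuisance scores are scaled by 0.3, reflecting that
  rigid anatomical alignment removes most status-independent shape
  variance;
* i.i.d. Gaussian noise, $\sigma = 0.05$ per coordinate/element.

Effect sizes are *projections*: the class-mean difference of the data
projected onto the corresponding unit latent direction equals the
configured effect (tested by a law-of-large-numbers check at $N = 2000$).
Consequently the density fields are a realistic baseline profile
(trabecular core plus high-density cortical boundary layer, mg/cm³ scale)
with order-one standardised variation on top; classification and AUC are
scale-invariant, so only the cosmetic realism of the variance scale is
sacrificed. With all effects zero the classes are exchangeable by
construction, and cross-validated AUCs of all models are null-calibrated
(checked over 20 seeds at $N = 200$; individual draws follow the
Mann–Whitney null with sd $\approx 0.041$, so the calibration assertions
target the median and the large-majority containment of draws rather than
every single draw, which a $\pm 0.10$ band cannot guarantee at this $N$).

For the effect-direction-recovery property (cosine between the generative
direction and the first PLS mode above 0.9 at $N = 200$) the single active
effect is set to 1.0: an a priori signal-to-noise computation — signal
coefficient $d\,n_1 n_0/N$ against nuisance projections of magnitude
$\sim\sqrt{N}/2$ per latent — gives an expected cosine of $\approx 0.97$
at $d = 1$, while the deliberately weak default shape effect
($d_s = 0.3$) cannot clear 0.9 in the presence of any realistic nuisance
structure.

**What the generator does not emulate:** anatomically realistic femur
geometry; CT voxel noise texture, beam hardening or partial-volume effects;
pair-matching on age, height and weight; clinical covariates. Passing tests
demonstrate the statistical machinery — mode extraction, fusion,
validation hygiene, influence screening — under a linear-Gaussian latent
structure; they do not certify performance on real imaging data.

## Problem sizes and runtime choices

The test-suite cohorts use $N = 20$–$200$ subjects, 150–800 tetrahedra and
27 control points; the reference classification experiment uses ten
cohorts of $N = 100$ at the default effect sizes and reports medians, and
the acceptance script mirrors it at $N = 93$. These sizes were chosen so
the full suite completes in well under a minute on one CPU while keeping
every statistical property measurable; all of them are configuration
parameters, not constants.

## Known limitations

* The deformation model is single-step small-deformation, not geodesic;
  large deformations fold.
* Vertex-to-vertex correspondence (no point-to-plane term) requires
  comparable mesh sampling of subject and template.
* The logistic layer is linear in the components; the masking interaction
  is only partially recoverable by a linear classifier (by design — the
  same limitation applies to all published variants of this pipeline).
* The bootstrap CI treats pooled CV scores as exchangeable, ignoring
  fold-model variability, as does the usual single-pooled-ROC convention.
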