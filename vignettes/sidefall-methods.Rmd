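---
title: "Methods: sideways-fall simulation and fracture-risk classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sideways-fall simulation and fracture-risk classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

Hip fracture after a sideways fall is governed by the contest between the
impact load delivered to the greater trochanter and the load-bearing
capacity of the proximal femur. `sidefall` implements that contest as a
patient-specific 2D plane-strain finite-element simulation driven by a
DXA-like areal bone mineral density (BMD) scan, reduces each simulated
subject to a canonical vector of 39 clinical, geometric, fall-related,
tissue and mechanical attributes, selects a compact predictive subset by
principal-component contribution analysis and correlation thresholding,
and benchmarks standard classifiers (logistic regression, support vector
machines, decision trees, random forests) on SMOTE-balanced training
sets, reporting sensitivity, specificity and accuracy over repeated
stratified splits.

Because clinical DXA datasets of fractured and control women are
restricted, the package ships a first-class synthetic-cohort generator
whose defaults emulate a two-group cohort of postmenopausal women
(fractured n = 89, control n = 48) with the published group means and
standard deviations for every clinical and morphometric attribute.

## The fall-impact chain

For a subject of weight $W$ (kg), height $H$ (cm) and body mass index
$\mathrm{BMI}$, the chain is

* trochanteric soft-tissue thickness (mm, women):
  $\mathrm{STH} = 2.3451\,\mathrm{BMI} - 33.4440$, floored at 1 mm;
* attenuation force: $\mathrm{FAT} = 71\,\mathrm{STH}$ (N);
* peak impact force from a single-degree-of-freedom mass-spring impact:
  the hip falls from $h = c_h H$, giving impact velocity
  $v = \sqrt{2 g h}$ and $\mathrm{FPK} = v \sqrt{k\, c_m W}$;
* attenuated force $\mathrm{FP} = \mathrm{FPK} - \mathrm{FAT}$ (flagged,
  floored at 50 N if the soft tissue would absorb the whole impact);
* hip pressure $\mathrm{HP} = \mathrm{FP}/(b\,t)$ (MPa), with $b$ the
  trochanteric pad length and $t$ a subject-specific thickness.

The internal impact parameters are not part of the published record.
They are free calibration constants, fitted once so that group-mean
anthropometrics reproduce the published group-mean peak forces (5206 and
5284 N) and then frozen: hip-height fraction $c_h = 0.51$, effective mass
fraction $c_m = 0.35$, contact stiffness $k = 80{,}100$ N/m. The two
group equations cannot be satisfied simultaneously (the printed force
ratio differs from $\sqrt{HW}$ scaling by 0.55%); the compromise fit is
accurate to about 0.3% for both groups. Likewise $b = 0.8\,\mathrm{ITW}$
and $t = 0.40\,\mathrm{NW}$ are calibration choices, fixed so that the
cohort-mean hip pressure lands in the published 6.4–6.8 MPa range; the
chain identities $\mathrm{FP} = \mathrm{FPK} - \mathrm{FAT}$ and
$\mathrm{HP}\,b\,t = \mathrm{FP}$ hold to machine precision for every
subject.

## The synthetic cohort generator

`sample_clinical()` draws age, height, weight and total BMD from
truncated Gaussians (±4 SD, floored at physical minima) at the group
parameters; BMI is always derived from height and weight so the exact
identity the fall model needs is preserved. `sample_shape()` draws the
seven morphometric targets (NW, HAL, NSA, SAL, ITW, STW, FA) the same
way, rejecting only basic inconsistencies (width ordering, physiological
neck-shaft angle, shaft length within the hip-axis allowance) that
exclude a negligible fraction of draws — so the sampled means calibrate
to their targets essentially exactly.

`render_scan()` rasterises a parametric proximal-femur silhouette: a
constant-width distal shaft, a calcar flare that holds the full
intertrochanteric width in a band at the hip-axis exit level, a
greater-trochanter column with a concave medial retreat that keeps an
open fossa notch along the neck, a neck capsule of width NW joining the
shaft axis to the head centre, and a circular head closing the hip axis
of length HAL. One free parameter (the trochanter width/collar factor)
is solved so the rasterised area matches the FA target; any residual gap
is closed by growing or trimming boundary pixels outside
measurement-protected zones. The BMD texture is a high-density cortical
rim (depth 2.2 mm at the reference BMD of 0.75 g/cm², scaled by the
subject's total BMD; rim/interior areal-density ratio 2.1) over a
trabecular interior with 5% multiplicative pixel noise, rescaled so the
mask-mean areal BMD equals the subject's total BMD exactly.

Not every independent draw of seven coupled dimensions corresponds to a
realisable femur; the renderer refuses such shapes and
`generate_cohort()` redraws with derived sub-seeds until one renders.
Two consequences are worth knowing. First, the *delivered* cohort
morphometrics are conditioned on joint realisability and can sit up to
roughly 0.2 SD from the nominal group means even though the sampler
itself is calibrated. Second, the silhouette is a template, not a real
projection: it reproduces the seven morphometric measurements and the
BMD statistics that drive everything downstream, but not the appearance
of a densitometer image, so passing tests demonstrate internal
consistency of the pipeline rather than fidelity to any individual
patient anatomy.

## Morphometry

All landmark detection uses the segmentation mask only. The design goal
was determinism: the published regions-of-interest procedure was
"semiautomatic", which is not reproducible, so every construction here
is an explicit rule.

* **Shaft axis**: the centreline of the most distal near-constant-width
  run of cross-sections, found by scanning breadth along the current
  axis estimate and iterating; a cap keeps the trochanteric collar
  (which is also near-constant) from being mistaken for the shaft.
  `standardise_pose()` rotates the scan so this axis sits 10° from the
  image vertical and, on request, mirrors it so the head is medial-left.
* **Head centre and radius**: an inlier-refit least-squares circle fit
  to the medial articular boundary arc near the medial extreme.
* **Neck**: the widest clearance corridor from the head to the shaft.
  Over candidate rays from the head centre spanning neck-shaft angles
  92–158°, the minimum distance-to-background along the ray (an exact
  Euclidean distance transform) is maximised; rays that leave the bone
  are not neck paths. Twice the maximin clearance is NW; the bottleneck
  locates the narrowest section; the axis is refined on the clearance
  ridge (the per-cut argmax of the distance field, which lies on the
  capsule axis and is immune to contiguous-run leakage into the
  trochanteric contact zone). NSA is the angle between this axis and
  the distal shaft direction.
* **HAL** is the contiguous mask chord through the head centre along
  the neck axis; **ITW** is the breadth perpendicular to the shaft axis
  in the held full-width band just distal of the chord's lateral exit
  (median of three probe offsets); **STW** is the shaft-run breadth;
  **SAL** is the shaft-axis extent of the lateral half-mask, so a head
  that overshoots the trochanter tip (valgus configurations) cannot
  contaminate it; **FA** is the mask area.

On rendered synthetic femurs this round-trips: across renderable seeds,
better than 90% of subjects recover every generating parameter within
5% (2° for NSA). The neck and trochanteric regions of interest are a
15 mm band centred on the narrowest neck section (perpendicular
half-width 0.9 NW) and the zone between the subtrochanteric level and
the neck-shaft junction lateral of the shaft axis, with any overlap
assigned to the neck.

## Finite-element model

The femur and two PMMA pads (E = 1500 MPa, ν = 0.37) are meshed by a
structured grid triangulation (two triangles per covered cell) at a
resolution chosen to approximate the target element count — the desk
default is 6,000 elements, and the reference-scale 60,000 is one
configuration away. A structured grid guarantees a conforming mesh with
no inverted elements; its boundary follows the contour at half-cell
fidelity, which regional averages tolerate.

Femur elements sample the areal BMD at their centroid and convert it to
apparent density through a reference projection thickness
($t_{\mathrm{ref}} = 1$ cm) and to Young's modulus by the power law
$E = 6850\,\rho^{1.49}$ MPa (ν = 0.3, floor 10 MPa). These coefficients
are configuration, not code constants; with the generator's BMD scale
they put cohort-mean trabecular moduli near 3.2 GPa and cortical moduli
near 10 GPa, consistent with the published tissue summaries at the
1.0 g/cm³ cortical threshold. A 3 cm projection thickness — a common
anatomical figure — would, combined with the hard constraint that the
mask-mean areal BMD equal the subject's total BMD, produce apparent
densities far too low for those summaries, which is why 1 cm is the
default.

Boundary conditions: the distal shaft end is fully fixed; every
head-pad node is restrained medially (x) and free vertically. The
trochanteric pad's lateral free boundary carries a uniform inward
pressure HP, lumped consistently onto edge nodes, so the resultant
equals pressure times loaded length exactly. The solver assembles
constant-strain triangles under plane strain and solves the sparse
system by Cholesky factorisation. Post-processing computes in-plane
principal stresses ($S_1 \ge S_3$) and strains ($E_1 \ge E_3$,
microstrain), the out-of-plane stress
$\sigma_{zz} = \nu(\sigma_{xx}+\sigma_{yy})$, von Mises stress including
$\sigma_{zz}$ (for uniaxial plane strain at ν = 0.3 this gives the
closed-form ratio 0.889), and strain energy density
$\tfrac12\sigma\!:\!\varepsilon$ in J/m³. Verification: an exact patch
test, equilibrium residuals below 10⁻⁶, exact load-scaling linearity,
translation objectivity, and a tip-loaded cantilever within 10% of
Euler–Bernoulli theory at desk density, converging under refinement.

"Maximum eigenvalue" attributes (MPStress, MPStrain) are the
largest-magnitude in-plane principal value with sign retained, because
the published magnitudes track the compressive principal components.

## Strength indices

The yield model is a uniform compressive yield strain (default 7,300
microstrain) and a per-element yield stress $E_e \varepsilon_y$; both
are configuration constants, since no values are part of the published
record. The fracture risk index of a region is the area-weighted mean
of von Mises stress over yield stress. The load-to-strength ratio is
defined on the per-element demand/capacity ratio
$|\min(E_3,0)|/\varepsilon_y$: the critical region is the contiguous
(edge-adjacent) element set comprising the highest ratios whose
cumulative area first reaches 9 mm², and LSR is the smallest ratio in
it. A greedy growth from the single peak element is not always optimal
(two separated clusters defeat it), so the implementation uses a
descending-threshold union-find sweep, which returns the exact optimum —
the largest threshold at which some connected component reaches the
target area — and is verified against an exhaustive per-threshold
component search on small meshes. Femoral strength is FP/LSR by
linearity.

## Attribute selection

Selection composes z-score normalisation (required for PCA on
heterogeneous units), SVD-based PCA, a contribution rule (an attribute
contributes to a component when its absolute loading exceeds 0.1 of the
component's maximum — the published account separates "weights ≈ 1"
from weights of 10⁻³ and below, and any floor in that gap gives the
same answer), contributor collection over the three leading components,
a joint Pearson/Spearman correlation mask at |r| ≥ 0.9, link-based
augmentation, and interdependence pruning (FAT and STH are exact
functions of BMI; CT is the complement of TB; the routinely collected
proxy is retained).

Augmentation has two modes. The default counts, for each attribute not
yet selected, its masked links to other unselected attributes and
accepts those with at least four; that rule is order-independent and
monotone in the threshold. The redundancy-aware sequential mode
processes candidates in alphabetical order and adds each accepted
attribute to the exclusion set, so links to an attribute whose
information is already carried stop counting — this consolidates
clusters of mutually correlated candidates into single representatives
and is the mode that reproduces the reference study's augmentation set
(HP, S3_N, FRI_N, FRI_T) from its published link table. The published
check table is itself asymmetric where a correlation matrix cannot be;
the shipped `study_link_mask()` therefore keeps a link between two
attributes that are checkable in both directions only when both
directions agree, which is the reading consistent with the published
outcome. On synthetic cohorts the exact generating relations make
FAT–STH–BMI and CT–TB correlate perfectly, so pruning always removes
FAT, STH and CT.

## Classification benchmark

Each run draws a stratified split (per-class floor of 70% to training),
applies SMOTE to the training set only — each class independently grown
to 200 rows by convex interpolation toward one of five same-class
nearest neighbours on z-scored features — trains the model, and
evaluates on the untouched test set with fractured as the positive
class. Logistic regression, seven SVM variants (linear, sigmoid and
Gaussian kernels, each optionally classifying by Platt-calibrated
posteriors, plus a Gaussian-process classifier standing in for a
Bayesian kernel machine with native posteriors) and a Gini decision
tree are repeated over seeded runs with mean, SD and best reported; the
random forest (1,000 trees, depth capped at 12) is treated as
self-averaging and reported from a single seeded run. SVM costs and
kernel widths use library defaults (cost 1, inverse-median-heuristic
width), exposed in `model_spec()`.

A note on attainable accuracy: on synthetic cohorts the entire group
difference is injected through the published summary statistics, and
the selected feature sets deliberately exclude raw BMD. When the
between-group BMD gap is widened to two pooled SDs, an ideal observer
on raw BMD plus geometry reaches about 0.87 accuracy, but classifiers
restricted to the FE-derived proxies (which mix BMD with subject
geometry and load) plateau around 0.76–0.83 on 42-subject test sets.
Median random-forest accuracy rises monotonically with the imposed
separation, which is the behaviour the generator is designed to
demonstrate; absolute accuracies on synthetic cohorts should not be
compared with clinical figures.

## Problem sizes and numerical choices

Defaults used throughout the examples and tests: 6,000-element desk
meshes (about 3,300 nodes; one sparse Cholesky solve per subject),
256×192-pixel scans at 0.6 × 1.05 mm, 137-subject cohorts, 25–1,000
benchmark runs depending on context. A full subject — render, pose,
morphometry, mesh, solve, reduce — takes well under a second at desk
density. Tolerances: the stiffness floor keeps near-void pixels from
making the system singular; the FP floor (50 N) keeps extreme
soft-tissue draws from producing a non-positive load (flagged, never
silent); zero-variance columns pass through normalisation as zeros with
a flag; ties in the LSR sweep resolve by element order, which cannot
change the optimum threshold.

## Known limitations

The silhouette template and its density texture are calibrated to
summary statistics, not to images; inter-attribute correlations within
the clinical and morphometric groups are not reproduced (attributes are
sampled independently except where identities force dependence, which
is also why jointly unrealisable draws must be redrawn). The 2D
plane-strain idealisation inherits the usual projection artefacts:
cortical/trabecular overlap along the beam direction, and stress fields
that should not be read as 3D predictions. Male subjects are out of
scope (the soft-tissue relation is only available for women), as is any
distinction between neck and trochanteric fracture outcomes.
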