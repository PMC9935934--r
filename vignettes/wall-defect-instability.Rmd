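---
title: "Relative instability of trochanteric wall defects: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative instability of trochanteric wall defects: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(trochfem)
```

## The question the package addresses

Trochanteric hip fractures are rarely a single clean fracture line: the
medial wall (the calcar region around the lesser trochanter), the lateral
wall, and posterior coronal fragments are often involved, and each missing
wall changes how stable the femur-implant construct is after fixation with a
cephalomedullary nail (PFNA-type: intramedullary nail, helical blade,
distal locking screw). `trochfem` quantifies the contribution of each wall
to construct instability: it builds eight fracture-fixation finite-element
models — a basic intertrochanteric fracture plus seven wall-defect variants
(M, AM, PM, L, AL, PL, and the posterior coronal PML defect) — solves them
under gait hip-contact loads, extracts six biomechanical outcome
indicators, and condenses them into a *relative instability ratio* per
model.

## The scoring model

For each indicator $k$ and model $i$, the relative instability ratio is the
min-max position of the indicator magnitude across the model family,

$$ r_{ik} = 100\,\frac{|v_{ik}| - \min_j |v_{jk}|}{\max_j |v_{jk}| - \min_j |v_{jk}|} \;[\%], $$

and a model's mean ratio is the unweighted mean of $r_{ik}$ over the
indicators. By construction a model attaining every column minimum scores
0% and one attaining every maximum scores 100%. Two deliberate choices:

* **Polarity.** All six default indicators enter as magnitudes (the
  compressive strain peak as $|\varepsilon_3|$): larger magnitude is read
  as less stable — the usual monotone reading in fixation biomechanics,
  where constructs drift toward yielding as these local quantities grow.
* **Ties.** An indicator with no spread across models carries no
  instability information; it scores 0 for everyone and is dropped from the
  mean instead of diluting it.

The default indicator set is: nail peak von Mises stress, blade peak von
Mises stress, peak maximum (tensile) principal strain, peak minimum
(compressive) principal strain magnitude, femoral-head vertex displacement,
and fracture-surface gap. Risky-volume indicators are computed and exported
but not scored by default. Scoring uses the dynamic (quasi-static gait)
climbing envelope, where the loads — and the reported peaks — are largest;
this is configurable.

## Synthetic geometry in place of patient CT

No patient CT accompanies this kind of study, so the geometry module
generates a parametric surrogate: a femoral head sphere on a neck tube,
blended through a trochanteric swell into a straight shaft — a
variable-radius tube swept along a bent medial axis, cut flat distally. The
surrogate defines exactly the landmarks the construction rules need (shaft
axis, lesser trochanter level, head centre/apex) and is deterministic given
its parameters. Defaults (head radius 24 mm, neck-shaft angle 125°, shaft
outer radius 14 mm, cortical shell 4 mm, trochanteric radius 26 mm, shaft
length 180 mm below the lesser trochanter) are typical adult values; the
neck-shaft angle equals the blade angle so the blade lies along the neck
axis. Anteversion defaults to 0° to keep the construct frontal-plane
symmetric; it is a parameter.

What the surrogate deliberately does **not** emulate: patient-specific
cortical thickness maps, the true asymmetric greater trochanter, the
anterior femoral bow, and anatomically curved fracture surfaces. Passing
trend tests on the surrogate therefore shows that the *pipeline* recovers
the defect mechanics on an idealised femur, not that it reproduces
patient-specific magnitudes — which is also why the published per-model
stress/strain magnitudes are not acceptance targets.

### Fracture and wall-defect rules

* The basic fracture is an oblique intertrochanteric surface
  ($z = 25\,\mathrm{mm} + \tan 25^\circ \cdot y$, higher laterally) whose
  trace is perturbed by a seeded band-limited sinusoid in azimuth
  (amplitude default 3 mm) — an "irregular curve" that re-randomises per
  repetition seed. A guard rejects amplitudes that would push the cut out
  of the trochanteric zone.
* The medial wall is the cortical zone within 2 cm above and below the
  lesser trochanter level; the lateral wall a 30 mm band on the lateral
  cortex spanning the blade-entry region. Azimuthal extents (±60° about
  the medial/lateral directions) are configuration, since the published
  carving rules name only the bands.
* Defect depth is half the local cortex-to-shaft-axis distance,
  implemented by the scaled-point test (a centroid is in the outer half iff
  doubling its radial coordinate leaves the bone).
* AM/PM and AL/PL are the anterior/posterior halves split by the sagittal
  plane through the shaft axis; PL additionally removes an 8 mm band of
  posterior-lateral wall proximal to the original PL region (the exact
  proximal extent is not standardised; exposed as
  `pl_upper_height`); PML removes PM, PL, and all posterior outer-wall
  bone between them.

### Meshing

Everything is meshed on one structured background grid per model (six
tetrahedra per cell, face-compatible Kuhn split), and elements are
classified by centroid: implant part, bone fragment (by fracture side),
defect (removed), or outside. This makes every volume identity exact by
construction — fragments plus removed defect tile the basic model — and
gives bone and implant conforming shared nodes (a tied, osseointegrated
interface). The two bone fragments are then separated by duplicating the
nodes on the fracture interface; the pairs carry smooth fracture-surface
normals and tributary areas for penalty contact. Elements not
face-connected to the main body (voxel classification islands) are
dropped so the stiffness operator has no spurious mechanisms. TET4 is the
default; TET10 (midside nodes, 4-point Gauss assembly) is available via
`order = 2`. The default grid spacing of 4 mm yields roughly 23,000
elements per model — a deliberate desk-scale budget (patient-CT studies of this
model family run ~145,000 ten-node elements per model).

Against this resolution, stair-stepped boundaries are the main geometric
error source. A mesh-sensitivity sweep on the basic model (tied interface,
static walking) gives head-vertex displacements of 2.96, 2.93, 3.66, 3.99
and 3.92 mm at 8, 5, 4, 3 and 2.5 mm spacing: the solution is converged to
a few percent only below 4 mm, where the blade diameter (10.5 mm) spans
several cells. The suite asserts convergence across the production
resolutions (4 vs 3 mm); coarser grids are resolution-limited.

## Materials

Bone elements get a synthetic Hounsfield-unit field: cortical mean 1500 HU
within 4 mm of the outer surface, trabecular mean 300 HU inside, plus a
seeded stationary noise field (SD 50 HU, random-phase cosine expansion).
Because the noise is a function of *position*, all eight variants of one
femur/repetition see the same HU volume — like eight fracture models cut
from one CT — so inter-variant indicator differences reflect the defects,
not the noise realisation. HU maps to apparent density
$\rho = 131 + 1.067\,\mathrm{HU}$ (kg/m³) and modulus
$E = -331 + 4.56\,\rho$ (MPa), floored at 1 MPa so low-density
(marrow/canal) elements keep a positive-definite stiffness; bone Poisson
ratio 0.3. Implant elements carry titanium-alloy constants
(105,000 MPa, 0.35). Bone moduli are optionally binned (default 10
equal-width bins, mirroring discrete CT material-mapping workflows; the
bin count used by commercial mapping workflows varies).

## Loads, boundary conditions, contact

The distal shaft cross-section is fully fixed. The hip contact force is
distributed in equal nodal shares over a 30° polar cap of the femoral head
facing the load. The printed static vectors — walking (647, 236, −1351) N
at 2.0 body weights, climbing (711, 436, −1393) N at 2.1 — come without a
stated axis convention. We apply the first component **medially**, the
second **posteriorly**, the third distally. The medial component presses
the head onto the calcar (varus-compression loading), reproducing the
reported qualitative pattern — compressive strain risk at the
medial/inferior cortex, tensile risk at the lateral fracture surface. The
posterior orientation of the second component follows instrumented-hip
measurements, where the anterior-posterior component of the contact force
points posteriorly in femur coordinates and grows during stair climbing;
it also makes the climbing load engage the posterior walls whose defects
the PM/PL/PML variants model. The rejected alternatives are mechanically
inconsistent: a lateral first component cancels the distal head
displacement under climbing, and an anterior second component unloads the
posterior fracture surface so that static walking can gap posterior-defect
models more than the climbing envelope, contradicting the
climbing-dominates-walking trend.

"Dynamic" loading is quasi-static: the static vector scaled along a gait
curve, one linear solve per phase, no inertia (published "dynamic" hip loads of this kind
are load-time curves, not transient dynamics with mass effects). The built-in templates are
placeholders with the canonical shapes — a two-peak walking curve (peaks
1.0/0.9) and a single-peak climbing curve (peak 1.15, 8 phases by default
in the study) — and any `(phase, scale)` table can be supplied. The
envelope records per-element maxima of von Mises stress and tensile
principal strain, minima of compressive principal strain, per-node peak
displacement, and the peak gap.

Contact: bone-implant and implant-implant are tied (shared mesh nodes).
The fracture surface uses penalty contact with compressive-only normal
springs on the duplicated node pairs (per-pair stiffness = penalty pressure
× tributary area; default penalty pressure 1000 × mean bone modulus /
grid spacing), resolved by active-set iteration; a Coulomb stick/slip
option uses the bone-bone friction coefficient 0.46. Friction coefficients
0.46/0.42/0.2 (bone-bone, bone-implant, implant-implant) are carried in the
configuration; the tied implant interfaces do not use them at desk scale.
With coincident pairs the contact problem is positively homogeneous, so
active sets are stable along a scaled gait curve and factorizations are
reused across phases.

## Indicators

Six scored indicators plus risky volumes, with two evaluation-region
choices that matter on the surrogate:

* **Bone strain indicators** (principal-strain peaks, risky volumes at the
  strict ±0.9% thresholds) are evaluated over the proximal region
  (centroids above z = −40 mm): strain risk in trochanteric fixation is
  assessed on the proximal fracture fragment, and on the uniform surrogate shaft the global
  strain maximum otherwise sits in the distal-constraint boundary layer,
  which no wall defect can influence. Risky-volume ratios use the model's
  own (post-defect) bone volume in that region as denominator.
* **Nail von Mises peak** is taken over the nail-blade junction zone
  (±30 mm): that is where nail stress concentrates in this fixation
  construct, whereas the
  surrogate's global nail maximum sits at the distal locking screw where
  the section bending moment is statically determined and
  defect-invariant. The blade peak is global over the blade. Both peaks are
  flagged against the 750 MPa titanium yield bound.
* **Head-vertex displacement** is the distal (−z) component at the most
  proximal head node (full magnitude also exported); **fracture gap** is
  the normal opening over interface pairs, floored at zero, evaluated by
  default on the fracture-surface portion that no wall defect can remove —
  otherwise carving a wall deletes exactly the pairs that gap most, and
  the defect models would *appear* tighter than the basic model on a
  surface that no longer exists. The maximum opening is the primary
  reported value; the *scored* gap indicator is the area-mean opening,
  because on a stair-stepped voxel interface the single-pair maximum is an
  order statistic whose inter-variant noise exceeds the defect signal
  among the near-stable models, while the mean integrates the opening over
  the shared surface.

Strain-risk comparisons are strict inequalities: an element exactly at
0.9% is not risky. TET4 strains are element-constant; TET10 strains are
evaluated at the centroid, keeping risk volumes element-local and
unambiguous.

## The study and its determinism

`run_study()` executes variants × load cases × repetitions. The default
study: 8 variants, static walking + static climbing + dynamic climbing
envelope, 3 repetitions, 4 mm grid, instability scored on the
dynamic-climbing repetition means. Each repetition derives a sub-seed from
the master seed and re-randomises the fracture-line perturbation and the HU
noise field — the stand-in for triplicate manual CT reconstruction —
while all variants within a repetition share both.
Everything downstream is deterministic given the master seed, which is
recorded in every exported artifact. A failing variant is logged and
skipped; the rest of the study completes.

```{r, eval = FALSE}
report <- run_study(study_config(seed = 1))
report$instability      # per-indicator and mean ratios
report$ranking          # order + concordance vs the reference ordering
export_artifacts(report, "out", formats = c("csv", "json"))
```

With the default seed this places the medial-wall defect highest and the
basic fracture lowest, with pairwise concordance ≈ 0.86 against the
reference ordering (BASIC < PL < AL < PM < L < PML < AM < M). Exact
order agreement is not expected on surrogate geometry: the middle ranks
differ and depend on details — lateral wall function is partly taken over
by the nail ("metal lateral wall"), the anteromedial wall's published
prominence rests on patient-specific anteversion and calcar anatomy that
the idealised femur flattens, and the posterior coronal defect's extent
is rule-driven rather than segmented.

## Numerical choices and degenerate inputs

* Stiffness assembly is exact closed-form TET4 (verified against an
  independent energy-difference oracle at 1e-10) and 4-point Gauss TET10;
  the unconstrained operator has exactly six rigid-body modes.
* Linear systems use sparse Cholesky (`Matrix`); equilibrium residuals are
  checked per solve (typically ~1e-9 relative; reactions equal the applied
  load to 0.1% or better).
* Contact active-set iteration caps at 30 changes of status; failure to
  settle is an error carrying the iteration trace, not a silent result.
* Min-max scoring refuses tables with fewer than two models, non-finite
  values, or negative magnitudes; empty defect regions (e.g. rules that
  miss the bone at a coarse grid) are geometry errors naming the variant.
* All randomness (fracture irregularity, HU noise, repetition sub-seeds)
  flows from one integer seed kept below 2^31.

## Known limitations

Linear kinematics and linear elasticity throughout (no yielding, no
large-sliding contact); cylinder surrogate for the helical blade; voxel
(stair-step) boundaries at desk-scale resolution; equal-share nodal load
application (consistent tractions are used in the solver tests); the gait
curve ordinates are configurable placeholders, not digitised published
curves; and the surrogate femur cannot reproduce patient-specific
magnitudes, only relative defect effects.
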