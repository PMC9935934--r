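# trochfem

Finite-element analysis of how cortical **wall defects** destabilise
fixed trochanteric hip fractures. For biomechanics researchers and
implant-fixation methodologists who want a fully scripted, reproducible
version of the classic eight-model wall-defect study — without patient CT
data or a commercial solver.

The package builds eight fracture-fixation models of a proximal femur with
a PFNA-type cephalomedullary nail (nail length 200 mm, blade angle 125°,
tip-apex distance 15 mm): a basic irregular intertrochanteric fracture and
seven wall-defect variants — medial (M), anteromedial (AM), posteromedial
(PM), lateral (L), anterolateral (AL), posterolateral (PL), and the
posterior coronal defect (PML). Each model is solved as a small-strain
linear-elastic tetrahedral FE problem under static and quasi-static gait
hip-contact loads, with penalty contact across the fracture surface, and
summarised by six outcome indicators:

* nail and blade peak von Mises stress (MPa),
* peak tensile / compressive principal strain of the proximal bone, with
  risky-volume fractions at the ±0.9 % strain thresholds,
* femoral-head vertex displacement toward the distal femur (mm),
* fracture-surface gap (mm).

The indicators are condensed into a **relative instability ratio** per
model: each indicator magnitude is min–max scaled across the eight models,

> r = 100 · (v − min) / (max − min)  [%],

and averaged over indicators, so the most stable construct scores 0 % and
the least stable 100 %. Bone material properties come from a synthetic CT
Hounsfield-unit field through the standard calibration
ρ = 131 + 1.067·HU (kg/m³), E = −331 + 4.56·ρ (MPa).

## Worked example

```r
library(trochfem)

# one model: medial wall defect, 4 mm grid (~23k elements)
a <- build_assembly(variant = "M", seed = 1, target_edge = 4)
a
#> model_assembly 'M': 5124 nodes, 20481 elements (TET4), 69 fracture pairs
#>   bone volume 184002 mm^3 (defect removed 24995 mm^3), TAD 15.00 mm

hu   <- synthesize_hu(a$mesh, hu_field_spec(seed = 2))
mats <- assign_materials(a$mesh, hu, n_bins = 10)
r    <- solve_static(a, mats, load_case("static_walking"))
extract_indicators(r, a)[c("blade_peak_vms", "head_vertex_displacement",
                           "fracture_gap")]
#> $blade_peak_vms            [1] 214.9019   # MPa, at the blade-nail junction
#> $head_vertex_displacement  [1] 4.043303   # mm toward the distal femur
#> $fracture_gap              [1] 0.06414594 # mm, max opening, shared surface
```

The full study (8 variants × {static walking, static climbing, dynamic
climbing envelope} × 3 repetitions with re-randomised fracture line and HU
noise) runs in a few minutes on one CPU:

```r
report <- run_study(study_config(seed = 1))
report$instability
#> Relative instability ratios (% of min-max range, mean over 6 indicators)
#>  model mean_ratio
#>      M       92.4
#>    PML       60.3
#>     PM       44.3
#>     AM       17.5
#>      L        4.1
#>     PL        3.9
#>     AL        3.3
#>  BASIC       3.1
report$ranking$concordance
#> [1] 0.857
```

The medial wall defect is by far the most destabilising, the basic
fracture the most stable, and the ranking agrees with the published
ordering (BASIC < PL < AL < PM < L < PML < AM < M) with pairwise
concordance ≈ 0.86; middle ranks differ because the geometry is a
parametric surrogate, not patient CT (notably, the anteromedial wall's
published prominence depends on patient-specific anteversion and calcar
anatomy that the surrogate idealises). Indicator tables, instability
ratios, meshes (VTU/STL) and a provenance block export with
`export_artifacts()`. A thin CLI lives in `scripts/run_study.R`
(`run` and `score` verbs); the scoring stage also runs standalone on any
user CSV of indicators via `run_scoring()`.

See the vignette (`vignettes/wall-defect-instability.Rmd`) for the model,
its assumptions, parameter defaults, and known limitations.

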