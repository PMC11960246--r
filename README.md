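# cartmorph

Morphometric analysis of distal femoral cartilage surfaces for focal knee
resurfacing implant (FKRI) design. Generic focal implants need
population-level answers to three questions: *where* do focal cartilage
defects occur on the femoral condyles, *how large* are they, and *what does
the healthy articular surface look like* at the places they occur.
`cartmorph` implements the full mesh-based analysis chain that answers
them, plus a synthetic cohort generator with closed-form ground truth so
that every stage can be validated without patient data.

## What it computes

Given a set of triangulated "native" (reconstructed healthy) cartilage
surfaces and paired focal-defect surface models, in millimetres:

1. **Correspondence** — every model is registered to a reference by rigid
   iterative closest point (ICP) followed by stiffness-relaxed, locally
   affine non-rigid ICP, yielding k shapes sharing one topology. Right-knee
   models are mirrored in the sagittal plane into a left-knee frame first.
2. **Statistical shape model (SSM)** — generalised Procrustes alignment
   (GPA, *without* scaling, so size remains a mode of variation) and PCA of
   the aligned vertex coordinates give the mean shape S̄, orthonormal mode
   matrix P and mode variances λ₁ ≥ … ≥ λ_q. A new instance is

       S = S̄ + P b,   b_i ~ N(0, λ_i)  (truncated at ±3√λ_i)

   Model quality is reported as compactness (cumulative variance fraction),
   accuracy (training reconstruction RMS, mm) and generalisation
   (leave-one-out reconstruction RMS, mm) per mode count.
3. **Defect heat map** — each native model is similarity-aligned (with
   scaling) to the mean shape; the same transform is applied verbatim to
   its defect model, and every mean-shape vertex counts the defect models
   whose articulating surface passes within τ (default 1 mm). The argmax
   vertex is the defect hotspot.
4. **Defect metrics** — articulating surface area; major axis (maximum
   pairwise vertex distance); minor axis (maximum extent perpendicular to
   the major axis); aspect ratio = major/minor.
5. **Local radii of curvature (ROC)** — a least-squares cylinder is fitted
   to the posterior condylar surface; at a probe point, the plane with the
   cylinder axis as normal measures the anteroposterior (AP) radius and the
   plane containing the axis measures the mediolateral (ML) radius. Each
   circle is fitted (Pratt + geometric refinement) to the exact mesh–plane
   section of an elliptical region of interest centred on the probe
   (default 2.7 cm² at aspect 1.70 → 24.2 × 14.2 mm axes, the median defect
   footprint). Signs: positive = convex, negative = concave.

## Worked example

A 70-model synthetic cohort (planted shape modes, log-normal defect sizes,
a planted defect hotspot, mixed left/right sides):

```r
library(cartmorph)

cfg    <- cohort_config(n_models = 70, seed = 1)
cohort <- generate_cohort(cfg)
#> synthetic_cohort: 70 models (40 right-sided), 4 planted modes, seed 1

## mirror right-sided ("as-scanned") models into the left-knee frame
natives <- cohort$natives; defects <- cohort$defects
right   <- cohort$manifest$side == "right"
natives[right] <- lapply(natives[right], mirror_sagittal)
defects[right] <- lapply(defects[right], mirror_sagittal)

cset  <- build_corresponded_set(natives, reference_index = 1,
                                method = "shared_topology")
align <- gpa(cset, with_scaling = FALSE)
model <- build_ssm(align)
#> shape_model: 1728 vertices, 69 modes from 70 training shapes
#>   leading sd(mm): 2.557, 1.294, 0.987, 0.958, 0.949
```

The two leading modes recover the planted 2 mm and 1 mm deformation
amplitudes; later modes sit at the 0.1 mm-per-vertex noise floor. Heat map
and hotspot morphology:

```r
mean_mesh <- surface_mesh(model$mean_shape, model$faces,
                          face_labels = model$face_labels)
tr   <- align_to_mean(lapply(1:70, function(i) cset$shapes[, , i]),
                      model$mean_shape)
tdef <- mapply(transfer_to_defect, defects, tr, SIMPLIFY = FALSE)
hm   <- defect_frequency(mean_mesh, tdef, tau = 1.0)
#> defect_heatmap: 70 defects, tau 1.00 mm, max count 56 at vertex 1364

post  <- select_posterior_articulating_surface(mean_mesh)
cyl   <- fit_cylinder(post$vertices)
#> cylinder_fit: radius 33.251 mm, axis (0.983, -0.084, -0.165), rms 0.5451 mm
probe <- mean_mesh$vertices[hm$argmax_vertex, ]
measure_roc(mean_mesh, probe, cyl, patch_area = 270, patch_aspect = 1.70)
#> roc_probe_result: AP +39.9 mm, ML +71.7 mm (patch 275 mm^2)
```

56 of 70 defects overlap the hotspot vertex; the surface there is convex in
both directions, with a tighter AP than ML curvature — the generator's
condylar geometry read back through the full measurement chain. Defect size
statistics (medians with interquartile ranges) come from
`summarise_metrics(defect_metrics_table(...))`, and `run_pipeline()` runs
all stages end-to-end from one seeded `run_config()`, writing CSV/PLY/JSON
outputs. A command-line wrapper is provided in `inst/scripts/cartmorph.R`.

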