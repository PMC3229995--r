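# cupwear

Measurement of linear wear of polyethylene (UHMWPE) acetabular cups from
labelled 3D surface point clouds — the kind digitized on CT isosurfaces or
with a coordinate measurement machine (CMM). The package is for implant
metrologists and orthopaedic imaging researchers who have surface points for
a pre-wear and a post-wear acquisition and want the femoral-head penetration
vector, plus the agreement statistics needed to validate such a method
against a reference.

## What it computes

Given point clouds labelled `cup_outer`, `head`, `plane1`, `plane2` (the two
cup opening faces) for each scan, `ct_wear()`:

1. fits a sphere to the cup and head points and a plane to each opening
   face by orthogonal-distance least squares — the sphere fit minimizes
   Σ(‖pᵢ − c‖ − r)², the plane fit is total least squares — eliminating
   every point more than 0.5 mm (≈ 1 SD, configurable) from the fitted
   surface and refitting until stable, which removes metal-artifact points;
2. anchors a right-handed cup frame: origin at the cup-sphere center,
   z along the mean opening-face normal away from the dome, x along the
   opening faces' intersection line;
3. expresses each scan's head-sphere center in its own cup frame and
   reports the **wear vector** w = u_post − u_pre, the **linear wear**
   ‖w‖ in mm, and the spherical angles θ (polar, from z) and φ (azimuth,
   from x) in degrees.

Because each scan is referred to its own cup geometry, the result is
invariant to rigid repositioning of the object between acquisitions.
`cmm_wear()` implements the tactile-probe reference variant (wear as the
displacement of a sphere fitted to the worn inner hemisphere), and
`wear_volume_from_mass()` converts gravimetric mass loss to volume at the
UHMWPE density 0.935 mg/mm³. A synthetic phantom generator
(`phantom_spec()` / `generate_scan_pair()`) produces scan pairs with known
ground truth; `bland_altman()`, `bias_interval()`, `repeatability_iso()`,
`accuracy_95()` and `estimate_creep()` provide the method-comparison
statistics.

## Worked example

```r
library(cupwear)

# a synthetic phantom pair: 28 mm head in a 54 mm cup, true wear vector
# (0.5, 0, 0) mm in the cup frame, 0.1 mm surface noise, scans repositioned
pair <- generate_scan_pair(phantom_spec(wear_vector_true = c(0.5, 0, 0),
                                        seed = 42))
w <- ct_wear(pair$pre, pair$post)
w
#> <wear_result> method CT
#>   linear wear: 0.5085 mm (display 0.51 mm)
#>   wear vector (cup frame): (0.5080, 0.0128, -0.0192) mm
#>   theta 92.2 deg, phi 1.4 deg
```

The measured 0.5085 mm recovers the injected 0.5 mm within the noise floor;
θ = 92.2° and φ = 1.4° agree with the true direction (90°, 0°) — a wear
vector pointing at the cup equator along the frame's x axis. Per-surface fit
diagnostics live in `w$diagnostics` (e.g. the pre-scan head sphere: radius
14.0017 mm, RMS residual 0.1008 mm, 3750 points used, 0 rejected).

Agreement of two methods over a table of per-cup wear values:

```r
tab <- wear_measurements()   # bundled 12-cup CT-vs-CMM table
bland_altman(tab$ct_mean, tab$cmm_mean)
#> <agreement_summary> n = 12
#>   mean difference (bias): -0.1233 (SD 0.3498)
#>   95% bias CI: [-0.3456, 0.0989]
#>   limits of agreement: [-0.8089, 0.5623]
```

The mean difference −0.12 mm says the imaging method slightly underestimates
wear relative to the tactile reference; the limits of agreement bound the
per-cup disagreement expected 95% of the time.

A shell interface wraps the same functions
(`inst/cli/cupwear`; exit codes: 0 ok, 2 parse error, 3 fit degeneracy):

```sh
Rscript inst/cli/cupwear simulate --out-dir scans --seed 5 --wear 0.5,0,0
Rscript inst/cli/cupwear wear --pre scans/pre.csv --post scans/post.csv \
    --method ct --out result.json
Rscript inst/cli/cupwear volume --mass 200        # 213.90 mm^3
```

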