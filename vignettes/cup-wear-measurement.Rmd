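---
title: "Measuring acetabular cup wear from 3D surface point clouds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring acetabular cup wear from 3D surface point clouds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cupwear)
```

## The measurement problem

Polyethylene (UHMWPE) acetabular cups wear: the femoral head slowly
penetrates the liner, and the debris this releases can trigger aseptic
loosening of the implant. The clinically interesting quantity is **linear
wear** — the depth of head penetration, typically 0.1–0.2 mm per year —
together with the **direction** of penetration. On a 3D image volume (or a
tactile digitization) neither is directly visible; what can be obtained is a
set of labelled surface points: a few thousand on the cup's outer shell, a
few thousand on the femoral head, and a few hundred on each of the two cup
opening faces.

`cupwear` turns two such labelled point-cloud sets — one before wear
("pre"), one after ("post") — into a wear vector. The chain is:

1. **Primitive fitting.** A sphere is fitted to the cup points and to the
   head points, a plane to each opening face, all by orthogonal-distance
   least squares. A sphere fit minimizes
   $\sum_i (\lVert p_i - c\rVert - r)^2$ over center $c$ and radius $r$; a
   plane fit minimizes the squared orthogonal point–plane distances (total
   least squares, solved by SVD).
2. **Artifact filtering.** Metal artifacts displace surface points. After
   each fit, every point lying *more than* 0.5 mm from the fitted surface
   (about 1 SD of typical CT surface noise) is eliminated and the primitive
   is refitted, until no point is removed. The comparison is strict: a
   residual exactly at the threshold is retained.
3. **Cup frame.** An orthonormal, right-handed frame is anchored on the
   cup: origin at the cup-sphere center, $z$ along the mean opening-face
   normal pointing away from the dome, $x$ along the intersection line of
   the two opening faces projected orthogonal to $z$, and $y = z \times x$.
4. **Registration and subtraction.** Each scan's head-sphere center is
   expressed in that scan's own cup frame. The **wear vector** is the
   difference of these frame coordinates (post − pre); **linear wear** is
   its norm; $\theta$ (polar, from $z$) and $\phi$ (azimuth, from $x$) are
   its spherical angles. Referring each scan to its own cup geometry makes
   the measurement invariant to how the object was positioned in the
   scanner — the same invariance a physical registration of the two volumes
   would provide, but without needing a shared world frame.

A second variant, `cmm_wear()`, mirrors the tactile-probe reference method:
there the wear is carried by the cup's *inner* surface, so the worn
(simulator-loaded) hemisphere is separated from the unworn one, the frame is
built from the opening planes and a sphere on the unworn hemisphere, and
wear is the displacement of the worn-hemisphere sphere center between scans.
`wear_volume_from_mass()` converts gravimetric mass loss to volumetric wear
at the UHMWPE density of 0.935 mg/mm³.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `filter_threshold` | 0.5 mm | artifact elimination distance; strict "more than" rule |
| `max_iterations` | 10 | cap on eliminate-and-refit passes per primitive |
| `worn_sign` | +1 | which frame-x side is the worn hemisphere (CMM variant) |
| `density_mg_mm3` | 0.935 | UHMWPE density for mass→volume conversion |

The elimination loop deserves a note. A single elimination pass is
ill-defined unless the provisional surface it is measured against is
specified; we therefore iterate fit → eliminate → refit to a fixed point
(at most 10 passes), which is self-consistent and, in practice, converges
in 1–2 passes. The single-pass behaviour is available with
`max_iterations = 1`. If the loop is still removing points when the cap is
reached, a convergence error naming the pass count is raised rather than
returning a fit that disagrees with its own rejection rule.

## The synthetic phantom

No imaging data ship with the package. Instead, `generate_scan_pair()`
emulates the bench validation setting end-to-end with known ground truth:
a cup of outer diameter 48–64 mm (default 54 mm) with a 28 mm head at
0.51 mm diametral clearance, mounted at 45° inclination; the head rests
half the clearance toward the cup pole; the post scan displaces the head by
a chosen true wear vector in cup-frame coordinates. Surfaces are sampled
uniformly by area (cup and head as hemispherical caps at realistic
digitization densities: 2500 cup, 3750 head, 500 per opening face — the
mid-ranges of typical practice), Gaussian noise of SD 0.1 mm is applied
along surface normals (1.5× on the metal-meshed outer shell, whose mesh
makes it rougher; this noise level also reproduces the ~0.15–0.20 mm
plane-fit RMS seen in practice), artifact outliers can be injected at a
chosen rate and minimum offset with their indices recorded for bookkeeping,
and each scan is independently repositioned by a random rigid motion of up
to 50 mm and 30° — deliberately larger than patient repositioning would be.
An optional `voxel_grid` snaps the scanner-axis coordinate to a slice
increment (e.g. 1.25 mm) to emulate reconstruction quantization.

Two generator choices were genuinely open and are worth recording:

- **Opening-face geometry.** The two faces of a real cup rim are not
  coplanar; we model them as annuli 2 mm apart with the second face tilted
  10° (chamfer-like). The tilt is not cosmetic: with *exactly parallel*
  faces the cup is rotationally symmetric about its axis, the in-plane
  azimuth is geometrically unidentifiable, and no algorithm could recover
  the $x/y$ components of the wear vector across repositioned scans. With
  any appreciable tilt the planes' intersection line pins the azimuth, and
  the whole frame is identifiable from geometry alone. `plane2_tilt = 0`
  restores the symmetric case, in which the frame falls back to a
  world-derived azimuth (deterministic, but meaningful only when scans are
  not repositioned — the fallback exists for degenerate inputs, not as a
  recommended configuration).
- **Azimuth sign rule.** The frame's $x$ direction is taken from
  $n_1 \times n_2$ (the opening-face normals, co-oriented) projected
  orthogonal to $z$. A sign rule based on where the face *points* lie would
  be unstable for annular faces, whose centroid sits on the symmetry axis;
  the cross-product rule is deterministic, robust, and rigid-motion
  equivariant, which the test suite verifies directly.

What the phantom does **not** emulate: beam hardening and realistic
metal-artifact structure (outliers here are clean outward displacements),
point-density variation from manual designation, creep of the liner between
scans, and non-sphericity of worn surfaces. Passing the simulation suite
therefore demonstrates the *software chain* — fitting, filtering, frame
construction, registration — under the stated noise model, not the imaging
physics. On real data the dominant error sources are artifact structure and
the difficulty of digitizing an uneven meshed shell, which is why bench
accuracy for this class of method (~0.5 mm) is far above the ~0.01 mm
software floor the simulations show.

## Agreement statistics

`validation_*` functions implement the statistics used to compare a new
wear method against a reference, with the sample SD ($n-1$) throughout:

- `bland_altman()`: per-unit differences $d_i = a_i - b_i$, bias
  $\bar d$, limits of agreement $\bar d \pm 1.96\,\mathrm{SD}(d)$.
- `bias_interval()`: $\bar d \pm t_{(1+\gamma)/2,\,n-1}\,
  \mathrm{SD}(d)/\sqrt n$.
- `repeatability_iso()`: from duplicate measurements, within-unit SD
  $s_w = \sqrt{\sum d_i^2 / 2n}$ and repeatability
  $1.96\sqrt2\,s_w \approx 2.77\,s_w$ — the 95% bound on the difference of
  two repeated measurements. The alternative $1.96\,\mathrm{SD}(d)$
  convention is available by flag.
- `accuracy_95()`: $|\bar d| + 1.96\,\mathrm{SD}(d)$, the 95%-level
  combination of systematic (bias) and random error. This formula is a
  documented convention: published accuracy figures of this kind are
  usually computed from per-scan raw data that are not re-derivable from
  printed per-unit means.
- `estimate_creep()`: mean apparent penetration of soak-control cups
  (soaked, never loaded), since any penetration they show is creep, not
  wear. Creep is reported separately and never subtracted from wear —
  an image-based method inherently measures the combination.

Normality is assessed graphically (`plot_bland_altman()`), not by formal
test, matching field practice for small method-comparison samples.

## Numerical choices

- Sphere fitting: closed-form algebraic (linearized) fit for
  initialization, then Levenberg–Marquardt on the orthogonal residuals with
  an analytic Jacobian, iterated to `ftol = ptol = 1e-15`. On noise-free
  data parameters are recovered to well below 1e-9 mm, and the measurement
  changes by under 1e-9 mm under 50 mm / 30° repositioning.
- Plane fitting: exact SVD solution, no iteration.
- Degeneracies raise classed errors (`cupwear_degeneracy`): fewer than 4
  usable sphere points or coplanar points, fewer than 3 or collinear plane
  points, a starved hemisphere in the CMM split, parallel opening planes
  with the fallback disabled. The zero wear vector has no direction; its
  angles are reported as a conventional 0 with `angles_defined = FALSE`
  rather than NaN.
- Orthonormality and handedness of every frame are enforced at 1e-9.
- Display rounding follows reporting practice (mm to 2 decimals, degrees to
  integers, round-half-even); JSON output always retains full precision.

## Problem sizes used in validation

The packaged validation runs use the generator's default digitization
counts; the heavier studies are a 100-pair parameter-recovery study
spanning true wear 0–2.5 mm at 0.1 mm noise (observed |bias| < 0.01 mm,
RMSE < 0.01 mm — comfortably inside the ~0.5 mm envelope a bench
validation of the full imaging chain achieves), a 20-motion repositioning
invariance check (< 1e-9 mm change), and a 2000-replicate coverage study
of the t-based bias interval at n = 12. All are recomputed from scratch by
`scripts/acceptance.R`.

## Known limitations

- The azimuth $\phi$ is ill-conditioned when wear is small (the direction
  of a near-zero vector is noise) and undefined for rotationally symmetric
  rims; angle accuracy on real cups is further limited by rim digitization
  quality. Clinically, wear direction is better referenced to the pelvis,
  which is out of scope here.
- Creep and wear are not separable from two scans; soak controls are the
  package's only creep handle.
- Per-scan raw datasets behind published headline accuracy/repeatability
  figures are generally unpublished; the package reproduces printed-table
  arithmetic exactly and covers the rest with property-based simulation.
- Input is labelled point clouds (CSV); DICOM reading, isosurface
  extraction and landmark placement belong to upstream imaging tools.
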