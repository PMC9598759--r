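---
title: "Virtual fetal echocardiography: models, rendering and verification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual fetal echocardiography: models, rendering and verification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vfecho)
```

## The rendering model

`vfecho` renders B-mode ultrasound from surface geometry, not from wave
physics. A heart model is a collection of closed triangle meshes, one per
cardiovascular structure, each carrying a material id and an integer
priority. For a probe pose $T$ (a $4\times4$ homogeneous rigid transform
taking image coordinates to heart coordinates) the renderer:

1. transforms the model into the image frame with $T^{-1}$;
2. lays out scan lines in the image plane — parallel lines spanning the
   footprint for a linear array, radial lines fanning evenly over the field
   of view from the transducer arc for a curvilinear array;
3. finds every scan-line/surface crossing with a bounding-volume hierarchy
   over all triangles (Möller–Trumbore ray–triangle tests);
4. fills the segments between crossings: each sample belongs to the
   highest-priority structure containing it, where containment follows from
   crossing parity per structure (a point-in-mesh test resolves lines that
   *start* inside a structure — legal, since a probe pose may sit inside
   the thorax volume);
5. assigns each sample its material's grey value, optionally damped by
   $\exp(-\mu \cdot p)$ where $\mu$ is the material's attenuation per mm and
   $p$ the cumulative in-tissue path to the sample;
6. scan-converts the per-line samples to the Cartesian pixel grid (nearest
   or bilinear; pixels outside a curvilinear fan are 0), producing the
   grey image and a companion slice of ground-truth structure ids rendered
   with the same sampling but always nearest-neighbor, since ids must not
   be interpolated.

The intensity model is deliberately minimal — constant grey per material,
attenuation and multiplicative speckle both off by default — because the
target appearance is a flat-filled cross-section of a blood-pool cast: the
cast is the echogenic object, the surroundings render black (background
grey 0, configurable). There is no refraction, shadowing or reverberation;
those are out of scope, as is cardiac motion.

### Numerical policy

Ray–triangle tests accept barycentric coordinates within $10^{-9}$ of the
triangle and distances within $10^{-9}$ mm of the ray segment; the
determinant cutoff for near-parallel rays is $10^{-12}$. The same constants
govern the compiled BVH path and the pure-R brute-force reference, so
grazing and vertex hits resolve *identically* in both — consistency, not
case-by-case correctness, is the contract, and the test suite asserts
equality of the two hit sets over thousands of random rays on all three
case models.

A ray passing exactly through a shared vertex or edge legitimately reports
one hit per incident triangle. Before parity is evaluated, coincident
crossings of one structure (within $10^{-7}$ mm) are collapsed: a cluster
that agrees in direction counts once (a pass through a vertex), a mixed
cluster cancels (a tangential graze). A line that exits a structure's
bounding box with odd parity left over raises an error — the signature of a
non-watertight mesh.

## The synthetic heart

No public specimen data accompany the cast-based workflow this package
emulates, so the generator is a first-class module: chambers are deformed
ellipsoids (a smooth low-order radial field, amplitude 5%, coefficients
drawn deterministically from the spec seed), vessels are tubes swept along
Chaikin-smoothed waypoint paths with parallel-transport frames. All
surfaces are watertight by construction, and tube endpoints are embedded
inside the structures they join, so anatomical continuity (ductus to
pulmonary trunk and descending aorta, cavae into the right atrium) is
detectable as mesh overlap; `structure_adjacency()` turns that into a
graph.

Absolute sizes are a design choice, set once at mid-gestation scale
consistent with 25–26-week anatomy: ventricular long axis ≈ 15 mm,
equivalent-sphere chamber radii 3.6–5.5 mm, great-artery radii
2.2–2.3 mm, branch vessels ≈ 1–1.8 mm. The three cases are:

* **normal** — full anatomy vocabulary (LA, LAA, RA, RAA, LV, RV, AO,
  Arch, DAO, aortic branches, PA, lPA, rPA, DA, SVC, IVC) plus a trachea
  placeholder for the three-vessels-and-trachea view;
* **double_aortic_arch** — the ascending aorta splits into left and right
  arches that both rejoin the descending aorta, closing a vascular ring
  around the trachea placeholder. The arch take-off points sit low enough
  that a transverse plane at the arch apex cuts exactly two disjoint arch
  cross-sections;
* **hrh_vsd_mga_pa** — the right ventricle is rescaled so RV/LV enclosed
  volume equals `rv_lv_ratio` (default 0.4) exactly; a tube of radius
  `vsd_radius` (default 1.5 mm) joins the ventricular cavities; the aorta
  arises anteriorly from the RV; and the pulmonary trunk's initial segment
  is absent — the PA begins blind above the ventricles and is fed only
  through the ductus.

What the generator does *not* emulate: myocardium and septal tissue (the
model is the blood pool, as a cast is), valve anatomy, motion, or the
perfusion-pressure distortions of real casting — the intended
calibration hook for the latter is `scale_structure()`, which rescales one
structure about a center. Tests passing on these models therefore certify
the pipeline's geometry and rendering, not anatomical fidelity to any real
specimen.

### Overlap priorities

Where meshes overlap (deliberately, at junctions), a voxel or pixel can
carry only one label. Priorities are assigned inversely to caliber: the
septal channel highest (60), the airway 35, thin vessels 32, veins 30,
arches 25, pulmonary trunk 23, aorta and descending aorta 22, chambers 15,
appendages 12. The rationale is conservation at the resolution of the
digitization: a great vessel losing a notch where a branch crosses it is a
negligible relative error, while a 1-mm branch clipped by a great vessel
can lose most of its voxels. Ties go to declaration order.

## Digitization and its round trip

`rasterize()` voxelizes by parity-filling rows of voxel centers against
each structure (with a deterministic sub-voxel jitter retry for degenerate
rows) and resolves overlaps by priority; the default grid, 0.4 mm in-plane
with 0.6 mm slices, mirrors a clinical CT protocol for desk-scale casts.
The resulting label volume is the digitization ground truth — the analogue
of the physical cast, in which the lumens partition space. Round-trip
statements are therefore made against it: thresholding the noise-free grey
volume, reassigning reference labels (`segment_volume()`), and extracting
surfaces recovers every structure and matches per-structure volumes within
5% at 0.4 mm (measured maximum ≈ 1.6%). Comparing extracted surfaces to
the *generator meshes* instead would conflate digitization error with
deliberate junction overlap, which the priority rule assigns to one side.

Connected components intentionally fail to separate the structures — the
blood pool is contiguous — which is why the delineation surrogate is
reference-guided: plain `label_components()` documents the merge (one
component), `match_labels()` renames disjoint components by maximal Dice,
and `segment_volume()` splits the thresholded foreground by the reference
label map, keeping any orphan foreground as numbered components. This
stands in for the interactive, manually validated segmentation of a real
workflow; with acquisition noise at 10% of contrast, voxelwise agreement
with the ground truth stays above 99%.

Surface extraction uses marching tetrahedra (six tetrahedra per cell
around a fixed diagonal): unlike classic marching cubes it has no
ambiguous cases, so closedness of the output is structural, not a matter
of table curation. On binary masks the raw surface is faceted and
overestimates area by ~25%; the default 25 Taubin iteration pairs
(λ = 0.5, μ = −0.53) bring a rasterized unit sphere's area within ~3% of
$4\pi$ while moving enclosed volume by well under 1%. Smoothing never
touches connectivity, so watertightness survives.

## Views and verification

Preset poses live in a YAML data file (pose as 16 row-major numbers,
required/forbidden structure lists), one entry per standard view, built
against the canonical frame: x = fetal left, y = posterior, z = cephalad,
origin at the four-chamber crux. The transverse views (four-chamber at
z = 0, three-vessel at z = 8, three-vessels-and-trachea at z = 9.5 mm) are
axial planes with the probe anterior; the outflow-tract, arch, ductal and
bicaval views are oblique planes through three anatomical anchor points.
Required-structure sets follow clinical convention (four-chamber ⊇ {LA,
RA, LV, RV}; three-vessel ⊇ {PA, AO, SVC}; LVOT ⊇ {LV, AO}; RVOT ⊇ {RV,
PA}; ductal ⊇ {PA, DA, DAO}; aortic arch ⊇ {AO, Arch, DAO}; bicaval ⊇
{SVC, IVC, RA}; 3VT adds the trachea and ductus).

`verify_view()` passes a slice when every required structure covers at
least `min_pixels` (default 30) pixels of the *label* slice — never the
grey image, whose values are not identity-preserving — and every forbidden
structure covers fewer. The default verification probe is a linear array
covering the whole heart (60 mm footprint and depth, 128 lines, 200
samples, 200×200 px at 0.3 mm); 30 pixels is then 2.7 mm², small enough to
admit genuine but oblique cuts, large enough to reject slivers.
`find_view()` wraps verification in seeded stochastic hill climbing
(translation σ 1 mm, rotation σ 3°, score = capped required coverage minus
forbidden coverage), returning as soon as a pose passes.

Pathology checks run on label slices with explicit spatial predicates:
`count_slice_regions()` (4-connected components of a structure mask — the
double arch shows exactly two arch cross-sections cephalad of the 3VT
plane), `slice_connected()` (LV and RV joined through the VSD channel, and
*not* joined without it), and `slice_adjacent()` (no PA pixel touches an
RV pixel in the atretic case).

## Problem sizes and determinism

The shipped defaults keep every computation at interactive scale: models
of ~15k triangles, label volumes of ~0.5M voxels, images of 200×200 px,
oracle comparisons over 1000 rays per case model, and 20-seed sweeps of
the case invariants. Randomness enters only through declared seeds — the
generator's chamber deformation, acquisition noise, speckle, and the view
search — and each consumer saves and restores the caller's RNG state, so
fixed seeds give byte-identical meshes and images and the command-line
runs record their parameters in `provenance.json`.

## Known limitations

* Grey values are display conventions, not acoustic impedances; no
  scattering texture, shadowing or enhancement artifacts.
* The anatomy is schematic: ellipsoids and tubes reproduce topology and
  approximate proportions, not patient-specific shape. The lesion
  signatures are built in by construction; their verification demonstrates
  that the *rendering and measurement* chain preserves them.
* Overlap-priority labeling makes per-structure voxel volumes
  interpretation-dependent at junctions (see above).
* `match_labels()` assumes components correspond to structures; it is the
  right tool only after lumens are separated (as in a physical cast), and
  the reference-guided `segment_volume()` is the default path otherwise.
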