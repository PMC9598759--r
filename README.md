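# vfecho: virtual fetal echocardiography from digitized heart models

Training in fetal echocardiography is limited by access: standard views are
hard to learn, physical ultrasound phantoms are expensive, and each phantom
holds only one anatomy. One way out is to digitize real cardiovascular
anatomy — for example a resin cast of the fetal blood pool imaged by CT and
segmented into per-structure surface meshes — and then *simulate* B-mode
ultrasound against those meshes, so a trainee can steer a virtual probe
through normal hearts and congenital lesions alike.

`vfecho` implements that pipeline end to end in R:

* **Anatomy.** A heart model is a set of named, watertight, outward-oriented
  triangle meshes (LA, RA, LV, RV, AO, PA, ductus arteriosus, caval veins,
  ...) with a material id and an overlap priority per structure, all in one
  anatomical frame (x = fetal left, y = posterior, z = cephalad, mm). Models
  load from STL/PLY/OBJ plus a YAML manifest, or come from the built-in
  procedural generator, which produces a normal mid-gestation heart and two
  lesion cases: a **double aortic arch** (vascular ring) and a
  **hypoplastic right heart** with ventricular septal defect, malposed
  great arteries and pulmonary atresia.
* **Digitization.** `rasterize()` emulates the cast CT scan (label volume at
  0.4 mm in-plane / 0.6 mm slices by default), `add_acquisition_noise()`
  produces grey intensities, and `threshold_cast()`, `label_components()`,
  `match_labels()`, `segment_volume()` and `extract_surfaces()` (marching
  tetrahedra + Taubin smoothing) recover watertight per-structure surfaces.
  Volumes read/write NRRD, NIfTI-1 and MetaImage.
* **Ultrasound simulation.** For a probe pose `T` (a 4x4 homogeneous
  transform mapping image coordinates to heart coordinates), scan lines are
  laid out per a linear or curvilinear probe configuration, all
  scan-line/mesh crossings are found with a bounding-volume hierarchy whose
  defining contract is equality with a brute-force all-triangle test, the
  segments between crossings are filled with per-material grey values
  (optional exponential depth attenuation and speckle), and the filled
  lines are scan-converted to a Cartesian B-mode image with a ground-truth
  structure-id slice alongside.
* **Views.** `standard_views()` ships preset poses and required-structure
  sets for the eight standard fetal echocardiography views (four-chamber,
  LVOT, RVOT, three-vessel, three-vessels-and-trachea, aortic arch, ductal,
  bicaval); `verify_view()` checks a rendered slice against a spec,
  `find_view()` recovers a passing pose by seeded local search, and
  `lesion_views()` adds the diagnostic planes for the two lesion cases.

## Worked example

```r
library(vfecho)

heart <- generate_heart(synthetic_heart_spec("normal", seed = 1))
heart
#> <heart_model: 17 structures [LA, LAA, RA, RAA, LV, RV, AO, Arch, DAO,
#>   AoBs, PA, lPA, rPA, DA, SVC, IVC, Trachea]>

views <- standard_views()
sim <- simulate_bmode(heart, views$four_chamber$pose, default_view_probe())
verify_view(sim$label, views$four_chamber)
#> <view_report 'four_chamber': PASS; LA=407 RA=383 LV=701 RV=645>
```

The report counts ground-truth label pixels per required structure at
0.3 mm pixels: all four chambers are on screen, so the four-chamber view
passes. The hypoplastic right heart renders the same plane with a
visibly small RV (RV/LV pixel ratio about 0.51 against 0.92 for the
normal heart):

```r
hrh <- generate_heart(synthetic_heart_spec("hrh_vsd_mga_pa"))
sim <- simulate_bmode(hrh, views$four_chamber$pose, default_view_probe())
counts <- slice_pixel_counts(sim$label)
counts["RV"] / counts["LV"]
#>        RV
#> 0.5106990
plot(sim$bmode)
```

The same pipeline is scriptable from a shell:

```sh
VFECHO=$(Rscript -e 'cat(system.file("cli", "vfecho", package = "vfecho"))')
Rscript $VFECHO genheart --case double_aortic_arch --out darch --seed 1
Rscript $VFECHO views --model darch --out darch_views
```

which writes the eight view images plus `report.json` with per-view pass
flags and pixel counts, and a `provenance.json` sufficient to reproduce
the run byte-for-byte.

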