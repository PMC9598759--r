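Package: vfecho
Title: Virtual Fetal Echocardiography from Digitized Heart Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Digitizes multi-structure fetal heart anatomy into posed surface
    meshes and simulates B-mode ultrasound images for arbitrary probe poses by
    scan-line/mesh intersection and material-based grey-value filling. Includes
    a procedural generator for a normal mid-gestation heart and two congenital
    lesions (double aortic arch; hypoplastic right heart with ventricular
    septal defect, malposed great arteries and pulmonary atresia), a cast-CT
    rasterizer and segmentation surrogate, preset probe poses for the eight
    standard fetal echocardiography views with automated verification, and a
    command-line interface for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    jsonlite,
    png,
    xml2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
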