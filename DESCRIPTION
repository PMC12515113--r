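Package: mandseg
Title: Two-Stage 3D U-Net Segmentation and Edentulous Geometry Synthesis
    for Mandibular CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for segmenting the mandible from CT-like volumes with a
    coarse-to-fine two-stage 3D U-Net and for generating anatomically valid
    edentulous (Cawood-Howell Class III and Class V atrophy) mandibular
    geometries from dentate scans. Includes volume and STL mesh input/output
    with world-coordinate handling, a parametric synthetic mandible phantom
    generator for fully testable end-to-end runs without clinical data,
    training-time spatial augmentation, iso-surface extraction with Taubin
    smoothing, Dice and symmetric average-surface-distance evaluation,
    automatic anatomical curve metrics (caudolateral and dental curves), and
    non-parametric statistical comparison machinery for cohort summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
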