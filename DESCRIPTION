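Package: octfluid
Title: Confidence Mapping of Diabetic Macular Edema Fluid in OCT B-Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patch-based characterization of retinal fluid accumulations
    (cystoid macular edema, diffuse retinal thickening, serous retinal
    detachment) in optical coherence tomography B-scans under the diffuse
    paradigm: labeled 64x64 window sampling with mirror completion at image
    borders, image-level 6-fold cross-validation over all 60 train/val/test
    fold assignments, a densely connected convolutional patch classifier
    trained under three regimes (from scratch, generalist transfer, and
    uncertainty-aware two-stage transfer in which a binary healthy-versus-
    pathological pretraining absorbs expert-labeled uncertainty regions),
    per-pixel confidence maps by voting over overlapping windows, and
    connected-component confidence analysis with sliding-median trend lines.
    Includes a synthetic layered-retina phantom generator so the whole
    pipeline is exercisable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
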