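Package: nucleoflux
Title: Kinetics of Light-Gated Nucleocytoplasmic Transport and Terminal
    Mechanical Stability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for studies of orientation-dependent protein
    traffic across the nuclear pore complex. Implements the two-compartment
    first-order model of optogenetically switched nuclear import/export and
    per-cell fitting of recovery time courses with quality-control filtering;
    quantification of nuclear and cytoplasmic signal from time-lapse image
    stacks with supplied masks; freely-jointed-chain (FJC) polymer elasticity
    and change-point detection of unfolding steps in magnetic-tweezers force
    ramps, including a Bell-model ramp simulator; a survey of intrinsic
    disorder around nuclear localization signals in transcription factors;
    and geometric backbone hydrogen-bond counting between beta-strands of PDB
    structures. Every input the pipeline consumes can be generated
    synthetically with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    bio3d,
    tiff,
    png,
    seqinr,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
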