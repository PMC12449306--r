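Package: rsdpet
Title: Residual Space Detection of Task-Induced Dopamine Release in Dynamic PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-level detection and semi-quantification of task-induced
    striatal dopamine release from dynamic [11C]raclopride PET. Implements
    reference-tissue kinetic models (MRTM, lp-ntPET with F-test detection),
    an iterative MRTM baseline extrapolation, and the RSD-Hybrid-IMRTM
    pipeline that combines model-derived and measured baselines through
    non-local-means weighting in z-scored kinetic-parameter space. Includes
    a residual form of lp-ntPET with peak-occupancy estimation, a digital
    phantom simulator based on the ntPET receptor-competition model, and
    ROC / tracking / overlap evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    RNifti,
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
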