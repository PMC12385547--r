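Package: spinaldti
Title: Simulation and Reliability Analysis of Axial Spinal-Cord Diffusion Tensor Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for studying the test-retest and inter-scanner reproducibility
    of high-resolution axial diffusion tensor imaging (DTI) of the cervical
    spinal cord. Provides a synthetic phantom generator for a single axial
    C2-level slice (elliptical cord with a gray-matter butterfly inside a
    bright CSF ring, six diffusion-encoding directions, Rician noise,
    anterior-posterior breathing motion, and a participant x scanner x session
    cohort structure with known variance components), preprocessing
    (cropping, midsagittal-profile motion correction, repetition averaging),
    log-linear tensor fitting with FA/MD/AD/RD maps and interpolation,
    automated elliptical cord segmentation with circular tract ROIs for the
    pyramidal tracts, dorsal columns and anterior horns, and a full
    reliability battery (paired t-tests, Cohen's d, single/average ICC with
    F-based confidence intervals and Cicchetti/Koo classification,
    within-participant coefficients of variation, Bland-Altman analysis).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
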