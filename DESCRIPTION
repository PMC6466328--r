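Package: sarpce
Title: Stochastic Radiofrequency Dosimetry for MRI with Polynomial-Chaos Surrogates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Voxel-phantom radiofrequency dosimetry for MRI transmit coils with a
    stochastic analysis of body positioning. Provides tissue-property tables and
    mass-weighted dielectric homogenization, a quasi-static forward model of the
    induced electric field in a circularly polarized birdcage-type coil, specific
    absorption rate (SAR) metrics (whole-body, head, and 10 g peak-spatial cube
    averages), and sparse polynomial-chaos surrogates of SAR over random Z-axis
    shift and body tilt. Surrogates use an orthonormal Hermite tensor basis with
    least-angle-regression term selection, corrected leave-one-out cross-validation,
    and Latin-hypercube experimental designs. Includes a synthetic phantom generator
    producing heterogeneous reference bodies and tissue-simplified individualized
    counterparts so the full pipeline runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pracma,
    optparse,
    RNifti
Config/testthat/edition: 3
RoxygenNote: 7.3.3
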