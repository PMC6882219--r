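Package: oratlas
Title: Optic Radiation Atlas Construction, Labeling and Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building a group atlas of the optic radiation and
    Meyer's loop from deterministic streamline tractography, propagating the
    atlas into individual space through affine plus dense-displacement
    transforms, and validating the labeling with a correspondence-rate
    statistic computed on maximal tract-density voxels, a shift-tolerance
    profile, a bootstrap test, a surgical safety-zone check, and anatomical
    measurements (anterior ridge, dTM, LGN-to-ridge distance, upper/lower
    division twist). Includes a synthetic phantom cohort generator with known
    ground truth for end-to-end parameter-recovery experiments, a
    deterministic streamline tracker on orientation/QA fields, tract density
    imaging, readers and writers for NIfTI volumes and TCK streamlines, and a
    navigation-compatible DICOM series export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
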