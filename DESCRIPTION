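Package: tmjmech
Title: Patient-Specific Temporomandibular Joint Biomechanics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for patient-specific biomechanical assessment of the
    temporomandibular joint (TMJ). Implements the function-assessment signal
    chain that turns bite-force and surface-EMG recordings into simulation
    inputs (target force curve and ipsilateral-to-contralateral activation
    ratios), a rigid-mandible forward-dynamics simulator with planar bite
    constraint, elastic-foundation joint contact and per-step force-tracking
    quadratic programming, articular-surface joint-gap and congruency mapping
    on triangulated meshes, landmark morphometrics with scaling-stress
    normalization, a mandible-length validation sweep, and deterministic
    synthetic-data generators for all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
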