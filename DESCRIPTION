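Package: slipstrain
Title: Fingerpad Surface Strain Fields and Tactile Afferent Encoding During Partial Slip
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to relate skin surface strain-rate fields in a fingerpad
    contact to the spike trains of single tactile afferents during tangential
    loading and partial slip. Tracked skin-feature trajectories are converted
    into Green-Lagrange strain-rate tensor fields on a Delaunay mesh, smoothed,
    and interpolated onto a fixed grid covering the contact area. Spike trains
    are summarized as Gaussian-smoothed firing rates, spike-triggered average
    strain maps with a no-spike null, and cross-validated linear encoding
    models including a reference-frame rotation scan for preferred strain
    orientation. A synthetic-experiment generator simulates the annular slip
    front of a partial-slip contact, friction-dependent force traces, and
    inhomogeneous-Poisson afferent spike trains with known ground truth, so
    the whole analysis chain can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    interp,
    signal,
    Matrix,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    rhdf5,
    yaml,
    optparse
Config/testthat/edition: 3
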