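Package: cbctshade
Title: Prior-Free Image-Domain Shading Correction for Cone-Beam CT
Version: 0.1.0
Authors@R: person("CBCT", "Tools", email = "cbct.tools@example.org", role = c("aut", "cre"))
Description: Estimates and removes the low-frequency multiplicative shading
    (bias) field of cone-beam CT volumes directly in the image domain, with
    no prior images or patient-specific assumptions.  Each transverse slice
    is resampled into polar coordinates about the patient centroid; wide
    angular median filtering followed by low-order polynomial fitting
    recovers the smooth bias field, which is mapped back to Cartesian space,
    median-filtered in 3D, divided out, and recalibrated to Hounsfield
    units.  Includes an optional precorrection round for global ring-shaped
    shading from bowtie/half-fan acquisitions, a digital phantom simulator
    with ground-truth bias fields, volume readers and writers (NIfTI-1,
    MetaImage, raw + sidecar), ROI-based quality metrics (mean CT-number
    error and spatial nonuniformity), and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
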