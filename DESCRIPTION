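Package: hemokymo
Title: Hemodynamic Analysis of Kilohertz Two-Photon Blood-Flow Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for ultrafast two-photon fluorescence imaging
    of cerebral blood flow, where unlabeled red blood cells appear as dark
    objects moving through fluorescently labeled plasma. Provides a synthetic
    blood-flow simulator with exact ground truth (kymographs, vessel videos,
    penetrating-vessel transit traces), line-illumination intensity
    normalization, rigid motion registration, kymograph extraction along
    polyline regions of interest, windowed cross-correlation particle image
    velocimetry and a Radon-transform velocity estimator, dense SIFT-flow
    2D velocity mapping by discrete energy minimization, vessel diameter
    measurement, blunted-parabola radial velocity profile fitting, red blood
    cell flux counting and transit half-time estimation, pulsatility and
    cardiac-harmonic spectral analysis, and a reproducible multi-stage
    pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
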