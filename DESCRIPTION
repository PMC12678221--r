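Package: vesselsmooth
Title: Noise Reduction and Smoothing of Vascular Surfaces from Low-Resolution Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reduce segmentation and voxelization noise in vascular
    lumen surfaces extracted from low-resolution (~0.7 mm/px) medical images.
    The geometry is cut into cross-sections along the slice axis, contours are
    resampled at equal arc length, longitudinal generator curves are rebuilt
    with natural cubic splines and cleaned with a selective standard-deviation
    / median filter, and the result is lofted back to a watertight STL mesh.
    Includes a Taubin smoothing baseline, synthetic voxelized vessel phantoms
    with known ground truth, sectioned arithmetic-mean roughness (Ra) metrics,
    mesh volume by the divergence theorem, and wall-shear-stress
    post-processing utilities (surface-averaged WSS, TAWSS, area-weighted
    distributions, pulsatile inlet waveform models).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
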