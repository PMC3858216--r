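Package: orbitrack
Title: Subpixel Tracking of Fluorescent Foci on Spherical Sporulating Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the motion of fluorescent protein clusters on the
    surface of near-spherical sporulating bacteria from single-plane time-lapse
    fluorescence microscopy. The pipeline segments cells with subpixel spline
    contours, detects diffraction-limited foci by Gaussian fitting, projects
    planar detections onto a spherical coordinate system (p, theta, phi) with
    phi = arccos(r/p), links detections into trajectories using great-circle
    (orthodromic) distances, and decomposes motion by fitting the mean square
    displacement to 4*D*t + v^2*t^2 to separate directed transport from surface
    diffusion. A synthetic time-lapse generator renders ground-truth surface
    trajectories into noisy image stacks so that every stage of the pipeline can
    be validated against known parameters. Additional quantifications include
    single-cell intensity-ratio time courses, lectin-stain area ratios,
    foci-per-cell counts, and kymographs resliced along a cluster path.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    tiff,
    jsonlite,
    mgcv,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
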