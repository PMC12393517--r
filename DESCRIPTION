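Package: minicircle
Title: Sequence-Dependent Poloidal Orientation Analysis of DNA Minicircles
Version: 0.1.0
Authors@R:
    person("Quantitative Biophysics Lab", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Tools for detecting and quantifying sequence-dependent poloidal
    bias in covalently closed DNA minicircles. Builds ideal three-site
    (sugar/phosphate/base) coarse-grained duplex models on perfect helical
    trajectories, bends them into uniformly twisted planar minicircles and
    closes the bonded topology; computes a global-morphology poloidal angle
    per conformation together with circular statistics (von Mises) and the
    signed horizontal displacement of a reference phosphate; segments
    particles in AFM-style height images to obtain the centroid/center-of-mass
    offset distance delta and the count-based relative affinity alpha; and
    extracts helical-phase shifts from positional series by fixed-period
    weighted sinusoidal fitting. Includes synthetic-data generators with known
    ground truth for every pipeline input, plus readers/writers for
    molecular-dynamics data and dump text formats, plain-text images, and CSV
    series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    Biostrings
Config/testthat/edition: 3
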