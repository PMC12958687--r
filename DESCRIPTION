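Package: pbict
Title: Propagation-Based Phase-Contrast CT Simulation, Reconstruction and
    Image Quality Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for simulating and analysing propagation-based X-ray
    phase-contrast computed tomography (PBI-CT) of lung-like specimens.
    Includes a digital lung phantom generator (airway tree, vessels,
    lobular septa, dense lobules), a coherent-imaging forward model
    (Fresnel propagation, anisotropic source-spot blur, photon-counting
    detector with Poisson statistics and panel defects), detector-domain
    pre-processing (flat-field correction, defect inpainting, off-center
    360-degree extended field-of-view conversion), self-supervised
    Noise2Noise sinogram denoising with a small 4-level encoder-decoder
    network, single-distance TIE-Hom (Paganin) phase retrieval, filtered
    back projection, vertical volume stitching, and a quantitative
    image-quality suite (contrast-to-noise ratio, edge-profile FWHM,
    radially averaged power spectra, edge enhancement, source-spot
    estimation from edge blur, and multislice-CT resolution simulation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
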