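Package: fnirsdot
Title: Image-Reconstructed Functional Near-Infrared Spectroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for volumetric image reconstruction of
    functional near-infrared spectroscopy (fNIRS) data. Cleans optode
    digitizations by rigid (Kabsch) alignment to per-cap-size templates,
    preprocesses channel time series (pruning, optical density, bandpass
    filtering, global signal regression), vectorizes per-channel sensitivity
    volumes into a sparse voxel basis, inverts the sensitivity matrix by
    spatially variant Tikhonov regularization, converts two-wavelength
    absorption images to oxy-/deoxy-hemoglobin, verifies reconstructions
    against channel data with sphere-based correlations, and fits voxelwise
    general linear models with gamma hemodynamic response functions. Includes
    seeded synthetic generators (layered head phantoms, banana-shaped
    sensitivity surrogates, digitizations, channel recordings) so the full
    pipeline runs without any real recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
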