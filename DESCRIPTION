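Package: hsitime
Title: Exploration of Hyperspectral Image Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the headless, scriptable exploration of time series of
    hyperspectral images (HSI) of benthic organisms such as cold-water corals.
    Provides an HDF5 cube store with polygon-based splitting of multi-sample
    scans, l1 spectral normalization and agglomeration spectra, pseudo
    grey-value and pseudocolor image rendering, 2-D embeddings (UMAP, t-SNE)
    of all masked pixel spectra pooled over time points, cross-domain linked
    selection (link and brush) between image, spectrum and embedding views,
    detection of time-point-exclusive embedding regions via k-nearest-neighbor
    label purity, spectral change quantification (crossing wavelengths,
    blue/red band-shift index), observer change-rating aggregation with star
    glyph tables, and a synthetic coral-like HSI generator with ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rhdf5,
    uwot,
    Rtsne,
    FNN,
    jsonlite,
    png,
    stats,
    grDevices,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    sp
Config/testthat/edition: 3
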