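Package: netembed
Title: Neural-Network Surrogates for t-SNE and UMAP Embeddings of Large
    Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Scales nonlinear dimensionality reduction to arbitrarily large
    omics datasets by learning the embedding with neural networks in both
    directions. A tractable subset of the data is embedded with exact t-SNE
    or UMAP under a correlation distance metric; forward (features to
    coordinates) and inverse (coordinates to features) multilayer perceptrons
    are trained on the subset and applied to the remaining or newly acquired
    samples. Includes readers for imzML mass spectrometry imaging data,
    delimited spectral matrices and Hi-C contact lists; pseudo-spectrum
    reconstruction from embedding coordinates with spectral-driver ranking
    and ppm-tolerance annotation; cross-omics projection of one modality into
    another modality's reduced space for matched samples; k-nearest-neighbour
    novelty scoring of new data; and RGB image rendering, box segmentation
    and leave-one-out linear discriminant classification on the reduced
    coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    Rtsne,
    uwot,
    data.table,
    jsonlite,
    xml2,
    tibble,
    generics,
    ggplot2,
    png
Suggests:
    testthat (>= 3.0.0),
    MASS,
    e1071,
    withr
Config/testthat/edition: 3
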