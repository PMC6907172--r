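Package: mutembed
Title: Multi-Modal Autoencoder Embeddings of Tumor Somatic Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of pan-cancer somatic mutation
    profiles with a multi-modal autoencoder that treats deleterious and
    non-deleterious variant counts as separate input modalities joined in a
    shared latent space. Provides the surrounding analysis pipeline: a
    synthetic-cohort simulator with nested tumor type/subtype labels,
    MAF-like record preprocessing into paired gene-count matrices (support
    filtering, zero-one normalization, stratified train/test/fold splits),
    Gaussian-kernel target alignment and hierarchical-clustering mutual
    information for scoring embedding quality, and per-subtype one-class
    nu-SVM classifiers benchmarked across latent and input spaces by AUC-ROC.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
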