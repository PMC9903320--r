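Package: ms2dist
Title: Distances Between Tandem Mass Spectrometry Datasets and
    Spectral Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes a symmetric distance between sets of tandem mass
    spectra (MS/MS) from windowed pairwise spectral similarity (cosine
    score or spectral angle), aggregates sample-level distances into a
    species-level distance matrix, and renders the matrix as a rooted
    ultrametric tree by UPGMA. Includes a tolerant Mascot Generic Format
    (MGF) reader/writer with intensity and chromatographic filters,
    per-dataset quality-control metrics, a precursor m/z difference by
    similarity diagnostic histogram, writers for MEGA, Newick and NEXUS
    formats, and a synthetic-spectrum generator for testing pipelines
    with controlled dataset overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    grDevices,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
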