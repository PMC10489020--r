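Package: chemmaps
Title: Chemical Space Mapping with Extended Similarity Indices
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Samples and maps the chemical space of molecular libraries
    represented by binary fingerprints. Implements the extended (n-ary)
    Jaccard-Tanimoto similarity with its coincidence-threshold column
    classification, linear-time complementary (leave-one-out) similarity
    ranking from medoid to periphery, five chemical-satellite sampling
    strategies, and backward/forward validation of two-component PCA maps
    built from similarity matrices, with distance-correlation quality
    curves. Includes SMILES ingestion and MACCS/ECFP4/RDKit fingerprint
    generation via the RDKit, a clustered synthetic fingerprint generator
    for download-free testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    vegan,
    withr
SystemRequirements: Python (>= 3.8) with the RDKit, for the fingerprint
    module only; all other functionality is pure R.
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
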