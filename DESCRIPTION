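Package: proteanrf
Title: Per-Residue Random Forest Prediction of Protean Segments in
    Intrinsically Disordered Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts protean segments, the parts of intrinsically
    disordered protein regions that undergo a disorder-to-order
    transition upon binding a partner, from sequence-derived evidence.
    Reads PSI-BLAST position-specific scoring matrices, PSIPRED
    secondary-structure tracks and per-residue disorder probability
    tracks, assembles a 342-dimensional sliding-window feature vector
    per residue (PSSM mutability, conservation, composition,
    physicochemical properties, secondary structure, disorder-segment
    descriptors and disorder topography), and trains a random-forest
    classifier evaluated by cluster-grouped cross-validation. Includes
    sequence-consensus analyses (amino-acid propensities,
    secondary-structure content, the Altscore indecisiveness statistic)
    and a synthetic-corpus generator for self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    optparse
Config/testthat/edition: 3
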