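Package: svmheatmap
Title: Heat Map Molecule Coloring for Linear SVM Fingerprint Models
Version: 0.1.0
Authors@R:
    person("Maintainer", "Package", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Interprets linear support-vector-machine screening models built
    on circular substructure (ECFP-style) fingerprints by mapping the model's
    feature weights back onto the bonds of a molecule. Provides an
    explicit-growth circular fingerprint that records, for every hashed
    feature, the exact set of atoms and bonds each occurrence covers; a
    liblinear-style L2-regularized hinge-loss solver with class weighting and
    repeated two-deep cross-validation; per-bond score attribution with
    full-set and single-molecule normalization; a red-orange-green two-part
    color gradient; SVG depiction of colored molecules; and a synthetic
    library generator that plants weighted substructures so the whole
    pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
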