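Package: netfeat
Title: Network-Derived Protein Features for Negative Example Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts local and global topological features of proteins from
    weighted protein-protein interaction networks (STRING-style edge lists)
    and evaluates their usefulness for choosing reliable negative examples in
    automated protein-function prediction. Implements seventeen per-protein
    features (neighborhood statistics, geometric centralities, their
    term-aware counterparts, and short random-walk probabilities), temporal
    holdout construction from two Gene Ontology annotation releases, a
    CART-wrapped sequential floating forward feature-selection experiment,
    per-term function prediction with class-weighted linear support vector
    machines and random forests under nested cross-validation, and budgeted
    negative selection with false-negative accounting. A synthetic-data
    generator with a controllable guilt-by-association effect makes the whole
    pipeline testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    rpart,
    e1071,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    igraph,
    jsonlite
Config/testthat/edition: 3
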