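Package: fibrilscan
Title: Energetic Profiling and Classification of Amyloid Fibril Polymorphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to build layered cross-beta protofilament assemblies from
    deposited coordinates, run an in silico alanine scan with a pluggable
    energy backend to obtain per-residue stability profiles (assembly energy
    changes, interface ddG, edge/internal layer decomposition, and folding
    SASA burial), and cluster and classify fibril polymorphs from those
    profiles using Ward agglomerative clustering and an interpretable
    random-forest procedure with exact decision-path contribution
    decomposition. Includes deterministic synthetic-fibril and
    synthetic-profile generators so every stage can be exercised without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    randomForest,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    ape,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
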