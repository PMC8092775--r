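Package: motifSpace
Title: Combinatorics of the Protein Linear Motif Universe
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate the size of the protein short linear motif
    (SLiM) universe from regular-expression motif classes. Parses and
    preprocesses ELM-style regular expressions into allowed-amino-acid sets,
    measures pairwise motif specificity as motif-discriminating positions
    (including the alignment procedure for classes of unequal length),
    computes pigeonhole and Erdos-Ko-Rado style bounds on the maximal number
    of motif classes that can coexist at a given specificity level and
    alphabet size, computes sequence-space occupancy, derives effective
    alphabet sizes from post-translational modification frequencies via
    Shannon entropy, and orchestrates database-level analyses with robustness
    experiments. A seeded synthetic motif-database generator emulating the
    statistical structure of curated SLiM databases makes every stage
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'alphabet.R'
    'AllGenerics.R'
    'AllClasses.R'
    'combinatorics.R'
    'io.R'
    'motif-ops.R'
    'motifSpace-package.R'
    'occupancy.R'
    'parse.R'
    'specificity.R'
    'pipeline.R'
    'ptm.R'
    'synthetic.R'
    'utils.R'
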