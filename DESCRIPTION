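Package: featkit
Title: Sequence-Derived Protein Features, PCA Reduction, and Hierarchical
    Nearest-Prototype Classification
Version: 0.1.0
Authors@R:
    person("featkit", "developers", email = "featkit@example.org",
           role = c("aut", "cre"))
Description: Computes a 1497-dimensional descriptor vector for protein
    sequences (amino acid and dipeptide composition; normalized Moreau-Broto,
    Moran and Geary autocorrelation over eight physicochemical scales;
    composition/transition/distribution global descriptors over seven 3-way
    residue groupings; sequence-order-coupling numbers and
    quasi-sequence-order descriptors over two amino-acid distance matrices;
    pseudo amino acid composition), reduces it by principal component
    analysis, classifies by cosine-similarity nearest prototype ("intimate
    sorting") in a five-level hierarchical cascade, and evaluates with
    jackknife per-class and overall accuracies. Includes embedded
    physicochemical constant tables, a seeded synthetic-fixture generator,
    FASTA/TSV input and output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
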