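Package: nitrosite
Title: Sequence-Based Prediction of Protein S-Nitrosylation Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for predicting cysteine S-nitrosylation (SNO) sites
    from protein sequence. Extracts cysteine-centered peptide windows from
    FASTA, encodes them with nine sequence descriptors (parallel-correlation
    pseudo amino acid composition and its general form, basic kmer
    compositions, bi-profile Bayes and its double / adapted-normal variants,
    pairwise and tri-amino-acid positional propensities), ranks features by
    information gain or by max-relevance max-distance (MRMD), performs
    incremental feature selection under cross-validation, and evaluates
    binary predictors with sensitivity, specificity, accuracy and Matthews
    correlation coefficient. Includes seeded generators for synthetic
    peptide-window datasets with planted positional motifs, a single-call
    model-fitting interface, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
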