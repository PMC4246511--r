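Package: protchar
Title: Protein Sequence Characterization for Machine Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parses the standard text formats of sequence-based protein
    structure prediction (FASTA, anchored multiple sequence alignments,
    PSI-BLAST ASCII position-specific scoring matrices, DSSP output, and
    SSpro/ACCpro and PSIPRED predictions) and converts them into numerical
    feature vectors: orthogonal (one-hot) encodings, residue and annotation
    compositions, physicochemical lookups, pairwise contact potentials,
    profile frequencies and Shannon information measures. Labeled feature
    vectors are serialized to SVM^light-style sparse or dense text files for
    off-the-shelf machine learning tools, via a library interface and a small
    command-line driver. A deterministic fixture generator fabricates
    mutually consistent synthetic inputs in every supported format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
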