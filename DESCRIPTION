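Package: nsltp
Title: Identification and Classification of Plant Non-Specific Lipid
    Transfer Proteins by Their Eight-Cysteine Scaffold
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for plant non-specific lipid transfer proteins
    (nsLTPs). Locates the conserved eight-cysteine motif
    (C-Xn-C-Xn-CC-Xn-CXC-Xn-C-Xn-C) and its cysteine-deficient variants
    in protein sequences, assigns the five-type classification from
    inter-cysteine spacing, parses and scans Prosite-syntax motif
    patterns (including built-in Type I / Type II nsLTP patterns and
    the PLANT_LTP entry PS00597), induces new Prosite-styled patterns
    from multiple alignments by per-column residue occurrence, computes
    molecular weight, net charge, isoelectric point and CXC-polarity
    profiles, and builds UPGMA and neighbor-joining trees from global
    alignment identities with Newick output. A synthetic-sequence
    generator produces pattern-conforming sequences, type-spaced
    sequences and single-violation decoys so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
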