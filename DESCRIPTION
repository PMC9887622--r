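Package: spliceotrace
Title: Reconstructing the Duplication and Intron History of Ancestral Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inference machinery for tracing the pre-LECA (last eukaryotic
    common ancestor) origin of a multi-protein complex from gene structures,
    protein alignments and gene trees: detection of homologous intron
    positions across paralogs by alignment column and codon phase, ancestral
    intron reconstruction by Dollo parsimony and by a two-state gain/loss
    Markov model, classification of duplication nodes by the fate of their
    products relative to the complex, collapsing of within-complex
    duplications into ancestral units, Dollo counting of recurrent losses on
    a species tree, and detection of recurrent paralog fates
    (subfunctionalization) after independent post-LECA duplications.
    Includes a synthetic gene-family generator with known duplication and
    intron histories so every inference stage can be validated against
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    methods,
    rtracklayer,
    S4Vectors,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
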