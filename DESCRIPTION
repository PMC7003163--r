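Package: codonDegen
Title: Principled Codon Degeneration and Supermatrix Utilities for Deep Phylogenomics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for codon-aware supermatrix phylogenomics: synonymous codon
    degeneration under a purity-preserving ("principled") protocol and the
    classical Degen1 protocol for any NCBI genetic code; ambiguity-averaged
    match/mismatch matrices over the IUPAC nucleotide alphabet with pairwise and
    sum-of-pairs (SP) alignment scoring; position-weight-matrix refinement of
    multiple sequence alignments; threading of codon sequences onto protein
    alignments; supermatrix concatenation with partition bookkeeping, filtering
    of codon sites where serine is encoded by both AGN and UCN codon classes,
    and GC content at third codon positions (GC3); and Fitch parsimony
    ancestral-state reconstruction with minimum state-switch counts on rooted
    binary trees.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    ape
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
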