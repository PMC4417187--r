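Package: mtdrscan
Title: Direct-Repeat Mutagenicity and Codon-Usage Analysis of Mitochondrial Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Enumerates maximal non-D-loop direct repeat (DR) pairs in annotated
    mitochondrial genomes, scores their deletion mutagenicity, and asks what
    shapes DR abundance. Provides eight selective sequence-randomization null
    models (gene-order shuffles, within-gene nucleotide and codon shuffles,
    unbiased synonymous codon usage re-encoding, and uniform-nucleotide
    sequences), synonymous codon usage statistics (Wright's effective number of
    codons, GC3, strand skews), and phylogenetically corrected longevity
    analyses (body-mass residuals, independent contrasts, subpopulation and
    ensemble tests). A synthetic-data module generates annotated mtDNA-like
    genomes and trait-bearing Yule phylogenies with known structure so the
    whole pipeline can be exercised without downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
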