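Package: codonbias
Title: Synonymous Codon Usage Bias Analysis for Small Viral Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of synonymous codon usage in protein-coding
    sequences, built around the workflow used for small DNA viruses such
    as Torque teno sus virus: nucleotide composition overall, by codon
    position and at synonymous third positions; relative synonymous codon
    usage (RSCU) and preferred-codon calling; Wright's effective number of
    codons (ENC) with the expected-ENC curve against GC3s; correspondence
    analysis of RSCU matrices; hierarchical clustering of genomes by RSCU;
    Spearman rank correlation matrices with significance banding; a
    sliding-window distance-to-reference recombination scan; and a
    synthetic coding-sequence generator with controllable third-position
    GC bias for validation. Ships a reference composition table for 41
    complete TTSuV2 coding sequences so published per-genome statistics
    are reproducible offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    seqinr,
    ape
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
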