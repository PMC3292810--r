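Package: seqscan
Title: Group-Aware Scanning of Sequence Alignments for Diversity,
    Recombination and RNA Secondary Structure
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for managing nucleotide and amino-acid multiple
    alignments annotated with independent tag-group classifications, and
    for scanning them for evolutionary signal.  Implements pairwise and
    group-mean evolutionary distances (Jukes-Cantor, Kimura
    two-parameter, Tajima-Nei, Nei-Gojobori and Li-Pamilo-Bianchi
    synonymous/non-synonymous, amino-acid p/Kimura/matrix models) with
    standard errors, motif and similarity dot-plot scans, composition
    statistics (dinucleotide odds ratios with amino-acid correction,
    relative synonymous codon usage, effective codon number, synonymous
    base-usage bias), consensus and parsimony ancestral reconstruction
    with context-stratified substitution spectra, phylogenetic
    segregation and recombination scans (association index, grouping
    scan, bootscanning, tree-order scan with Robinson-Foulds
    phylogeny-violation matrices), minimum-folding-energy-difference RNA
    secondary structure scanning against constrained sequence shuffles
    (exact dinucleotide-preserving, codon-order and synonymous-codon
    algorithms), covariation and structure-conservation summaries, and
    seeded synthetic-fixture generators with ground-truth manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    phangorn,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
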