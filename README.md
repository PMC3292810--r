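# seqscan

Group-aware scanning of nucleotide and amino-acid alignments for sequence
diversity, recombination and RNA secondary structure.

Molecular epidemiologists and virus evolution labs routinely hold multiple
alignments in which every sequence belongs to groups along several
independent axes — genotype, host, year, compartment.  Most interesting
questions are *group* questions: how divergent are genotypes across the
genome, do variants segregate by compartment, where does a putative
recombinant switch parents, which genome regions fold.  seqscan makes the
grouping a first-class part of the data (four independent tag sets of up to
26 groups each, carried in a TSV sidecar next to any standard alignment
format) and provides the analytical methods on top of it:

* **Distances** — p, Jukes–Cantor, Kimura 2-parameter, Tajima–Nei with
  standard errors; Nei–Gojobori and Li–Pamilo–Bianchi synonymous /
  non-synonymous distances; amino-acid p, Kimura and similarity-matrix
  distances; sliding-window divergence scans within/between groups; motif
  scans and similarity dot-plots with transition scoring and frame-aware
  translated comparison.
* **Composition** — mono/dinucleotide frequencies and odds ratios
  (stratified by codon position, optionally corrected for the encoded
  protein via an exact expectation), RSCU, Wright's effective codon number
  (ENc), and signed base-usage bias at synonymous positions.
* **Sequence changes** — consensus or Fitch-parsimony ancestors and
  directed, context-stratified substitution spectra with opportunity
  counts (e.g. CpG-conditioned C→T rates).
* **Segregation & recombination** — association index
  `A = Σ (1 − g_max/t)/2^(t−1)` with a permutation null, grouping scores
  `G_a ∝ Σ 2^(−N)` normalised across groups, sliding-window GroupingScan
  and bootscan, and tree-order scans with Robinson–Foulds
  phylogeny-violation matrices at a bootstrap support threshold.
* **RNA structure** — a deterministic weighted maximum-pairing folding
  engine (external thermodynamic folders attach via a simple contract),
  MFED and Z statistics against constrained shuffles, cross-sequence
  pairing conservation (StructureDist) and covariant-duplex scans.
* **Randomisation** — exact dinucleotide-preserving (Euler-path) shuffles,
  codon-order and synonymous-codon scrambles with machine-checked
  invariant certificates, and a parameterised mutation engine with
  transition:transversion and neighbour-context control.
* **Synthetic fixtures** — seeded generators (grouped alignments,
  recombinants, hairpin inserts, context-biased mutant sets) that return
  ground-truth manifests, used throughout the test suite.

## Worked example

Simulate a two-group alignment, splice a recombinant at column 410, and ask
the scans where the query switches parents:

```r
library(seqscan)

fx  <- make_grouped_alignment(group_sizes = c(8, 8), length = 800,
                              inter_divergence = 0.3,
                              intra_divergence = 0.02, seed = 11)
rec <- make_recombinant(fx$aln, left_group = 1, right_group = 2,
                        breakpoint = 410, seed = 12)
rec$aln
#> tagged_alignment: 17 nucleotide sequence(s) x 800 column(s)
#>   tag set 1: 16 tagged row(s) in 2 group(s)

association_index(fx$aln, tag_set = 1, replicates = 5,
                  null_randomizations = 50, seed = 13)
#> A = 1.52588e-05, null 0.612265 +/- 0.2481 (5 perms) => AI = 2.492e-05

prof <- bootscan(rec$aln, query = "query", tag_set = 1,
                 window = 200, step = 50, replicates = 20, seed = 14)
head(as.data.frame(prof), 4)
#>   midpoint series  metric value
#> 1    100.5 group1 support    90
#> 2    150.5 group1 support    80
#> 3    100.5 group2 support     0
#> 4    150.5 group2 support     0
scan_crossover(prof, "group1", "group2")
#> [1] 400.5
```

The association index of ~2.5e-05 says group labels and tree are almost
perfectly segregated (1 = no association between phylogeny and grouping).
The bootscan supports stay with group 1 on the left of the genome and flip
to group 2 on the right; the estimated crossover 400.5 sits one fifth of a
window step from the true breakpoint 410.

RNA-structure scanning on a planted hairpin:

```r
hp <- embed_hairpin(paste(sample(c("A","C","G","T"), 100, TRUE),
                          collapse = ""), stem_len = 20, loop_len = 4,
                    seed = 15)
mfed(hp$seq, n_controls = 50, seed = 16)
#> MFE native -139 vs controls -128.2 +/- 2 (n=50, dinucleotide)
#>   MFED -10.8 (8.42%), z = -5.4
```

z = −5.4 places the native fold far below its dinucleotide-preserving
shuffles: sequence-order-dependent structure, as planted.

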