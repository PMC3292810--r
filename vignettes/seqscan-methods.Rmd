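---
title: "seqscan methods: grouped-alignment scanning for diversity, recombination and RNA structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqscan methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqscan)
```

# The grouped-alignment model

Everything in seqscan operates on a `tagged_alignment`: a gapped residue
matrix together with four independent *tag sets*, each assigning every row to
one of 26 groups (0 = unassigned).  The tag sets are independent
classification axes — e.g. genotype, host species, isolation year, and
anatomical compartment of the same virus alignment — and every analytical
method that compares groups takes a `tag_set` argument naming the axis to
use.  Tags travel with the alignment through a plain TSV sidecar
(`<file>.tags`) so that any FASTA/PHYLIP/NEXUS/CLUSTAL file round-trips with
its group structure intact.

Coordinates are 1-based and inclusive everywhere, matching both R indexing
idiom and the way biologists quote alignment positions.  Gap-only columns are
never auto-stripped: scans are coordinate-addressed, so removing columns
would silently shift every window midpoint.  `U` is normalised to `T` on
input and the original convention restored per record on output.

# Evolutionary distances

Pairwise nucleotide distances (`nt_distance`) implement the uncorrected *p*
distance, Jukes–Cantor, Kimura two-parameter and Tajima–Nei models with
delta-method standard errors.  All models use *pairwise deletion*: a site is
compared only when both sequences carry an unambiguous base there.  This is
deliberate — sliding-window scans repeatedly compare short stretches, and
complete deletion would let a single gappy sequence blank entire windows.

When the argument of a model's logarithm is non-positive (saturation), the
result is *flagged*, never thrown: a scan across a fast-evolving region
should keep going and simply omit the point.  The Tajima–Nei model uses the
full correction term built from base frequencies and the table of mismatch
pair frequencies; it is the most sensitive to compositional skew and
saturates earliest on extreme inputs.

Codon-level distances follow Nei–Gojobori (1986): synonymous site counts per
codon are the expected fraction of single-base changes that preserve the
amino acid (changes creating stop codons count as non-synonymous), and
observed differences are averaged over all minimal-change pathways between
the two codons with equal weight.  Site counts therefore satisfy
S + N = 3 × (compared codons) exactly, which the test suite asserts.  The
Li–Pamilo–Bianchi alternative classifies positions into 0-, 2- and 4-fold
degenerate classes (each sequence contributing half a site, so a position
whose class differs between the two codons is split between classes) and
applies Kimura-type transition/transversion corrections per class.  Its
standard error is reported as `NA`: the class-covariance terms needed for a
faithful variance are out of scope here, and an approximate formula would be
worse than an honest missing value.

For amino acids, alongside *p* and the Kimura correction
(d = −ln(1 − p − 0.2 p²)), a similarity-matrix distance is provided:

d = 1 − (S_obs − S_exp) / (S_max − S_exp)

with S_obs the mean matrix score of aligned residue pairs, S_max the mean
self-score, and S_exp the expected score under the pooled residue
frequencies of the two sequences.  Identical sequences score 0; a pair no
more similar than frequency-matched noise scores 1.  PAM250 is the default
matrix; any matrix with residue dimnames can be supplied.

# Composition statistics

`dinuc_frequencies` reports each dinucleotide's frequency and its odds ratio
against the product of mononucleotide frequencies — the classic statistic in
which vertebrate CpG suppression appears as a ratio well below 1.  For
coding sequences the strata `1-2`, `2-3` and `3-1` (bridging the codon
junction) are reported separately, since the reading frame concentrates
compositional signals at specific codon positions.

The amino-acid–corrected expectation (`dinuc_expected_aa_corrected`) asks a
sharper question: *given the encoded protein*, what dinucleotide content
would we expect?  Each codon is notionally replaced by a synonymous codon
drawn with probability proportional to the sequence's own codon-position
base composition, and the expected dinucleotide counts are accumulated.
Because the expectation factorises over adjacent position pairs
(within-codon pairs couple only through one codon's distribution, junction
pairs are independent across codons), it is computed **exactly** in closed
form for any sequence length; a Monte-Carlo mode is retained and serves as
an independent cross-check in the tests.  A ratio of observed over this
expectation close to 1 means the protein alone explains the dinucleotide
content; persistent deviations (e.g. CpG below expectation even after the
correction) indicate selection on the nucleotide sequence itself.

Codon usage is summarised by RSCU (observed codon count over the
uniform-usage expectation within its synonymous family) and Wright's
effective codon number,

ENc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆,

with the per-family homozygosity F = (nΣp² − 1)/(n − 1), families with fewer
than two observations excluded, Wright's fallback F₃ = (F̄₂ + F̄₄)/2 when the
single 3-fold family is unobserved, and clamping to [20, 61].  ENc = 20 at
maximal bias (one codon per amino acid) and approaches 61 under uniform
synonymous usage.

The "Variance"/"Bias" statistics quantify base preference at synonymous
third positions: per degenerate family, the deviation of each base's
observed third-position share from its uniform-usage share, combined across
families with weights proportional to family codon counts.  `bias` sums
signed deviations (the four base values cancel to zero by construction);
`variance` sums squared deviations, a total scatter measure.  The exact
formulas behind these headings are not published, so this definition is the
package's pinned contract, fixed by the unit tests.

# Ancestral reconstruction and substitution spectra

Substitution patterns are read off comparisons of each sequence with its
immediate ancestor.  Two ancestor models are provided.  The *consensus*
model (strict majority per column; ties become IUPAC ambiguity codes, which
subsequent comparisons skip) assumes no tree structure and is appropriate
for dense, star-like samples.  The *parsimony* model reconstructs ancestors
by two-pass Fitch parsimony on a supplied or NJ-inferred tree, with ties
broken deterministically in the fixed order A < C < G < T, and scores
changes on every edge.  The implied change count equals the Fitch parsimony
score exactly — a property the tests verify against exhaustive enumeration
of all internal labelings on small instances.

The flanking context of every change is read from the *ancestral* sequence:
mutation context is the pre-mutation state, which is what a
methylation-driven CpG→TpG process sees.  Alongside the change counts, the
spectrum records the ancestral opportunity counts per (base, upstream,
downstream) stratum, so conditional rates such as "C→T when followed by G"
are directly computable (`context_rate`) without re-deriving denominators.

# Phylogenetic segregation and recombination scans

All tree-based methods build neighbor-joining trees from the module's own
distance matrices (negative branch lengths clamped to zero) and assess
robustness by bootstrap: *site* resampling draws alignment columns with
replacement; *sequence* (population) resampling draws ⌊2y/3⌋ members per
group without replacement, always retaining the query.  NJ on matrices with
tied entries is agglomeration-order dependent; seqscan keeps the input row
order deterministic so identical calls give identical trees, but users
should be aware that duplicate sequences can attach in tie-dependent ways.

**Association index.**  For each internal node of the (midpoint-rooted) tree
with t tagged leaves below it and g_max of them in the most abundant group,
the dispersion is (1 − g_max/t)/2^(t−1); the association value A sums this
over all internal nodes, so deep, well-mixed nodes dominate and pure clades
contribute nothing.  AI is A for the native labels divided by the mean A
over label permutations; values near 0 indicate strong phylogeny–group
segregation and values near 1 indicate none.  The 2^(t−1) denominator
underflows harmlessly to zero for very large mixed clades.

**Grouping score.**  For a query leaf and each group a, the raw score sums
2^(−N) over group members, where N counts the internal nodes on the
query-to-member path (both end attachment nodes included; on the worked tree
`((Q,(A1,A2)),(B1,B2))` the raw scores are 0.5 and 0.25).  The published
formula alone does not sum to one across groups, so the normalised score
G_a = raw_a / Σ_b raw_b is reported, making the stated sum-to-one identity
explicit.  G is averaged over bootstrap replicate trees, midpoint-rooted for
a consistent node count.

**Bootscan.**  Per window, the percentage of bootstrap replicates in which
the query lies in a clade containing only members of group g.  The clade
must contain a non-empty *proper* subset of the group: with exactly two
groups, a query attached on the edge between two complete group clades
would otherwise count for both groups at once, and the proper-subset rule
makes such uninformative placements score zero instead.

**Breakpoint localisation.**  `scan_crossover` estimates the recombination
breakpoint as the point where the two leading series exchange rank, by
linear interpolation between adjacent window midpoints; when the sign change
spans a run of tied windows (the 0/0 dead zone bootscan produces while the
query sits between parental clades), the bracket midpoint is used, because
support magnitudes are not distances.

**Tree-order scan.**  Per window, the NJ tree is annotated with bootstrap
support and ladderized deterministically (larger clade first, ties by the
smallest contained alignment row), giving each sequence a y-position; stacked
across windows this visualises where group blocks dissolve or reorder.  The
compatibility matrix counts, for every window pair, supported-clade
*violations*: bipartitions of one tree with support at or above the
threshold that cannot coexist with some supported bipartition of the other.
With the threshold disabled, the same machinery yields the plain
Robinson–Foulds symmetric difference, tested against brute-force bipartition
comparison and an independent implementation.

# RNA secondary structure

The builtin folding engine is a weighted maximum-pairing dynamic programme
(Nussinov-style): nested pairs only, at least three unpaired bases inside
every pair, weights GC = 3, AU = 2, GU = 1, energy = −(total weight).
Traceback is deterministic (the leftmost base of each interval pairs with
the smallest admissible partner achieving the optimum).  The engine is
exhaustively optimal — tested against full enumeration of nested structures
for every input up to length 16 — and completely reproducible offline, which
is what the scanning statistics need.  It is *not* a thermodynamic model: it
has no stacking energies or loop penalties, and random sequences fold to
near their composition bound.  Consequently MFED contrasts are weaker than
with a thermodynamic folder, and the synthetic hairpin generator defaults to
a 20 bp GC-biased stem so the planted signal is unambiguous (z < −2)
under this engine.  Thermodynamic engines attach through a one-line external
contract — a command template receiving a FASTA path and printing
`ENERGY <float>` and `PAIR <i> <j>` lines — and everything downstream
(MFED, scans, StructureDist) is engine-agnostic.

MFED compares the native minimum folding energy with scrambled controls:
`mfed = mfe_native − mean(controls)` and z = mfed/sd(controls).  Negative z
means more predicted structure than the controls.  The default control
algorithm is the **exact dinucleotide-preserving shuffle** (Euler-path
doublet method), because folding energies are strongly dinucleotide
dependent and a mononucleotide shuffle would overstate structure.  A
homopolymer yields identical controls; the z score is then flagged rather
than reported as ±Inf.

`structure_dist` folds every selected sequence on its degapped coordinates,
maps pairs back to alignment columns, and aggregates: per column pair, the
number of sequences predicting the pair over the number in which both
columns are foldable (ungapped).  Covariant support — different sequences
realising the same alignment-coordinate pair with different complementary
bases — is exactly what this detects.  `covariance_scan` approaches the same
question without folding: a column pair is covariant when at least
`min_covariants` distinct complementary combinations occur, both columns
vary, and non-complementary combinations stay within a tolerance (default
0.1); covariant seeds are extended in both directions while flanks pair in
≥ 90% of sequences, and duplexes of at least `min_duplex` pairs are
reported.  These thresholds are package contracts pinned by tests, not
published values.

# Constrained randomisation and mutation

Each `scramble` algorithm declares what it preserves, and `check_scramble`
verifies the declaration after the fact: uniform permutation (mononucleotide
counts), the Euler-path doublet shuffle (*exact* dinucleotide counts — the
walk consumes every doublet edge exactly once, with a random last-exit
arborescence for uniformity), codon-order permutation (codon multiset),
synonymous re-encoding (the protein), and the combined codon-order +
dinucleotide algorithm, which accepts a codon permutation only when every
dinucleotide count stays within ±10% of native or ±1 count, whichever is
larger — the pure ±10% band is unsatisfiable for zero- and single-count
dinucleotides under any non-identity permutation.  The band is attached to
each output as its certificate; exceeding the attempt cap is an error, not a
silent fallback.

`mutate_seq` draws per-site Bernoulli hits with probability proportional to
the site's total substitution rate, normalised so the expected substitutions
per site equal the target; transitions and transversions split by the
ts:tv rate ratio, and context multipliers (e.g. C→T ×5 when followed by G)
scale specific substitution types at matching sites.  Bernoulli hits keep
inclusion probabilities exactly proportional to rates, so conditional rate
ratios in the output match the specification — fixed-count weighted sampling
without replacement, the obvious alternative, compresses a 5-fold multiplier
to about 4.2 at realistic densities.  Synonymous/non-synonymous filters are
enforced by rejection against the ancestral codon; unsatisfiable sites are
skipped.

# Synthetic fixtures and what passing tests mean

The generators provide every scanning method with seeded inputs of known
truth: two-level grouped alignments (default shape: three groups of 15, 27
and 25 sequences, 1200 columns, 0.3 inter- and 0.02 intra-group divergence —
a typical multi-genotype virus alignment), recombinants spliced from two
group members at a recorded breakpoint, hairpin inserts with recorded
coordinates, and star-phylogeny mutant sets with context-biased changes
(default: 2000 changes across 20 descendants of a 2000-nt ancestor, C→T ×5
before G).  Each generator returns a manifest echoing all parameters, so
downstream statistics are checked against the generating truth rather than
against re-derived simulation internals.

These fixtures deliberately omit several features of real data: no indels
(so no alignment error), site-independent substitution (no rate
heterogeneity or invariant sites), uniform base composition, and star or
two-level phylogenies rather than realistic coalescent genealogies.
Passing tests therefore demonstrate that the *methods recover what their
models assume*; they do not establish robustness to model violations, which
on real data is the user's question to answer with the bootstrap and
permutation machinery provided.

Problem sizes in the tests and acceptance script — 16-sequence/800-column
recombination scans with 20 bootstrap replicates, 100-nt folding windows
with 50 controls, 1000-case folding and 100-case parsimony oracles — were
chosen as the smallest sizes at which the statistics' expected behaviour is
comfortably distinguishable from noise, and scale linearly upward for real
analyses.

# Numerical and degenerate-input conventions

* Saturated distances flag and return NaN; scans omit the point with a
  notice; NJ refuses to build a tree over a saturated pair, naming it.
* Consensus ties produce IUPAC ambiguity codes; downstream comparisons skip
  non-ACGT states.
* Windows shorter than the folding minimum after degapping are omitted;
  window arithmetic never pads or wraps.
* `2^(t−1)` underflow in the association statistic is harmless (denormals
  flush to a zero contribution).
* All stochastic operations take explicit seeds; CLI outputs carry a
  provenance header with the command line, seed and package version.

# Known limitations

Model-based maximum-likelihood distances, rate heterogeneity, Bayesian
association indices, suboptimal folding ensembles, pseudoknots and indel
simulation are out of scope.  The Li–Pamilo–Bianchi standard error is not
reported.  The builtin folding engine's max-pairing objective limits MFED
contrast relative to thermodynamic folders (attach one through the external
contract when absolute energies matter).  NJ tie-breaking is input-order
dependent, as in any agglomerative implementation; seed and row order pin it
in practice.
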