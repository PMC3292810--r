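test_that("mono- and dinucleotide statistics match hand counts", {
  expect_equal(unname(mono_frequencies("ACGT")), rep(0.25, 4))
  expect_equal(sum(mono_frequencies(rand_nt(100))), 1, tolerance = 1e-9)
  df <- dinuc_frequencies("ACACAC")
  expect_equal(df$frequency[df$dinucleotide == "AC"], 3 / 5)
  expect_equal(df$ratio[df$dinucleotide == "AC"], 0.6 / (0.5 * 0.5))
  expect_equal(sum(df$frequency), 1, tolerance = 1e-9)
  # gaps break adjacency counts: only ungapped residues remain
  df2 <- dinuc_frequencies("AC-AC")
  expect_equal(sum(df2$count), 3L)
})

test_that("codon-position dinucleotide strata partition the counts", {
  s <- rand_coding(40)
  all_c <- dinuc_frequencies(s, "all")$count
  parts <- sapply(c("1-2", "2-3", "3-1"), function(st) {
    dinuc_frequencies(s, st)$count
  })
  expect_equal(rowSums(parts), all_c)
})

test_that("RSCU follows the family-mean definition", {
  counts <- codon_counts(strrep("TTT", 3))              # poly-Phe
  counts["TTC"] <- 1L
  r <- rscu(counts)
  expect_equal(r$rscu[r$codon == "TTT"], 1.5)
  expect_equal(r$rscu[r$codon == "TTC"], 0.5)
  expect_equal(r$rscu[r$codon == "ATG"], NA_real_)      # unobserved family
  counts2 <- setNames(rep(10L, 61), names(codon_counts("ATG")))
  r2 <- rscu(counts2)
  expect_true(all(abs(r2$rscu - 1) < 1e-9))             # uniform usage
  expect_equal(r2$rscu[r2$codon == "ATG"], 1)           # 1-fold family
  # observed-family mean RSCU is 1
  set.seed(15)
  r3 <- rscu(codon_counts(rand_coding(500)))
  fam_means <- tapply(r3$rscu, r3$aa, mean)
  expect_true(all(abs(stats::na.omit(fam_means) - 1) < 1e-9))
})

test_that("effective codon number hits Wright's limits", {
  # one codon per amino acid at large n -> maximal bias, ENc = 20
  fams <- seqscan:::codon_families()
  counts <- setNames(rep(0L, 61), unlist(fams, use.names = FALSE))
  for (f in fams) counts[f[1]] <- 100L
  expect_equal(enc(counts), 20)
  # exactly uniform synonymous usage at 10,000+ codons -> near 61
  counts_u <- setNames(rep(164L, 61), names(counts))    # 10,004 codons
  expect_true(enc(counts_u) >= 59.5 && enc(counts_u) <= 61)
  # family with a single observation is excluded (still defined overall)
  counts_s <- counts; counts_s["TTC"] <- 1L
  expect_true(is.finite(enc(counts_s)))
  expect_true(is.na(enc(setNames(rep(0L, 61), names(counts)))))
})

test_that("synonymous base bias is signed, weighted and sums to zero", {
  # all Phe as TTT: T over-used, C under-used at the synonymous position
  sb <- synonymous_bias(strrep("TTT", 10))
  bias <- setNames(sb$bias, sb$base)
  expect_gt(bias[["T"]], 0)
  expect_lt(bias[["C"]], 0)
  expect_equal(abs(bias[["T"]]), abs(bias[["C"]]), tolerance = 1e-12)
  expect_equal(sum(sb$bias), 0, tolerance = 1e-9)
  set.seed(16)
  sb2 <- synonymous_bias(rand_coding(300))
  expect_equal(sum(sb2$bias), 0, tolerance = 1e-9)
  expect_true(all(sb2$variance >= 0))
  # uniform within-family usage -> zero variance and bias
  fams <- seqscan:::codon_families()
  uni <- paste(rep(unlist(fams, use.names = FALSE), 3), collapse = "")
  sb3 <- synonymous_bias(uni)
  expect_true(all(abs(sb3$bias) < 1e-9))
  expect_true(all(sb3$variance < 1e-9))
})

test_that("amino-acid-corrected dinucleotide expectation honours the protein", {
  # single-codon families: expectation equals observation, all ratios 1
  r <- dinuc_aa_corrected_ratio("ATGTGG")
  expect_true(all(r[is.finite(r)] == 1))
  # poly-Phe: no G reachable anywhere, CpG (and all G-containing) expectation 0
  e <- dinuc_expected_aa_corrected(strrep("TTT", 3))
  expect_equal(unname(e["CG"]), 0)
  expect_true(all(e[grepl("G", names(e))] == 0))
  expect_equal(sum(e), 1, tolerance = 1e-9)
})

test_that("exact expectation agrees with Monte-Carlo estimation", {
  set.seed(17)
  s <- rand_coding(40)
  ex <- dinuc_expected_aa_corrected(s, method = "exact")
  mc <- dinuc_expected_aa_corrected(s, method = "monte_carlo", n_rep = 400L,
                                    seed = 18)
  expect_equal(unname(mc), unname(ex), tolerance = 0.02)
})

test_that("synonymous re-encodings keep aa-corrected ratios near one", {
  set.seed(19)
  s <- rand_coding(2000)  # long enough that every dinucleotide is well counted
  for (k in 1:3) {
    re <- scramble(s, "codon_synonymous")
    ratio <- dinuc_aa_corrected_ratio(re)
    ratio <- ratio[is.finite(ratio)]
    expect_true(all(ratio > 0.8 & ratio < 1.2))
  }
})

test_that("composition report aggregates by scope", {
  s <- rand_coding(50)
  aln <- tagged_alignment(c(a = s, b = s, c = rand_coding(50)))
  aln <- set_tags(aln, 1, c("a", "b"), 1)
  per <- composition_report(aln, "per_sequence")
  grp <- composition_report(aln, "per_group")
  expect_equal(grp[["1"]]$mono, per$a$mono)      # identical members = member value
  expect_equal(grp[["1"]]$enc, per$a$enc)
  whole <- composition_report(aln, "whole_selection")
  expect_equal(sum(whole$whole_selection$mono), 1, tolerance = 1e-9)
  expect_error(composition_report(aln[integer(0), ]), "at least one|empty")
})
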