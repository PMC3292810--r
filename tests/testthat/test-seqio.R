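test_that("round trips preserve ids, residues and order for every format", {
  set.seed(4)
  aln <- tagged_alignment(c(alpha = "ACGT-ACGT", beta = "ACGTTACGT",
                            gamma = "ACGAAACGT"))
  long <- tagged_alignment(setNames(
    replicate(4, rand_nt(150)), c("a", "b", "c", "d")
  ))
  for (aln_x in list(aln, long)) {
    for (fmt in c("fasta", "phylip", "nexus", "clustal")) {
      f <- tempfile()
      write_alignment(aln_x, f, fmt)
      rt <- read_alignment(f)            # format auto-detected
      expect_identical(unname(aln_strings(rt)), unname(aln_strings(aln_x)),
                       info = fmt)
      expect_identical(rt$ids, aln_x$ids, info = fmt)
    }
  }
  # interleaved PHYLIP
  f <- tempfile()
  write_alignment(long, f, "phylip", interleaved = TRUE)
  expect_identical(aln_strings(read_alignment(f, "phylip")), aln_strings(long))
})

test_that("tag assignments survive write/read through the sidecar for all 4 sets", {
  aln <- tagged_alignment(c(a = "ACGT", b = "ACGT", c = "ACGT"))
  aln <- set_tags(aln, 1, "a", 3, label = "grp3")
  aln <- set_tags(aln, 2, c("a", "b"), 1)
  aln <- set_tags(aln, 3, "c", 26)
  aln <- set_tags(aln, 4, "b", 7)
  f <- tempfile()
  write_alignment(aln, f, "fasta")
  rt <- read_alignment(f)
  expect_identical(rt$tags, aln$tags)
  expect_true("grp3" %in% rt$group_meta$label)
  # sidecar line format: tag_set <TAB> id <TAB> group
  expect_true(any(grepl("^1\ta\t3", readLines(paste0(f, ".tags")))))
})

test_that("GenBank flat files import sequence and features", {
  f <- write_genbank_fixture(tempfile())
  aln <- read_alignment(f, "genbank")
  expect_equal(n_seq(aln), 1L)
  expect_identical(unname(aln_strings(aln)), "ATGGCGTACGTTAACCGTAGCGTA")
  feat <- aln$features[[1]][[1]]
  expect_identical(feat$key, "CDS")
  expect_identical(feat$location, "1..24")
  expect_identical(feat$qualifiers$gene, "demo")
})

test_that("EMBL flat files import sequence and features", {
  f <- tempfile()
  writeLines(c(
    "ID   TOY2; SV 1; linear; genomic DNA; STD; VRL; 12 BP.",
    "DE   toy embl record.",
    "FT   CDS             1..12",
    "FT                   /gene=\"x\"",
    "SQ   Sequence 12 BP;",
    "     atggcgtacgtt                                                  12",
    "//"
  ), f)
  aln <- read_alignment(f, "embl")
  expect_identical(unname(aln_strings(aln)), "ATGGCGTACGTT")
  expect_identical(aln$features[[1]][[1]]$key, "CDS")
  expect_identical(aln$features[[1]][[1]]$qualifiers$gene, "x")
})

test_that("unequal-length input is right-padded and flagged", {
  f <- tempfile()
  writeLines(c(">a", "ACGTACGT", ">b", "ACGT"), f)
  aln <- read_alignment(f, "fasta")
  expect_true(aln$padded)
  expect_identical(unname(aln_strings(aln))[2], "ACGT----")
})

test_that("strict PHYLIP truncates long ids with uniqueness repair", {
  aln <- tagged_alignment(c(identifier_one = "ACGT", identifier_two = "ACGT"))
  f <- tempfile()
  w <- capture_warnings(write_alignment(aln, f, "phylip"))
  expect_match(w, "truncat", all = FALSE)
  expect_match(w, "repairing", all = FALSE)
  rt <- read_alignment(f, "phylip")
  expect_equal(n_seq(rt), 2L)
  expect_false(anyDuplicated(rt$ids) > 0)
})

test_that("unreadable or malformed files raise informative errors", {
  expect_error(read_alignment(tempfile()), "no such file")
  f <- tempfile(); writeLines("garbage content", f)
  expect_error(read_alignment(f), "auto-detect.*line 1")
  expect_error(tagged_alignment(c(a = "ACGT", b = "AFGT"),
                                alphabet = "nucleotide"), "invalid nucleotide")
})

test_that("U is normalised to T internally and restored on output", {
  aln <- tagged_alignment(c(rna = "ACGU", dna = "ACGT"))
  expect_identical(unname(aln_strings(aln)), c("ACGT", "ACGT"))
  f <- tempfile()
  write_alignment(aln, f, "fasta", tags = FALSE)
  lines <- readLines(f)
  expect_identical(lines[2], "ACGU")
  expect_identical(lines[4], "ACGT")
})

test_that("translation follows the standard code, gap and frame rules", {
  expect_identical(translate_seq("ATGAAA"), "MK")
  expect_identical(translate_seq("ATGAAA", reverse_complement = TRUE), "FH")
  expect_identical(translate_seq("AT-GAA"), "XE")
  expect_identical(translate_seq("ATGAAAG"), "MK")    # trailing partial dropped
  expect_identical(translate_seq("ATGAAA", frame = 1), "*")  # "TGA" stop, partial dropped
  aln <- tagged_alignment(c(a = "ATGAAA", b = "ATGTTT"))
  tr <- translate_alignment(aln)
  expect_identical(unname(aln_strings(tr)), c("MK", "MF"))
  expect_identical(tr$alphabet, "amino_acid")
  expect_error(translate_alignment(tr), "nucleotide")
})

test_that("double reverse complement leaves translation invariant", {
  set.seed(11)
  for (k in 1:20) {
    s <- rand_nt(60)
    expect_identical(translate_seq(reverse_complement(reverse_complement(s))),
                     translate_seq(s))
  }
})

test_that("selections are validated and subsetting keeps tags in step", {
  aln <- tagged_alignment(c(a = "ACGTAC", b = "ACCTAC", c = "AGGTAC"))
  aln <- set_tags(aln, 1, c("a", "c"), 2)
  sub <- aln[c("c", "a"), 2:4]
  expect_identical(sub$ids, c("c", "a"))
  expect_identical(unname(aln_strings(sub)), c("GGT", "CGT"))
  expect_identical(unname(sub$tags[, 1]), c(2L, 2L))
  expect_error(aln[, 0:3], "out of range")
  expect_error(aln["zz", ], "unknown sequence id")
  expect_error(set_tags(aln, 5, "a", 1), "tag_set")
  expect_error(set_tags(aln, 1, "a", 27), "group")
})
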