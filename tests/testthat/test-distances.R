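test_that("closed-form distances match independent formula evaluation", {
  a <- strrep("A", 100)
  b_jc <- paste0(strrep("G", 10), strrep("A", 90))             # p = 0.1
  r <- nt_distance(a, b_jc, "jukes_cantor")
  expect_equal(r$value, -0.75 * log(1 - 4 * 0.1 / 3), tolerance = 1e-9)
  expect_lt(abs(r$value - 0.107326), 1e-6)
  b_k2p <- paste0(strrep("G", 10), strrep("C", 5), strrep("A", 85))  # P=.1 Q=.05
  r <- nt_distance(a, b_k2p, "kimura2p")
  expect_equal(r$value, -0.5 * log(1 - 0.25) - 0.25 * log(1 - 0.1), tolerance = 1e-9)
  expect_lt(abs(r$value - 0.170181), 1e-6)
  aa <- strrep("L", 100); bb <- paste0(strrep("V", 20), strrep("L", 80))  # p=0.2
  r <- aa_distance(aa, bb, "kimura")
  expect_equal(r$value, -log(1 - 0.2 - 0.2 * 0.04), tolerance = 1e-9)
  expect_lt(abs(r$value - 0.233194), 1e-6)
})

test_that("identical sequences give zero distance with zero SE in every model", {
  s <- rand_nt(120)
  for (m in c("p", "jukes_cantor", "kimura2p", "tajima_nei")) {
    r <- nt_distance(s, s, m)
    expect_equal(r$value, 0)
    expect_equal(r$std_error, 0)
    expect_equal(r$sites_used, 120L)
  }
  p <- translate_seq(rand_coding(40))
  for (m in c("p", "kimura")) expect_equal(aa_distance(p, p, m)$value, 0)
})

test_that("saturation flags instead of erroring", {
  a <- strrep("A", 20); b <- strrep("G", 20)    # p = 1
  r <- nt_distance(a, b, "jukes_cantor")
  expect_identical(r$flag, "saturated")
  expect_true(is.nan(r$value))
  r2 <- aa_distance(strrep("L", 20), strrep("V", 20), "kimura")  # p = 1 > 0.85
  expect_identical(r2$flag, "saturated")
})

test_that("JC and K2P agree with ape::dist.dna on gap-free data", {
  set.seed(7)
  for (k in 1:10) {
    a <- rand_nt(300)
    b <- mutate_seq(a, 0.15)
    bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(c(a, b)), ""), identity)))
    expect_equal(nt_distance(a, b, "jukes_cantor")$value,
                 as.numeric(ape::dist.dna(bin, "JC69")), tolerance = 1e-12)
    expect_equal(nt_distance(a, b, "kimura2p")$value,
                 as.numeric(ape::dist.dna(bin, "K80")), tolerance = 1e-12)
  }
})

test_that("distances are symmetric and correction models dominate p", {
  set.seed(8)
  for (k in 1:15) {
    a <- rand_nt(200); b <- mutate_seq(a, runif(1, 0.02, 0.4))
    for (m in c("p", "jukes_cantor", "kimura2p", "tajima_nei")) {
      expect_identical(nt_distance(a, b, m)$value, nt_distance(b, a, m)$value)
    }
    p <- nt_distance(a, b, "p")$value
    jc <- nt_distance(a, b, "jukes_cantor")$value
    k2p <- nt_distance(a, b, "kimura2p")$value
    if (is.finite(jc) && is.finite(k2p)) {
      expect_true(k2p >= jc - 1e-12 && jc >= p - 1e-12)
    }
  }
})

test_that("corrections converge to p as divergence vanishes", {
  set.seed(6)
  a <- rand_nt(10000)
  b <- mutate_seq(a, 0.01, seed = 6)
  p <- nt_distance(a, b, "p")$value
  for (m in c("jukes_cantor", "kimura2p", "tajima_nei")) {
    d <- nt_distance(a, b, m)$value
    expect_lt(abs(d - p) / p, 0.01)
  }
})

test_that("pairwise deletion excludes gapped and ambiguous sites", {
  r <- nt_distance("ACGT-RAC", "ACGTTAAC")
  expect_equal(r$sites_used, 6L)       # gap and R columns dropped
  expect_equal(r$value, 0)
})

test_that("NG86 codon distances match single-codon hand calculations", {
  same <- rand_coding(30)
  r0 <- codon_distance(same, same)
  expect_equal(r0$syn$value, 0); expect_equal(r0$nonsyn$value, 0)
  # TTT vs TTC: synonymous single difference; S(TTT)=S(TTC)=1/3
  r <- codon_distance("TTT", "TTC")
  expect_equal(r$syn$value, 1 / (1 / 3), tolerance = 1e-12)
  expect_equal(r$nonsyn$value, 0)
  # TTT vs CTT: Phe->Leu, non-synonymous; N = 3 - (1/3 + 1)/2 = 7/3
  r <- codon_distance("TTT", "CTT")
  expect_equal(r$syn$value, 0)
  expect_equal(r$nonsyn$value, 1 / (7 / 3), tolerance = 1e-12)
})

test_that("NG86 site counts satisfy S + N = 3 x compared codons", {
  set.seed(9)
  for (k in 1:5) {
    a <- rand_coding(25); b <- rand_coding(25)
    cp <- seqscan:::clean_codon_pairs(a, b)
    S <- sum(vapply(cp$a, seqscan:::ng86_sites, numeric(1)) +
               vapply(cp$b, seqscan:::ng86_sites, numeric(1))) / 2
    N <- 3 * length(cp$a) - S
    expect_equal(S + N, 3 * length(cp$a), tolerance = 1e-9)
  }
})

test_that("Li-Pamilo-Bianchi distances behave sensibly", {
  s <- rand_coding(60)
  r <- codon_distance(s, s, "li_pb")
  expect_equal(r$syn$value, 0); expect_equal(r$nonsyn$value, 0)
  m <- mutate_seq(s, 0.05, seed = 2)
  r1 <- codon_distance(s, m, "li_pb"); r2 <- codon_distance(m, s, "li_pb")
  expect_equal(r1$syn$value, r2$syn$value)
  expect_equal(r1$nonsyn$value, r2$nonsyn$value)
  expect_true(r1$syn$value >= 0 && r1$nonsyn$value >= 0)
})

test_that("matrix-normalised amino-acid distance is 0 for identical proteins", {
  p <- translate_seq(rand_coding(50))
  expect_equal(aa_distance(p, p, "matrix")$value, 0, tolerance = 1e-12)
  q <- translate_seq(mutate_seq(rand_coding(50), 0.3, seed = 3))
  d <- aa_distance(p, q, "matrix")$value
  expect_true(d > 0)
})

test_that("dist_matrix fast path equals nt_distance on every pair", {
  set.seed(10)
  aln <- tagged_alignment(setNames(
    c(rand_nt(150), replicate(4, mutate_seq(rand_nt(150), 0.1))), letters[1:5]
  ))
  for (m in c("p", "jukes_cantor", "kimura2p")) {
    d <- dist_matrix(aln, m)
    for (i in 1:4) for (j in (i + 1):5) {
      expect_equal(d[i, j], nt_distance(aln$mat[i, ], aln$mat[j, ], m)$value,
                   tolerance = 1e-12)
    }
  }
})
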