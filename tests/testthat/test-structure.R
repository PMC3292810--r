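test_that("builtin folding matches hand-worked cases and pair weights", {
  expect_error(fold_mfe("AAAA"), "min_loop")     # too short to fold at all
  f0 <- fold_mfe("AAAAAA")
  expect_equal(f0$energy, 0)                     # no complementary pair
  expect_equal(nrow(f0$pairs), 0L)
  f <- fold_mfe("GGGAAAACCC")
  expect_equal(f$energy, -9)                     # three G-C pairs at weight 3
  expect_equal(nrow(f$pairs), 3L)
  expect_identical(fold_mfe("GGGAAAACCC")$pairs, f$pairs)  # deterministic
})

test_that("builtin engine equals exhaustive enumeration on short sequences", {
  set.seed(47)
  for (k in 1:150) {
    n <- sample(6:14, 1)
    chars <- sample(c("A", "C", "G", "T"), n, TRUE)
    f <- fold_mfe(paste(chars, collapse = ""))
    expect_equal(-f$energy, enum_fold_weight(chars), info = paste(chars, collapse = ""))
  }
})

test_that("predicted structures are nested with the loop constraint", {
  set.seed(48)
  for (k in 1:30) {
    s <- rand_nt(40)
    f <- fold_mfe(s)
    p <- f$pairs
    if (!nrow(p)) next
    expect_true(all(p[, 2] - p[, 1] > 3))                  # min_loop
    expect_false(anyDuplicated(as.vector(p)) > 0)          # <= 1 pair/position
    if (nrow(p) > 1) {
      for (i in 1:(nrow(p) - 1)) for (j in (i + 1):nrow(p)) {
        a <- p[i, ]; b <- p[j, ]
        nested <- (b[1] > a[1] & b[2] < a[2]) | (a[1] > b[1] & a[2] < b[2]) |
          (b[1] > a[2]) | (a[1] > b[2])
        expect_true(nested)
      }
    }
    db <- dot_bracket(f, nchar(s))
    expect_equal(nchar(db), nchar(s))
  }
})

test_that("the external engine contract parses ENERGY/PAIR output", {
  fake <- tempfile(fileext = ".sh")
  writeLines(c("#!/bin/sh", "echo 'ENERGY -4.25'", "echo 'PAIR 1 10'",
               "echo 'PAIR 2 9'"), fake)
  Sys.chmod(fake, "0755")
  f <- fold_mfe("GGGAAAACCC", engine = "external",
                external_cmd = paste(fake, "%s"))
  expect_equal(f$energy, -4.25)
  expect_equal(nrow(f$pairs), 2L)
  expect_identical(f$engine_id, "external")
  expect_error(fold_mfe("GGGAAAACCC", engine = "external"), "builtin")
})

test_that("MFED flags degenerate controls and centres on null data", {
  m <- suppressWarnings(mfed(strrep("A", 40), n_controls = 12L, seed = 49))
  expect_equal(m$mfed, 0)
  expect_identical(m$z_flag, "sd_zero")
  expect_warning(mfed(rand_nt(40), n_controls = 5L, seed = 50), "10 controls")
  set.seed(51)
  zs <- vapply(1:12, function(k) {
    mfed(rand_nt(80), n_controls = 30L, seed = 500 + k)$z
  }, numeric(1))
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.6)
})

test_that("a planted hairpin yields strong negative z and scan localisation", {
  set.seed(52)
  hp <- embed_hairpin(rand_nt(100), stem_len = 20L, loop_len = 4L, seed = 53)
  m <- mfed(hp$seq, n_controls = 50L, seed = 54)
  expect_lt(m$z, -2)
  # scan: |z| largest in the window overlapping the insert
  set.seed(55)
  bg <- rand_nt(240)
  hp2 <- embed_hairpin(bg, position = 120L, stem_len = 20L, loop_len = 4L,
                       seed = 56)
  prof <- mfed_scan(hp2$seq, window = 80L, step = 40L, n_controls = 30L,
                    seed = 57)
  z <- prof[prof$metric == "z", ]
  best <- z$midpoint[which.min(z$value)]
  expect_lte(abs(best - 142), 80)      # insert spans columns 121-164
})

test_that("mfed_scan handles group means and degenerate windows", {
  s <- rand_nt(60)
  aln <- tagged_alignment(c(a = s, b = s))
  aln <- set_tags(aln, 1, c("a", "b"), 1)
  p1 <- mfed_scan(aln, window = 60L, step = 60L, n_controls = 15L, seed = 58)
  p2 <- mfed_scan(aln, window = 60L, step = 60L, n_controls = 15L, seed = 58,
                  by_group = TRUE)
  expect_equal(p2$value[p2$metric == "mfed"],
               mean(p1$value[p1$metric == "mfed"]), tolerance = 1e-9)
  # step beyond length -> a single window
  p3 <- mfed_scan(s, window = 100L, step = 200L, n_controls = 12L, seed = 59)
  expect_equal(length(unique(p3$midpoint)), 1L)
})

test_that("structure conservation is total for identical or covariant inputs", {
  al <- tagged_alignment(c(a = "GGGGAAAACCCC", b = "GGGGAAAACCCC"))
  sd1 <- structure_dist(al)
  expect_true(all(sd1$entries$frequency == 1))
  # covariant hairpin: G:C stem vs C:G stem at the same alignment coordinates
  al2 <- tagged_alignment(c(a = "GGGGAAAACCCC", b = "CCCCAAAAGGGG"))
  sd2 <- structure_dist(al2)
  expect_true(all(sd2$entries$frequency == 1))
  expect_true(all(sd2$entries$col_j - sd2$entries$col_i > 3))
  # frequencies always within [0, 1]
  set.seed(60)
  al3 <- tagged_alignment(setNames(replicate(4, rand_nt(50)), paste0("r", 1:4)))
  sd3 <- structure_dist(al3)
  expect_true(all(sd3$entries$frequency >= 0 & sd3$entries$frequency <= 1))
  expect_true(mean(sd3$entries$frequency) < 1)
})

test_that("covariance scan finds planted covariant helices, not scrambled ones", {
  set.seed(62)
  pre <- rand_nt(4); loop <- rand_nt(8); post <- rand_nt(4)
  mk <- function(p5) paste0(pre, p5, loop, reverse_complement(p5), post)
  helix5 <- c("GAGCAC", "GAGAAC", "GAGTAC", "GAGCAC")
  al <- tagged_alignment(setNames(vapply(helix5, mk, character(1)), paste0("s", 1:4)))
  cv <- covariance_scan(al, min_covariants = 2L, min_duplex = 4L)
  expect_gt(nrow(cv), 0L)
  expect_true(any(cv$covariant & cv$col_i == 8 & cv$col_j == 21))
  expect_gte(max(table(cv$duplex)), 4L)
  # identical sequences: no variability, no covariant site
  al_same <- tagged_alignment(setNames(rep(mk("GAGCAC"), 3), paste0("t", 1:3)))
  cv_same <- covariance_scan(al_same, min_covariants = 2L, min_duplex = 4L)
  expect_true(!any(cv_same$covariant))
  # column-scrambled control loses the duplex
  set.seed(61)
  perm <- sample(aln_length(al))
  al_scr <- al[, perm]
  cv_scr <- covariance_scan(al_scr, min_covariants = 2L, min_duplex = 4L)
  expect_equal(nrow(cv_scr), 0L)
})
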