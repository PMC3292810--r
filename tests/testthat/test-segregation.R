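test_that("association statistic matches node-walk hand calculations", {
  # single cherry holding one member of each group
  tr2 <- ape::read.tree(text = "(a,b);")
  expect_equal(association_statistic(tr2, c(a = 1, b = 2)), 0.25)
  # two clades of 4+4, perfectly segregated: only the root mixes
  tr8 <- ape::read.tree(text = "(((A1,A2),(A3,A4)),((B1,B2),(B3,B4)));")
  g8 <- setNames(rep(1:2, each = 4), c(paste0("A", 1:4), paste0("B", 1:4)))
  expect_equal(association_statistic(tr8, g8), 0.00390625)
  # permuting labels on the segregated tree increases A
  set.seed(25)
  worse <- replicate(20, association_statistic(tr8, setNames(sample(g8), names(g8))))
  expect_true(mean(worse > 0.00390625) >= 0.95)
})

test_that("mean AI over label randomisations is one", {
  set.seed(26)
  tree <- ape::rtree(20)
  g <- setNames(rep(1:2, each = 10), tree$tip.label)
  nulls <- replicate(200, association_statistic(tree, setNames(sample(g), names(g))))
  natives <- replicate(200, association_statistic(tree, setNames(sample(g), names(g))))
  expect_equal(mean(natives) / mean(nulls), 1, tolerance = 0.1)
})

test_that("association index pipeline separates segregated from random labels", {
  aln <- make_two_group_aln(6L, 400L, seed = 27)
  res <- association_index(aln, replicates = 5L, null_randomizations = 40L, seed = 28)
  expect_lt(res$AI, 0.2)
  expect_gt(res$A_null_mean, res$A_native)
  shuffled <- aln
  shuffled$tags[, 1] <- sample(shuffled$tags[, 1])
  res2 <- association_index(shuffled, replicates = 5L, null_randomizations = 40L,
                            seed = 29)
  expect_gt(res2$AI, res$AI)
  expect_error(association_index(aln[1:6, ]), "two non-empty groups")
})

test_that("grouping score matches the worked path-count example and sums to 1", {
  tr <- ape::read.tree(text = "((Q,(A1,A2)),(B1,B2));")
  g <- setNames(c(1, 1, 2, 2), c("A1", "A2", "B1", "B2"))
  gs <- grouping_score(tr, g, "Q")
  expect_equal(unname(gs$raw), c(0.5, 0.25))
  expect_equal(unname(gs$G), c(2 / 3, 1 / 3))
  expect_equal(sum(gs$G), 1, tolerance = 1e-9)
  # query embedded in one group's clade scores highest for that group
  set.seed(30)
  for (k in 1:10) {
    tree <- ape::rtree(9)
    g9 <- setNames(rep(1:2, c(4, 4)), setdiff(tree$tip.label, "t9"))
    gsk <- grouping_score(tree, g9, "t9")
    expect_equal(sum(gsk$G), 1, tolerance = 1e-9)
  }
})

test_that("neighbor-joining recovers additive topologies deterministically", {
  aln3 <- tagged_alignment(c(a = "ACGT", b = "ACGA", c = "AGGT"))
  expect_s3_class(nj_tree(aln3), "phylo")
  # additive 4-taxon matrix: ((a,b),(c,d)) with internal edge
  d <- matrix(c(0, 2, 7, 7,  2, 0, 7, 7,  7, 7, 0, 2,  7, 7, 2, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- ape::nj(as.dist(d))
  expect_equal(rf_distance(tr, ape::read.tree(text = "((a,b),(c,d));")), 0L)
  # row permutation leaves the unrooted topology invariant (generic distances:
  # tied entries would make the NJ agglomeration order-dependent)
  fx <- make_grouped_alignment(group_sizes = c(4L, 4L), length = 1000L,
                               inter_divergence = 0.3, intra_divergence = 0.05,
                               seed = 31)
  t1 <- nj_tree(fx$aln)
  set.seed(1)
  t2 <- nj_tree(fx$aln[sample(n_seq(fx$aln)), ])
  expect_equal(rf_distance(t1, t2), 0L)
  expect_true(all(t1$edge.length >= 0))
})

test_that("nj errors on saturated pairs, naming them", {
  aln <- tagged_alignment(c(a = strrep("A", 30), b = strrep("G", 30),
                            c = strrep("C", 30)))
  expect_error(nj_tree(aln, "jukes_cantor"), "saturated.*'a'.*'b'")
})

test_that("bootstrap resampling is seed-reproducible and sized correctly", {
  aln <- make_two_group_aln(6L, 200L, seed = 32)
  b1 <- bootstrap_trees(aln, 3L, "site", seed = 33)
  b2 <- bootstrap_trees(aln, 3L, "site", seed = 33)
  expect_equal(lapply(b1, ape::write.tree), lapply(b2, ape::write.tree))
  expect_equal(length(b1[[1]]$tip.label), n_seq(aln))    # site mode keeps rows
  bs <- bootstrap_trees(aln, 2L, "sequence", tag_set = 1L, seed = 34)
  expect_equal(length(bs[[1]]$tip.label), 2L * floor(2 * 6 / 3))
  small <- aln[c(1, 7:12), ]
  expect_warning(bootstrap_trees(small, 1L, "sequence", tag_set = 1L, seed = 35),
                 "fewer than 2")
})

test_that("RF distance matches worked example, brute force and phangorn", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  set.seed(36)
  for (k in 1:30) {
    ta <- ape::rtree(8); tb <- ape::rtree(8)
    rf <- rf_distance(ta, tb)
    expect_equal(rf, brute_rf(ta, tb))
    expect_equal(rf, as.integer(phangorn::RF.dist(ta, tb)))
    expect_equal(rf, rf_distance(tb, ta))                  # symmetry
    tc <- ape::rtree(8)
    expect_lte(rf_distance(ta, tc), rf + rf_distance(tb, tc))  # triangle
  }
  expect_error(rf_distance(t1, ape::rtree(5)), "leaf sets")
})

test_that("support-thresholded RF counts only supported incompatibilities", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),(E,F));")
  t2 <- ape::read.tree(text = "((A,C),(B,D),(E,F));")
  t1$node.label <- c("", "95", "40", "99")
  t2$node.label <- c("", "97", "20", "99")
  # only the supported AB|... split of t1 conflicts with supported AC|... of t2
  n <- rf_distance(t1, t2, support_threshold = 70)
  expect_equal(n, 1L)
  expect_equal(rf_distance(t1, t2, support_threshold = 100), 0L)
})

test_that("bootscan gives near-total support for a group member query", {
  aln <- make_two_group_aln(5L, 300L, seed = 1)
  # query = copy of a group-1 member, untagged
  q <- unname(aln_strings(aln, 1))
  aln2 <- tagged_alignment(setNames(c(aln_strings(aln), q), c(aln$ids, "query")))
  aln2$tags[seq_len(n_seq(aln)), ] <- aln$tags
  bs <- bootscan(aln2, "query", window = 300L, step = 300L, replicates = 20L,
                 seed = 39)
  g1 <- bs$value[bs$series == "group1"]
  expect_true(all(g1 >= 95))
  # per-window supports across groups sum to at most 100
  sums <- tapply(bs$value, bs$midpoint, sum)
  expect_true(all(sums <= 100 + 1e-9))
})

test_that("grouping and bootscan localise a recombination breakpoint", {
  base <- make_grouped_alignment(group_sizes = c(8L, 8L), length = 800L,
                                 inter_divergence = 0.3,
                                 intra_divergence = 0.02, seed = 40)
  rec <- make_recombinant(base$aln, 1L, 2L, breakpoint = 410L, seed = 41)
  gp <- grouping_scan(rec$aln, "query", window = 200L, step = 50L,
                      replicates = 20L, seed = 42)
  expect_lte(abs(scan_crossover(gp, "group1", "group2") - 410), 50)
  bsc <- bootscan(rec$aln, "query", window = 200L, step = 50L,
                  replicates = 20L, seed = 43)
  expect_lte(abs(scan_crossover(bsc, "group1", "group2") - 410), 50)
  # two windows, step = window -> exactly 2 profile points per group
  gp2 <- grouping_scan(rec$aln, "query", window = 400L, step = 400L,
                       replicates = 5L, seed = 44)
  expect_equal(nrow(gp2), 4L)
})

test_that("treeorder scan keeps clean data compatible and orders deterministically", {
  aln <- make_two_group_aln(5L, 600L, seed = 45)
  res <- treeorder_scan(aln, window = 300L, step = 300L, replicates = 25L,
                        support_threshold = 70, seed = 46)
  expect_true(all(res$compatibility$violations == 0L))
  expect_true(all(res$compatibility$window_i < res$compatibility$window_j))
  # without recombination each group occupies one contiguous y-block, in the
  # same group order, in every window
  for (m in res$midpoints) {
    ord <- res$order_table[res$order_table$midpoint == m, ]
    expect_equal(sort(ord$y), seq_len(n_seq(aln)))
    runs <- rle(ord$group[order(ord$y)])
    expect_equal(sort(runs$values), c(1L, 2L))     # contiguous group blocks
  }
  first_group <- vapply(res$midpoints, function(m) {
    ord <- res$order_table[res$order_table$midpoint == m, ]
    ord$group[which.min(ord$y)]
  }, integer(1))
  expect_equal(length(unique(first_group)), 1L)    # group order stable
})
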