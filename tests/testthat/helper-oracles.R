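# Independent brute-force oracles and small fixture builders used across the
# suite.  Each oracle deliberately uses a different algorithmic route than the
# implementation it checks.

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

rand_coding <- function(n_codons) {
  sense <- names(genetic_code())[genetic_code() != "*"]
  paste(sample(sense, n_codons, TRUE), collapse = "")
}

# exhaustive maximum-weight nested pairing by plain recursion on the RIGHT
# end (the engine pairs the leftmost base during traceback), no memoisation:
# visits every nested structure
enum_fold_weight <- function(chars, min_loop = 3L) {
  wt <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) 3L
    else if (key %in% c("AT", "TA")) 2L
    else if (key %in% c("GT", "TG")) 1L
    else 0L
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L)                        # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      w <- wt(chars[k], chars[j])
      if (w == 0L) next
      cand <- w + (if (k > i) rec(i, k - 1L) else 0L) + rec(k + 1L, j - 1L)
      if (cand > best) best <- cand
    }
    best
  }
  rec(1L, length(chars))
}

# bipartitions of a phylo by explicit edge-walk (no prop.part): for each
# internal edge, the tip set below it, canonicalised to the side without the
# alphabetically first tip
brute_splits <- function(tree) {
  n_tip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  below <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], below))
  }
  ref <- sort(tree$tip.label)[1]
  out <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2]
    if (child <= n_tip) next
    side <- below(child)
    other <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (ref %in% side) other else side
    out <- c(out, paste(sort(canon), collapse = "|"))
  }
  unique(out)
}

brute_rf <- function(t1, t2) {
  s1 <- brute_splits(t1); s2 <- brute_splits(t2)
  sum(!s1 %in% s2) + sum(!s2 %in% s1)
}

# exhaustive parsimony: minimum changes over all internal-node labelings
brute_parsimony <- function(tree, tip_states) {
  n_tip <- length(tree$tip.label)
  n_int <- tree$Nnode
  bases <- c("A", "C", "G", "T")
  states <- rep(NA_character_, n_tip + n_int)
  states[seq_len(n_tip)] <- tip_states[tree$tip.label]
  grid <- expand.grid(rep(list(bases), n_int), stringsAsFactors = FALSE)
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    states[(n_tip + 1L):(n_tip + n_int)] <- as.character(grid[r, ])
    chg <- sum(states[tree$edge[, 1]] != states[tree$edge[, 2]])
    if (chg < best) best <- chg
  }
  best
}

# ten-line GenBank flat-file fixture written at test time
write_genbank_fixture <- function(path) {
  writeLines(c(
    "LOCUS       TOY1          24 bp    DNA     linear   VRL 01-JAN-2000",
    "DEFINITION  toy coding record.",
    "FEATURES             Location/Qualifiers",
    "     CDS             1..24",
    "                     /gene=\"demo\"",
    "                     /product=\"demo protein\"",
    "ORIGIN",
    "        1 atggcgtacg ttaaccgtag cgta",
    "//"
  ), path)
  path
}

make_two_group_aln <- function(n_per = 4L, len = 300L, seed = 1L) {
  fx <- make_grouped_alignment(group_sizes = c(n_per, n_per), length = len,
                               inter_divergence = 0.3, intra_divergence = 0.02,
                               seed = seed)
  fx$aln
}
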