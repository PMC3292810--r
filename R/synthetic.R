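# Seeded fixture generators with ground-truth manifests.  Every generator
# returns the data plus a manifest echoing all parameters, so downstream
# statistics can be checked against the generating truth without re-deriving
# the simulation.

random_nt <- function(n, freqs = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  paste(sample(names(freqs), n, replace = TRUE, prob = freqs), collapse = "")
}

#' Simulate a grouped alignment
#'
#' Two-level phylogeny: a root ancestor, per-group ancestors mutated from it
#' (inter-group divergence), and group members mutated from their group
#' ancestor (intra-group divergence).  Tag set 1 records the groups.  The
#' default shape (groups of 15, 27 and 25) mirrors a typical three-genotype
#' virus alignment.
#'
#' @param group_sizes Integer vector (>= 2 groups) of sequences per group.
#' @param length Alignment length (no indels are simulated).
#' @param inter_divergence Expected substitutions/site from root to each
#'   group ancestor.
#' @param intra_divergence Expected substitutions/site from group ancestor to
#'   each member.
#' @param ts_tv_ratio Transition:transversion ratio of the mutation process.
#' @param seed RNG seed.
#' @return List with `aln` (a `tagged_alignment`, ids `g<k>_s<i>`) and
#'   `manifest` (parameters, root and group-ancestor sequences).
#' @export
make_grouped_alignment <- function(group_sizes = c(15L, 27L, 25L),
                                   length = 1200L, inter_divergence = 0.3,
                                   intra_divergence = 0.02, ts_tv_ratio = 2,
                                   seed = NULL) {
  if (base::length(group_sizes) < 2L) stop("need at least two groups")
  if (intra_divergence >= inter_divergence) {
    warning("intra-group divergence >= inter-group divergence: segregation not guaranteed")
  }
  if (!is.null(seed)) set.seed(seed)
  root <- random_nt(length)
  ancestors <- vapply(seq_along(group_sizes), function(g) {
    mutate_seq(root, inter_divergence, ts_tv_ratio)
  }, character(1))
  seqs <- character(0); ids <- character(0); grp <- integer(0)
  for (g in seq_along(group_sizes)) {
    for (i in seq_len(group_sizes[g])) {
      seqs <- c(seqs, mutate_seq(ancestors[g], intra_divergence, ts_tv_ratio))
      ids <- c(ids, sprintf("g%d_s%d", g, i))
      grp <- c(grp, g)
    }
  }
  aln <- tagged_alignment(setNames(seqs, ids))
  for (g in seq_along(group_sizes)) {
    aln <- set_tags(aln, 1L, ids[grp == g], g, label = paste0("group", g))
  }
  list(aln = aln, manifest = list(
    kind = "grouped_alignment", group_sizes = group_sizes, length = length,
    inter_divergence = inter_divergence, intra_divergence = intra_divergence,
    ts_tv_ratio = ts_tv_ratio, seed = seed, root = root,
    group_ancestors = ancestors
  ))
}

#' Construct a recombinant query from two groups
#'
#' Concatenates the first `breakpoint` columns of a (randomly chosen) member
#' of the left group with the remaining columns of a member of the right
#' group.  `breakpoint = 0` yields a pure right-group sequence;
#' `breakpoint = aln_length(aln)` a pure left-group sequence.
#'
#' @param aln A tagged alignment (tag set `tag_set`).
#' @param left_group,right_group Group numbers.
#' @param breakpoint Number of columns inherited from the left parent
#'   (0..alignment length).
#' @param tag_set Tag set of the groups.
#' @param id Id given to the recombinant.
#' @param seed RNG seed (parent choice).
#' @return List with `aln` (input plus the untagged recombinant row),
#'   `record` (the recombinant string) and `manifest` (true breakpoint and
#'   parent ids).
#' @export
make_recombinant <- function(aln, left_group, right_group, breakpoint,
                             tag_set = 1L, id = "query", seed = NULL) {
  L <- aln_length(aln)
  if (breakpoint < 0L || breakpoint > L) stop("breakpoint outside the alignment")
  if (!is.null(seed)) set.seed(seed)
  grp <- get_groups(aln, tag_set)
  pick <- function(g) {
    ids <- names(grp)[grp == g]
    if (!base::length(ids)) stop("group ", g, " is empty")
    ids[sample.int(base::length(ids), 1L)]
  }
  lp <- pick(left_group); rp <- pick(right_group)
  left <- aln_strings(aln, lp)
  right <- aln_strings(aln, rp)
  rec <- paste0(substr(left, 1L, breakpoint), substr(right, breakpoint + 1L, L))
  out <- tagged_alignment(
    setNames(c(aln_strings(aln), rec), c(aln$ids, id)),
    alphabet = aln$alphabet
  )
  out$tags[seq_len(n_seq(aln)), ] <- aln$tags
  out$group_meta <- aln$group_meta
  list(aln = out, record = rec, manifest = list(
    kind = "recombinant", breakpoint = breakpoint, left_group = left_group,
    right_group = right_group, left_parent = lp, right_parent = rp,
    query_id = id, seed = seed
  ))
}

#' Embed a perfect hairpin in a sequence
#'
#' Inserts stem + loop + reverse-complement stem after `position`; the
#' builtin folding engine pairs all `stem_len` stem positions when the
#' insert is folded alone.
#'
#' @param seq Background string.
#' @param position Columns before the insert (0..nchar(seq)).
#' @param stem_len Stem length in base pairs (0 returns the input unchanged).
#' @param loop_len Loop length (>= 3 to satisfy the default minimum loop).
#' @param gc_bias Probability of G/C bases in the stem (stronger stems fold
#'   more distinctively).
#' @param seed RNG seed.
#' @return List with `seq` and `manifest` (insert coordinates, stem string).
#' @export
embed_hairpin <- function(seq, position = NULL, stem_len = 20L, loop_len = 4L,
                          gc_bias = 0.7, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(seq)
  if (is.null(position)) position <- n %/% 2L
  if (stem_len == 0L) {
    return(list(seq = seq, manifest = list(kind = "hairpin", stem_len = 0L)))
  }
  p <- c((1 - gc_bias) / 2, gc_bias / 2, gc_bias / 2, (1 - gc_bias) / 2)
  stem <- random_nt(stem_len, setNames(p, c("A", "C", "G", "T")))
  loop <- random_nt(loop_len)
  insert <- paste0(stem, loop, reverse_complement(stem))
  out <- paste0(substr(seq, 1, position), insert, substr(seq, position + 1L, n))
  list(seq = out, manifest = list(
    kind = "hairpin", position = position, stem_len = stem_len,
    loop_len = loop_len, stem = stem, loop = loop,
    insert_start = position + 1L, insert_end = position + nchar(insert),
    seed = seed
  ))
}

#' Star-phylogeny set with context-biased mutations
#'
#' A random ancestor and `n_seqs` descendants, each mutated independently so
#' the whole set accumulates about `n_changes` substitutions under the given
#' context multipliers (e.g. a CpG-driven C->T excess).
#'
#' @param ancestor_len Ancestor length.
#' @param n_seqs Number of descendant sequences.
#' @param n_changes Total expected substitutions across the set.
#' @param multipliers Context multiplier data frame (see [mutate_seq()]);
#'   default: C->T rate multiplied 5-fold before G.
#' @param ts_tv_ratio Transition:transversion ratio.
#' @param seed RNG seed.
#' @return List with `aln` (ancestor `anc` + descendants, untagged) and
#'   `manifest`.
#' @export
make_context_mutant_set <- function(ancestor_len = 2000L, n_seqs = 20L,
                                    n_changes = 2000L,
                                    multipliers = data.frame(
                                      from = "C", to = "T", side = "down",
                                      base = "G", multiplier = 5
                                    ),
                                    ts_tv_ratio = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  anc <- random_nt(ancestor_len)
  target <- n_changes / (n_seqs * ancestor_len)
  seqs <- vapply(seq_len(n_seqs), function(i) {
    mutate_seq(anc, target, ts_tv_ratio, context_multipliers = multipliers)
  }, character(1))
  aln <- tagged_alignment(setNames(c(anc, seqs),
                                   c("anc", sprintf("s%d", seq_len(n_seqs)))))
  list(aln = aln, manifest = list(
    kind = "context_mutant_set", ancestor_len = ancestor_len, n_seqs = n_seqs,
    n_changes = n_changes, multipliers = multipliers,
    ts_tv_ratio = ts_tv_ratio, ancestor = anc, seed = seed
  ))
}
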