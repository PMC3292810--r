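# Tree plumbing: neighbor-joining on module distance matrices, bootstrap
# resampling, bipartition handling and the Robinson-Foulds partition metric
# (plain and bootstrap-support-thresholded).

#' Neighbor-joining tree for a selection
#'
#' Standard NJ on the pairwise distance matrix; negative branch lengths are
#' clamped to zero.  Deterministic given the input row order.
#'
#' @param aln A `tagged_alignment`.
#' @param model Distance model (see [nt_distance()]).
#' @param rows,columns Optional selection.
#' @return An `ape::phylo` (unrooted), tip labels = sequence ids.
#' @export
nj_tree <- function(aln, model = "jukes_cantor", rows = NULL, columns = NULL) {
  d <- dist_matrix(aln, model, rows, columns)
  if (nrow(d) < 3L) stop("neighbor-joining needs at least three sequences")
  bad <- which(!is.finite(d) & upper.tri(d), arr.ind = TRUE)
  if (nrow(bad)) {
    stop("saturated/inapplicable distance between '", rownames(d)[bad[1, 1]],
         "' and '", colnames(d)[bad[1, 2]], "'")
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Bootstrap replicate trees
#'
#' Site resampling draws alignment columns with replacement; sequence
#' (population) resampling draws `floor(2y/3)` rows per tagged group without
#' replacement (the query row, if given, is always retained).
#'
#' @param aln A `tagged_alignment`.
#' @param replicates Number of replicate trees (>= 1).
#' @param resampling `"site"` or `"sequence"`.
#' @param model Distance model.
#' @param tag_set Tag set for sequence resampling.
#' @param query Query id retained under sequence resampling.
#' @param rows,columns Optional selection.
#' @param seed Optional RNG seed (reproducible replicate set).
#' @return List of `ape::phylo` trees.
#' @export
bootstrap_trees <- function(aln, replicates = 100L, resampling = "site",
                            model = "jukes_cantor", tag_set = 1L, query = NULL,
                            rows = NULL, columns = NULL, seed = NULL) {
  resampling <- match.arg(resampling, c("site", "sequence"))
  stopifnot(replicates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  sub <- aln[rows, columns]
  L <- aln_length(sub)
  out <- vector("list", replicates)
  if (resampling == "site") {
    for (r in seq_len(replicates)) {
      out[[r]] <- nj_tree(sub, model, columns = sample.int(L, L, replace = TRUE))
    }
    return(out)
  }
  grp <- get_groups(sub, tag_set)
  if (!is.null(query)) grp <- grp[names(grp) != query]
  idx <- split(names(grp), grp)
  small <- vapply(idx, length, integer(1)) < 2L
  if (any(small)) {
    warning("group(s) with fewer than 2 members excluded from sequence resampling: ",
            paste(names(idx)[small], collapse = ", "))
    idx <- idx[!small]
  }
  if (!length(idx)) stop("no groups large enough for sequence resampling")
  for (r in seq_len(replicates)) {
    take <- unlist(lapply(idx, function(ids) sample(ids, floor(2 * length(ids) / 3))))
    out[[r]] <- nj_tree(sub, model, rows = c(query, take))
  }
  out
}

# ---- bipartitions ----------------------------------------------------------

# Non-trivial splits of a phylo as canonical label sets: each split is the
# side NOT containing the reference (lexicographically smallest) label,
# encoded as a sorted comma-joined string.  Values = bootstrap support from
# node.label when present (NA otherwise).
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  n_tip <- length(tree$tip.label)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  support <- if (!is.null(tree$node.label)) suppressWarnings(as.numeric(tree$node.label)) else rep(NA_real_, tree$Nnode)
  out <- list()
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    other <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (ref %in% side) other else side
    key <- paste(sort(canon), collapse = ",")
    out[[key]] <- support[k]
  }
  out
}

splits_incompatible <- function(s1, s2, all_tips) {
  a <- strsplit(s1, ",", fixed = TRUE)[[1]]
  b <- strsplit(s2, ",", fixed = TRUE)[[1]]
  ac <- setdiff(all_tips, a); bc <- setdiff(all_tips, b)
  length(intersect(a, b)) > 0 && length(intersect(a, bc)) > 0 &&
    length(intersect(ac, b)) > 0 && length(intersect(ac, bc)) > 0
}

#' Robinson-Foulds partition metric / supported phylogeny violations
#'
#' With `support_threshold = NULL`, the symmetric-difference (partition)
#' metric: the number of non-trivial bipartitions present in exactly one of
#' the two trees.  With a threshold, the count of bipartitions of `t1` with
#' bootstrap support at or above the threshold that are incompatible (cannot
#' coexist in any tree) with some supported bipartition of `t2` — the
#' "phylogeny violation" count of the tree-order scan.
#'
#' @param t1,t2 `ape::phylo` trees on the same leaf set.
#' @param support_threshold Bootstrap percentage, or `NULL`.
#' @return Integer count.
#' @export
rf_distance <- function(t1, t2, support_threshold = NULL) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("trees have different leaf sets")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  if (is.null(support_threshold)) {
    return(sum(!names(s1) %in% names(s2)) + sum(!names(s2) %in% names(s1)))
  }
  keep1 <- names(s1)[!is.na(unlist(s1)) & unlist(s1) >= support_threshold]
  keep2 <- names(s2)[!is.na(unlist(s2)) & unlist(s2) >= support_threshold]
  if (!length(keep1) || !length(keep2)) return(0L)
  tips <- t1$tip.label
  sum(vapply(keep1, function(a) {
    any(vapply(keep2, function(b) splits_incompatible(a, b, tips), logical(1)))
  }, logical(1)))
}

# attach bootstrap support (%) to a tree's internal nodes from replicate trees
add_support <- function(tree, boot_trees) {
  keys <- names(tree_splits(tree))
  counts <- setNames(rep(0, length(keys)), keys)
  for (bt in boot_trees) {
    hits <- intersect(names(tree_splits(bt)), keys)
    counts[hits] <- counts[hits] + 1
  }
  support <- round(100 * counts / length(boot_trees))
  # map back onto node labels via prop.part order
  tips <- sort(tree$tip.label)
  ref <- tips[1]
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  node_lab <- rep("", tree$Nnode)
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    other <- setdiff(tree$tip.label, side)
    if (length(side) < 2L || length(other) < 2L) next
    canon <- if (ref %in% side) other else side
    key <- paste(sort(canon), collapse = ",")
    node_lab[k] <- as.character(support[key])
  }
  tree$node.label <- node_lab
  tree
}

# deterministic ladderization: at every internal node, larger clade first,
# ties broken by the smallest contained tip order index; returns tip ids in
# display (y) order
ladder_order <- function(tree, tip_rank = NULL) {
  n_tip <- length(tree$tip.label)
  if (is.null(tip_rank)) tip_rank <- setNames(seq_len(n_tip), sort(tree$tip.label))
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  rec <- function(node) {
    if (node <= n_tip) {
      return(list(tips = tree$tip.label[node], size = 1L,
                  min_rank = tip_rank[[tree$tip.label[node]]]))
    }
    parts <- lapply(kids[[as.character(node)]], rec)
    ord <- order(-vapply(parts, `[[`, integer(1), "size"),
                 vapply(parts, `[[`, numeric(1), "min_rank"))
    parts <- parts[ord]
    list(tips = unlist(lapply(parts, `[[`, "tips")),
         size = sum(vapply(parts, `[[`, integer(1), "size")),
         min_rank = min(vapply(parts, `[[`, numeric(1), "min_rank")))
  }
  rec(n_tip + 1L)$tips
}
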