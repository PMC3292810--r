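# Phylogeny-group segregation methods: association index (AI), grouping
# score / GroupingScan, bootscanning and the tree-order scan.

#' Association value A of a tree
#'
#' Sums per-node dispersion `(1 - g_max/t) / 2^(t-1)` over all internal nodes
#' of the rooted tree, where `t` is the number of (tagged) sequences below the
#' node and `g_max` the count of the most abundant group among them.  Zero for
#' perfect segregation apart from the unavoidable mixing at the root.
#'
#' @param tree `ape::phylo`; midpoint-rooted first if unrooted.
#' @param groups Named vector (names = tip labels) of group ids; tips absent
#'   from `groups` are ignored in the node counts.
#' @return Numeric A >= 0.
#' @export
association_statistic <- function(tree, groups) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  A <- 0
  for (k in seq_along(pp)) {
    below <- labs[pp[[k]]]
    g <- groups[below[below %in% names(groups)]]
    t_n <- length(g)
    if (t_n < 2L) next
    gmax <- max(table(g))
    A <- A + (1 - gmax / t_n) / 2^(t_n - 1)
  }
  A
}

#' Association index for a fixed tree
#'
#' AI = A(native labels) / mean A over label-randomised replicates, where the
#' null permutes the group labels across the tagged leaves.
#'
#' @param tree `ape::phylo`.
#' @param groups Named group vector (see [association_statistic()]).
#' @param null_randomizations Number of label permutations.
#' @param seed Optional RNG seed.
#' @return A `segregation_result` list: `A_native`, `A_null_mean`,
#'   `A_null_sd`, `AI`, `replicates` (here, permutations).
#' @export
association_test <- function(tree, groups, null_randomizations = 100L, seed = NULL) {
  if (length(unique(groups)) < 2L) stop("association index needs at least two groups")
  if (!is.null(seed)) set.seed(seed)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  A <- association_statistic(tree, groups)
  nulls <- vapply(seq_len(null_randomizations), function(r) {
    association_statistic(tree, setNames(sample(groups), names(groups)))
  }, numeric(1))
  structure(
    list(A_native = A, A_null_mean = mean(nulls), A_null_sd = sd(nulls),
         AI = A / mean(nulls), replicates = null_randomizations),
    class = "segregation_result"
  )
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("A = %.6g, null %.6g +/- %.4g (%d perms) => AI = %.4g\n",
              x$A_native, x$A_null_mean, x$A_null_sd, x$replicates, x$AI))
  invisible(x)
}

#' Association index for an alignment
#'
#' Full pipeline: bootstrap replicate NJ trees, A averaged over them, null
#' from label permutations on each replicate tree.
#'
#' @param aln A `tagged_alignment`.
#' @param tag_set Tag set defining the groups.
#' @param replicates Bootstrap replicate trees (site resampling).
#' @param null_randomizations Label permutations per replicate tree.
#' @param model Distance model for NJ.
#' @param rows,columns Optional selection.
#' @param seed RNG seed.
#' @return A `segregation_result` (fields as in [association_test()], with
#'   `replicates` = bootstrap trees).
#' @export
association_index <- function(aln, tag_set = 1L, replicates = 10L,
                              null_randomizations = 100L,
                              model = "jukes_cantor", rows = NULL,
                              columns = NULL, seed = NULL) {
  groups <- get_groups(aln[rows, NULL], tag_set)
  if (length(unique(groups)) < 2L) stop("association index needs at least two non-empty groups")
  if (!is.null(seed)) set.seed(seed)
  trees <- bootstrap_trees(aln, replicates, "site", model,
                           rows = rows, columns = columns)
  A_nat <- numeric(0); A_null <- numeric(0)
  for (tr in trees) {
    tr <- phangorn::midpoint(tr)
    A_nat <- c(A_nat, association_statistic(tr, groups))
    A_null <- c(A_null, vapply(seq_len(null_randomizations), function(r) {
      association_statistic(tr, setNames(sample(groups), names(groups)))
    }, numeric(1)))
  }
  structure(
    list(A_native = mean(A_nat), A_null_mean = mean(A_null),
         A_null_sd = sd(A_null), AI = mean(A_nat) / mean(A_null),
         replicates = replicates),
    class = "segregation_result"
  )
}

#' Grouping score of a query sequence
#'
#' For each group `a`, the raw score sums `2^-N` over group members, where
#' `N` is the number of internal nodes on the tree path between the query and
#' the member; scores are normalised across groups so they sum to one.  High
#' G means the query is deeply embedded in (not segregated from) that group.
#'
#' @param tree `ape::phylo` containing the query tip.
#' @param groups Named group vector over the other tips (the query's own tag,
#'   if present, is ignored).
#' @param query Query tip label.
#' @return A `grouping_result`: list with `G` (normalised, sums to 1), `raw`,
#'   and `query`.
#' @export
grouping_score <- function(tree, groups, query) {
  if (!query %in% tree$tip.label) stop("query '", query, "' not in tree")
  groups <- groups[names(groups) != query]
  groups <- groups[names(groups) %in% tree$tip.label]
  if (length(unique(groups)) < 2L) stop("grouping score needs at least two tagged groups")
  n_tip <- length(tree$tip.label)
  qi <- match(query, tree$tip.label)
  raw <- vapply(split(names(groups), groups), function(ids) {
    sum(vapply(ids, function(id) {
      path <- ape::nodepath(tree, qi, match(id, tree$tip.label))
      2^-sum(path > n_tip)
    }, numeric(1)))
  }, numeric(1))
  tot <- sum(raw)
  structure(
    list(G = if (tot > 0) raw / tot else raw, raw = raw, query = query),
    class = "grouping_result"
  )
}

#' @export
print.grouping_result <- function(x, ...) {
  cat("grouping scores for query '", x$query, "':\n", sep = "")
  print(round(x$G, 4))
  invisible(x)
}

#' Sliding-window GroupingScan
#'
#' Per window, the mean normalised grouping score of the query for each
#' tagged group, averaged over bootstrap replicate trees.  A crossover of the
#' leading group along the genome indicates recombination.
#'
#' @param aln A `tagged_alignment` containing the (typically untagged) query.
#' @param query Query sequence id.
#' @param tag_set Tag set defining candidate parental groups.
#' @param window,step Window width and step (columns).  Windows narrower than
#'   50 columns give unstable trees and trigger a warning.
#' @param replicates Bootstrap replicate trees per window.
#' @param resampling `"site"` or `"sequence"` (see [bootstrap_trees()]).
#' @param model Distance model.
#' @param seed RNG seed.
#' @return A `scan_profile` (metric `"G"`, one series per group, labelled
#'   `group<g>`).
#' @export
grouping_scan <- function(aln, query, tag_set = 1L, window = 300L, step = 50L,
                          replicates = 20L, resampling = "site",
                          model = "jukes_cantor", seed = NULL) {
  if (window < 50L) warning("window below 50 columns; grouping scores will be noisy")
  if (!is.null(seed)) set.seed(seed)
  groups <- get_groups(aln, tag_set)
  keep <- c(query, names(groups)[names(groups) != query])
  sub <- aln[keep, NULL]
  starts <- window_starts(aln_length(sub), window, step)
  out <- list()
  for (s in starts) {
    cols <- s:(s + window - 1L)
    trees <- bootstrap_trees(sub, replicates, resampling, model,
                             tag_set = tag_set, query = query, columns = cols)
    gmat <- vapply(trees, function(tr) {
      gs <- grouping_score(phangorn::midpoint(tr), groups, query)
      full <- setNames(rep(0, length(unique(groups))), sort(unique(groups)))
      full[names(gs$G)] <- gs$G
      full
    }, numeric(length(unique(groups))))
    gmean <- rowMeans(as.matrix(gmat))
    for (g in names(gmean)) {
      out[[length(out) + 1L]] <- data.frame(
        midpoint = s + (window - 1) / 2, series = paste0("group", g),
        metric = "G", value = gmean[[g]], stringsAsFactors = FALSE
      )
    }
  }
  scan_profile(do.call(rbind, out), window, step)
}

#' Sliding-window bootscan
#'
#' Per window, the percentage of bootstrap replicate trees in which the query
#' falls inside a clade containing only members of group `g` (besides the
#' query itself), for each tagged group.
#'
#' @inheritParams grouping_scan
#' @return A `scan_profile` (metric `"support"`, percent, one series per
#'   group).  Per-window supports over groups sum to at most 100.
#' @export
bootscan <- function(aln, query, tag_set = 1L, window = 300L, step = 50L,
                     replicates = 100L, model = "jukes_cantor", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  groups <- get_groups(aln, tag_set)
  keep <- c(query, names(groups)[names(groups) != query])
  sub <- aln[keep, NULL]
  gids <- sort(unique(groups))
  starts <- window_starts(aln_length(sub), window, step)
  out <- list()
  for (s in starts) {
    cols <- s:(s + window - 1L)
    trees <- bootstrap_trees(sub, replicates, "site", model, columns = cols)
    hits <- setNames(rep(0L, length(gids)), gids)
    for (tr in trees) {
      for (g in gids) {
        if (query_in_group_clade(tr, query, names(groups)[groups == g])) {
          hits[as.character(g)] <- hits[as.character(g)] + 1L
        }
      }
    }
    for (g in names(hits)) {
      out[[length(out) + 1L]] <- data.frame(
        midpoint = s + (window - 1) / 2, series = paste0("group", g),
        metric = "support", value = 100 * hits[[g]] / replicates,
        stringsAsFactors = FALSE
      )
    }
  }
  scan_profile(do.call(rbind, out), window, step)
}

# does any split of the (unrooted) tree place the query with only members of
# `members`?  The query must be embedded within the group: the clade holds the
# query plus a non-empty PROPER subset of the group (a query merely adjacent
# to two complete group clades would otherwise "cluster" with both at once).
query_in_group_clade <- function(tree, query, members) {
  pp <- ape::prop.part(tree)
  labs <- attr(pp, "labels")
  all_tips <- tree$tip.label
  for (k in seq_along(pp)) {
    side <- labs[pp[[k]]]
    for (cand in list(side, setdiff(all_tips, side))) {
      if (length(cand) < 2L || length(cand) >= length(all_tips)) next
      rest <- setdiff(cand, query)
      if (query %in% cand && length(rest) >= 1L &&
          length(rest) < length(members) && all(rest %in% members)) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Tree-order scan
#'
#' Per window: an NJ tree with bootstrap support, deterministically
#' ladderized (larger clade first, ties by smallest alignment row index),
#' giving every sequence a y-position; plus a phylogenetic compatibility
#' matrix counting supported-bipartition violations ([rf_distance()] at the
#' support threshold) between every window pair.
#'
#' @param aln A `tagged_alignment`.
#' @param tag_set Tag set used to annotate the order table.
#' @param window,step Window width and step (columns).
#' @param replicates Bootstrap replicates per window for support values.
#' @param support_threshold Bootstrap percentage defining a "supported" clade.
#' @param model Distance model.
#' @param seed RNG seed.
#' @return List with `order_table` (window midpoint, id, group, y), and
#'   `compatibility` (data frame `window_i`, `window_j`, `violations` for
#'   i < j), `trees` (per-window trees with support in `node.label`), and
#'   `midpoints`.
#' @export
treeorder_scan <- function(aln, tag_set = 1L, window = 300L, step = 50L,
                           replicates = 100L, support_threshold = 70,
                           model = "jukes_cantor", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  starts <- window_starts(aln_length(aln), window, step)
  groups <- get_groups(aln, tag_set, drop_unassigned = FALSE)
  tip_rank <- setNames(seq_len(n_seq(aln)), aln$ids)
  trees <- list(); order_rows <- list(); mids <- numeric(0)
  for (s in starts) {
    cols <- s:(s + window - 1L)
    tr <- nj_tree(aln, model, columns = cols)
    boots <- bootstrap_trees(aln, replicates, "site", model, columns = cols)
    tr <- add_support(tr, boots)
    trees[[length(trees) + 1L]] <- tr
    mid <- s + (window - 1) / 2
    mids <- c(mids, mid)
    ord <- ladder_order(tr, tip_rank)
    order_rows[[length(order_rows) + 1L]] <- data.frame(
      midpoint = mid, id = ord, group = unname(groups[ord]),
      y = seq_along(ord), stringsAsFactors = FALSE
    )
  }
  comp <- list()
  nw <- length(trees)
  if (nw > 1L) {
    for (i in 1:(nw - 1)) for (j in (i + 1):nw) {
      comp[[length(comp) + 1L]] <- data.frame(
        window_i = mids[i], window_j = mids[j],
        violations = rf_distance(trees[[i]], trees[[j]], support_threshold)
      )
    }
  }
  list(
    order_table = do.call(rbind, order_rows),
    compatibility = if (length(comp)) do.call(rbind, comp) else
      data.frame(window_i = numeric(), window_j = numeric(), violations = integer()),
    trees = trees, midpoints = mids
  )
}

#' Breakpoint estimate from a two-group scan profile
#'
#' Linear interpolation of the crossover point where the two leading series
#' of a [grouping_scan()] or [bootscan()] profile exchange rank.
#'
#' @param profile A `scan_profile` with series `group<a>` and `group<b>`.
#' @param series_a,series_b Series names to compare (default: the two series
#'   with the highest overall values).
#' @return Estimated alignment position of the crossover, or `NA` if the
#'   leading series never switches.
#' @export
scan_crossover <- function(profile, series_a = NULL, series_b = NULL) {
  df <- as.data.frame(profile)
  if (is.null(series_a) || is.null(series_b)) {
    tot <- sort(tapply(df$value, df$series, mean), decreasing = TRUE)
    series_a <- names(tot)[1]; series_b <- names(tot)[2]
  }
  a <- df[df$series == series_a, ]; a <- a[order(a$midpoint), ]
  b <- df[df$series == series_b, ]; b <- b[order(b$midpoint), ]
  diffs <- a$value - b$value
  nz <- which(diffs != 0)
  if (length(nz) < 2L) return(NA_real_)
  flip <- which(sign(diffs[nz[-length(nz)]]) != sign(diffs[nz[-1]]))
  if (!length(flip)) return(NA_real_)
  i <- nz[flip[1]]; j <- nz[flip[1] + 1L]
  x1 <- a$midpoint[i]; x2 <- a$midpoint[j]
  if (j - i > 1L) return((x1 + x2) / 2)   # sign change across a tied/dead zone
  d1 <- diffs[i]; d2 <- diffs[j]
  x1 + (x2 - x1) * d1 / (d1 - d2)
}
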