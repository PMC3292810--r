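# Ancestral reconstruction and context-stratified substitution spectra.
# Ancestors come either from a simple consensus (no tree structure assumed)
# or from Fitch two-pass parsimony on a supplied/inferred tree; directed
# changes are then scored against the immediate ancestor, with the flanking
# context read from the ancestral (pre-mutation) sequence.

BIT <- c(A = 1L, C = 2L, G = 4L, T = 8L)

state_to_bits <- function(chars) {
  sets <- iupac_sets()
  vapply(chars, function(ch) {
    s <- sets[[ch]]
    if (is.null(s)) 15L else sum(BIT[s])   # gap/unknown = any state
  }, integer(1), USE.NAMES = FALSE)
}

bits_to_base <- function(bits) {
  # lowest set bit, fixed order A < C < G < T
  c("A", "C", "G", "T")[as.integer(log2(bitwAnd(bits, -bits))) + 1L]
}

#' Consensus sequence
#'
#' Per column, the most frequent state if its share strictly exceeds the
#' threshold; otherwise the IUPAC ambiguity code of the states tied at the
#' maximum count.  Gaps are counted as a state.
#'
#' @param aln A nucleotide `tagged_alignment`.
#' @param rows,columns Optional selection.
#' @param threshold Majority threshold (default 0.5 = strict majority).
#' @return Consensus string.
#' @export
consensus_sequence <- function(aln, rows = NULL, columns = NULL, threshold = 0.5) {
  sub <- aln[rows, columns]
  if (n_seq(sub) < 2L) stop("consensus needs at least two sequences")
  apply(sub$mat, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    if (tab[1] / length(col) > threshold) return(names(tab)[1])
    top <- names(tab)[tab == tab[1]]
    if ("-" %in% top) return("-")
    code <- iupac_code_for(unlist(iupac_sets()[top], use.names = FALSE))
    if (is.null(code) || is.na(code)) "N" else code
  }) |> paste(collapse = "")
}

#' Fitch parsimony ancestral reconstruction
#'
#' Two-pass Fitch parsimony per column on a rooted binary tree (an unrooted
#' tree is midpoint-rooted and resolved first).  Ties at internal nodes are
#' broken by the fixed base order A < C < G < T, so reconstruction is
#' deterministic; the number of implied changes equals the Fitch parsimony
#' score.
#'
#' @param aln A nucleotide `tagged_alignment`.
#' @param tree An `ape::phylo` whose tip labels match sequence ids.
#' @return List with `ancestors` (character matrix, one row per internal
#'   node, rownames `node<k>`), `score` (total parsimony score), `score_per_column`,
#'   and `tree` (the rooted binary tree used, tips in input order).
#' @export
fitch_ancestral <- function(aln, tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!setequal(tree$tip.label, aln$ids)) {
    miss <- setdiff(tree$tip.label, aln$ids)
    stop("tree/alignment leaf mismatch",
         if (length(miss)) paste0(": missing from alignment: ",
                                  paste(miss, collapse = ", ")) else "")
  }
  tree <- prepare_rooted(tree)
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  L <- aln_length(aln)

  sets <- matrix(0L, n_tip + n_node, L)
  for (i in seq_len(n_tip)) {
    sets[i, ] <- state_to_bits(aln$mat[match(tree$tip.label[i], aln$ids), ])
  }
  edge <- tree$edge[order(tree$edge[, 1], decreasing = TRUE), , drop = FALSE]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  score <- rep(0L, L)
  # downpass: children combine pairwise in postorder
  seen <- logical(n_tip + n_node)
  for (k in seq_len(nrow(po))) {
    par <- po[k, 1]; chi <- po[k, 2]
    if (!seen[par]) {
      sets[par, ] <- sets[chi, ]
      seen[par] <- TRUE
    } else {
      inter <- bitwAnd(sets[par, ], sets[chi, ])
      un <- bitwOr(sets[par, ], sets[chi, ])
      empty <- inter == 0L
      score <- score + empty
      sets[par, ] <- ifelse(empty, un, inter)
    }
  }
  # uppass: root takes its lowest state; children keep the parent state when
  # possible, else their own lowest state
  final <- matrix(0L, n_tip + n_node, L)
  root <- n_tip + 1L
  final[root, ] <- bitwAnd(sets[root, ], -sets[root, ])   # lowest set bit
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (k in seq_len(nrow(pre))) {
    par <- pre[k, 1]; chi <- pre[k, 2]
    keep <- bitwAnd(sets[chi, ], final[par, ]) != 0L
    final[chi, ] <- ifelse(keep, final[par, ], bitwAnd(sets[chi, ], -sets[chi, ]))
  }
  anc_nodes <- (n_tip + 1L):(n_tip + n_node)
  anc <- matrix(bits_to_base(final[anc_nodes, , drop = FALSE]), length(anc_nodes), L)
  rownames(anc) <- paste0("node", anc_nodes)
  list(ancestors = anc, score = sum(score), score_per_column = score, tree = tree)
}

prepare_rooted <- function(tree) {
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  if (!ape::is.binary.phylo(tree)) tree <- ape::multi2di(tree)
  tree
}

#' Context-stratified substitution spectrum
#'
#' Directed substitutions between each sequence (or tree node) and its
#' immediate ancestor.  In consensus mode every row is compared to the
#' consensus of the selection; in parsimony mode every edge of the tree
#' contributes (descendant vs Fitch ancestor).  The upstream/downstream
#' context of a change is read from the ancestral sequence; sites at sequence
#' ends (or with non-ACGT context) fall into the `"any"` stratum.
#'
#' @param aln A nucleotide `tagged_alignment`.
#' @param mode `"consensus"` or `"parsimony"`.
#' @param tree Required for parsimony mode.
#' @param frame 1-based first codon position for the codon-position stratum.
#' @param rows,columns Optional selection (consensus mode).
#' @param threshold Consensus threshold (consensus mode).
#' @return Object of class `substitution_spectrum`: list with `changes`
#'   (data frame `from`, `to`, `upstream`, `downstream`, `codon_pos`,
#'   `count`), `opportunities` (ancestral site counts per
#'   `base`/`upstream`/`downstream` stratum), `totals` (sites compared),
#'   `mode` and `n_comparisons`.
#' @export
substitution_spectrum <- function(aln, mode = "consensus", tree = NULL,
                                  frame = 1L, rows = NULL, columns = NULL,
                                  threshold = 0.5) {
  mode <- match.arg(mode, c("consensus", "parsimony"))
  sub <- aln[rows, columns]
  prs <- list()
  if (mode == "consensus") {
    cons <- consensus_sequence(sub, threshold = threshold)
    for (i in seq_len(n_seq(sub))) {
      prs[[i]] <- list(anc = as_chars(cons), des = sub$mat[i, ])
    }
  } else {
    if (is.null(tree)) stop("parsimony mode requires a tree")
    fa <- fitch_ancestral(sub, tree)
    tr <- fa$tree
    n_tip <- length(tr$tip.label)
    node_seq <- function(k) {
      if (k <= n_tip) sub$mat[match(tr$tip.label[k], sub$ids), ]
      else fa$ancestors[k - n_tip, ] |> unname()
    }
    for (e in seq_len(nrow(tr$edge))) {
      prs[[e]] <- list(anc = node_seq(tr$edge[e, 1]), des = node_seq(tr$edge[e, 2]))
    }
  }

  L <- aln_length(sub)
  codon_pos <- as.character(((seq_len(L) - frame) %% 3L) + 1L)
  ch_list <- list(); opp_list <- list()
  total_sites <- 0L
  for (pr in prs) {
    anc <- pr$anc; des <- pr$des
    ok <- anc %in% BASES & des %in% BASES
    total_sites <- total_sites + sum(ok)
    up <- c("any", anc[-L]); down <- c(anc[-1], "any")
    up[!up %in% BASES] <- "any"; down[!down %in% BASES] <- "any"
    idx <- which(ok)
    opp_list[[length(opp_list) + 1L]] <- data.frame(
      base = anc[idx], upstream = up[idx], downstream = down[idx],
      codon_pos = codon_pos[idx], stringsAsFactors = FALSE
    )
    chg <- which(ok & anc != des)
    if (length(chg)) {
      ch_list[[length(ch_list) + 1L]] <- data.frame(
        from = anc[chg], to = des[chg], upstream = up[chg],
        downstream = down[chg], codon_pos = codon_pos[chg],
        stringsAsFactors = FALSE
      )
    }
  }
  agg <- function(df, keys) {
    if (is.null(df) || !nrow(df)) {
      return(cbind(stats::setNames(
        as.data.frame(matrix(character(), 0, length(keys)), stringsAsFactors = FALSE),
        keys), data.frame(count = integer())))
    }
    out <- stats::aggregate(list(count = rep(1L, nrow(df))), df[keys], sum)
    out[do.call(order, out[keys]), , drop = FALSE]
  }
  changes <- agg(if (length(ch_list)) do.call(rbind, ch_list) else NULL,
                 c("from", "to", "upstream", "downstream", "codon_pos"))
  opps <- agg(do.call(rbind, opp_list), c("base", "upstream", "downstream", "codon_pos"))
  structure(
    list(changes = changes, opportunities = opps, totals = total_sites,
         mode = mode, n_comparisons = length(prs)),
    class = "substitution_spectrum"
  )
}

#' @export
print.substitution_spectrum <- function(x, ...) {
  cat(sprintf("substitution_spectrum (%s): %d change(s) over %d compared site(s), %d comparison(s)\n",
              x$mode, sum(x$changes$count), x$totals, x$n_comparisons))
  invisible(x)
}

#' Context-conditional substitution rate
#'
#' Changes per ancestral opportunity for a given substitution, optionally
#' conditioned on the upstream and/or downstream base.
#'
#' @param spectrum A `substitution_spectrum`.
#' @param from,to Ancestral and derived base.
#' @param upstream,downstream Conditioning base (A/C/G/T), or `NULL` for any,
#'   or a vector of bases (e.g. `c("A","C","T")` for "not G").
#' @return Rate (changes / opportunities); `NA` if no opportunities.
#' @export
context_rate <- function(spectrum, from, to, upstream = NULL, downstream = NULL) {
  ch <- spectrum$changes
  op <- spectrum$opportunities
  keep_ch <- ch$from == from & ch$to == to
  keep_op <- op$base == from
  if (!is.null(upstream)) {
    keep_ch <- keep_ch & ch$upstream %in% upstream
    keep_op <- keep_op & op$upstream %in% upstream
  }
  if (!is.null(downstream)) {
    keep_ch <- keep_ch & ch$downstream %in% downstream
    keep_op <- keep_op & op$downstream %in% downstream
  }
  n_op <- sum(op$count[keep_op])
  if (n_op == 0L) return(NA_real_)
  sum(ch$count[keep_ch]) / n_op
}
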