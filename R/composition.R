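# Composition statistics: mono-/dinucleotide frequencies and odds ratios
# (optionally amino-acid-corrected for coding sequences and stratified by
# codon position), codon usage (RSCU), Wright's effective codon number, and
# signed base-usage bias at synonymous third positions.

BASES <- c("A", "C", "G", "T")
DINUCS <- as.vector(outer(BASES, BASES, paste0))

degap_nt <- function(seq) {
  chars <- as_chars(seq)
  chars[chars == "U"] <- "T"
  chars[chars %in% BASES]
}

#' Mononucleotide frequencies
#' @param seq Nucleotide string; gaps and ambiguity codes are excluded.
#' @return Named numeric vector over A, C, G, T summing to 1.
#' @export
mono_frequencies <- function(seq) {
  chars <- degap_nt(seq)
  f <- as.vector(table(factor(chars, levels = BASES))) / max(length(chars), 1L)
  setNames(f, BASES)
}

# dinucleotide counts over adjacent ungapped positions, optionally only at
# codon-position strata: "all", "1-2", "2-3", "3-1" (bridging junction)
dinuc_counts <- function(seq, stratum = "all", frame = 1L) {
  chars <- degap_nt(seq)
  n <- length(chars)
  if (n < 2L) return(setNames(rep(0L, 16L), DINUCS))
  first <- chars[-n]; second <- chars[-1]
  if (stratum != "all") {
    # codon position of the first member of the pair, relative to frame
    pos1 <- ((seq_len(n - 1L) - frame) %% 3L) + 1L
    want <- c(`1-2` = 1L, `2-3` = 2L, `3-1` = 3L)[stratum]
    keep <- pos1 == want
    first <- first[keep]; second <- second[keep]
  }
  tab <- table(factor(paste0(first, second), levels = DINUCS))
  setNames(as.integer(tab), DINUCS)
}

#' Dinucleotide frequencies and observed/expected ratios
#'
#' @param seq Nucleotide string.
#' @param stratum `"all"` or a codon-position stratum `"1-2"`, `"2-3"`,
#'   `"3-1"` (the bridging positions across the codon junction).
#' @param frame Reading frame (1-based start of the first full codon) for the
#'   codon-position strata.
#' @return Data frame with `dinucleotide`, `count`, `frequency` and `ratio`
#'   (frequency divided by the product of the component mononucleotide
#'   frequencies; the classic odds ratio in which CpG suppression shows as a
#'   low AC-corrected value).
#' @export
dinuc_frequencies <- function(seq, stratum = "all", frame = 1L) {
  counts <- dinuc_counts(seq, stratum, frame)
  tot <- sum(counts)
  freq <- if (tot > 0) counts / tot else counts * 0
  mono <- mono_frequencies(seq)
  expd <- as.vector(outer(mono, mono))
  ratio <- ifelse(expd > 0, freq / expd, NA_real_)
  data.frame(dinucleotide = DINUCS, count = as.integer(counts),
             frequency = as.numeric(freq), ratio = as.numeric(ratio),
             stringsAsFactors = FALSE)
}

codons_of <- function(seq, frame = 1L) {
  chars <- degap_nt(seq)
  if (frame > 1L) chars <- chars[-seq_len(frame - 1L)]
  ncod <- length(chars) %/% 3L
  if (ncod == 0L) return(character())
  chars <- chars[seq_len(3L * ncod)]
  paste0(chars[c(TRUE, FALSE, FALSE)], chars[c(FALSE, TRUE, FALSE)],
         chars[c(FALSE, FALSE, TRUE)])
}

#' Codon counts of a coding sequence
#'
#' @param seq Nucleotide string.
#' @param frame 1-based position of the first codon.
#' @param warn_stop Warn (and skip) internal stop codons.
#' @return Named integer vector over the 61 sense codons.
#' @export
codon_counts <- function(seq, frame = 1L, warn_stop = TRUE) {
  cods <- codons_of(seq, frame)
  code <- genetic_code()
  stops <- cods[!is.na(code[cods]) & code[cods] == "*"]
  if (length(stops) && warn_stop && length(stops) > (cods[length(cods)] %in% stops)) {
    warning("internal stop codon(s) skipped: ", paste(unique(stops), collapse = ", "))
  }
  sense <- names(code)[code != "*"]
  tab <- table(factor(cods[cods %in% sense], levels = sense))
  setNames(as.integer(tab), sense)
}

#' Relative synonymous codon usage
#'
#' RSCU of codon j in a synonymous family of size n is its count divided by
#' the family mean count; a family with zero total usage gets `NA`.
#'
#' @param counts Named codon counts (see [codon_counts()]).
#' @return Data frame with `codon`, `aa`, `count` and `rscu`.
#' @export
rscu <- function(counts) {
  fams <- codon_families()
  out <- lapply(names(fams), function(aa) {
    cods <- fams[[aa]]
    x <- counts[cods]
    tot <- sum(x)
    r <- if (tot > 0) x / (tot / length(cods)) else rep(NA_real_, length(cods))
    data.frame(codon = cods, aa = aa, count = as.integer(x), rscu = as.numeric(r),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Effective codon number (Wright 1990)
#'
#' Per-family codon homozygosity `F = (n * sum(p^2) - 1)/(n - 1)`, averaged
#' within degeneracy classes; `ENc = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6` with
#' Wright's missing-family fallback (`F3 = (F2 + F4)/2` when the single
#' 3-fold family is unobserved) and clamping to `[20, 61]`.
#'
#' @param counts Named codon counts (see [codon_counts()]).
#' @return Effective codon number (numeric scalar); `NA` when no synonymous
#'   family has at least two observations.
#' @export
enc <- function(counts) {
  fams <- codon_families()
  degs <- vapply(fams, length, integer(1))
  Fhat <- vapply(names(fams), function(aa) {
    x <- counts[fams[[aa]]]
    n <- sum(x)
    if (n < 2L) return(NA_real_)
    p <- x / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))
  classes <- c(2, 3, 4, 6)
  Fbar <- vapply(classes, function(k) {
    v <- Fhat[degs == k]
    v <- v[!is.na(v)]
    if (!length(v)) NA_real_ else mean(v)
  }, numeric(1))
  names(Fbar) <- classes
  if (is.na(Fbar["3"]) && !is.na(Fbar["2"]) && !is.na(Fbar["4"])) {
    Fbar["3"] <- (Fbar["2"] + Fbar["4"]) / 2
  }
  n_fam <- c(`2` = sum(degs == 2), `3` = sum(degs == 3),
             `4` = sum(degs == 4), `6` = sum(degs == 6))
  if (any(is.na(Fbar) | Fbar <= 0)) return(NA_real_)
  val <- 2 + sum(n_fam / Fbar)
  min(max(val, 20), 61)
}

#' Base-usage bias at synonymous third positions
#'
#' For each base, the per-family deviation of its observed third-position
#' share from the uniform-usage expectation, combined across families with
#' weights proportional to family codon counts.  `bias` sums the signed
#' deviations (so the four values sum to zero); `variance` sums their
#' squares, measuring total scatter of conformity to the expected values.
#'
#' @param seq In-frame coding nucleotide string.
#' @param frame 1-based position of the first codon.
#' @return Data frame with `base`, `variance`, `bias`; attribute
#'   `"inapplicable"` is `TRUE` when there are no synonymous codons.
#' @export
synonymous_bias <- function(seq, frame = 1L) {
  counts <- codon_counts(seq, frame, warn_stop = FALSE)
  fams <- codon_families()
  fams <- fams[vapply(fams, length, integer(1)) > 1L]   # degenerate families only
  dev <- matrix(0, length(fams), 4, dimnames = list(names(fams), BASES))
  w <- numeric(length(fams))
  for (k in seq_along(fams)) {
    cods <- fams[[k]]
    x <- counts[cods]
    n <- sum(x)
    w[k] <- n
    if (n == 0) next
    third <- substr(cods, 3, 3)
    for (b in BASES) {
      obs <- sum(x[third == b]) / n
      expd <- mean(third == b)
      dev[k, b] <- obs - expd
    }
  }
  tot <- sum(w)
  if (tot == 0) {
    out <- data.frame(base = BASES, variance = NA_real_, bias = NA_real_)
    attr(out, "inapplicable") <- TRUE
    return(out)
  }
  wts <- w / tot
  data.frame(
    base = BASES,
    variance = as.numeric(colSums(dev^2 * wts)),
    bias = as.numeric(colSums(dev * wts)),
    stringsAsFactors = FALSE
  )
}

# ---- amino-acid-corrected dinucleotide expectation -------------------------

# per-codon synonymous-assignment distributions: for each codon of the
# sequence, a weight for every synonymous codon, proportional to the product
# of the sequence's own codon-position base frequencies
syn_codon_weights <- function(cods) {
  code <- genetic_code()
  fams <- codon_families()
  mat <- do.call(rbind, strsplit(cods, ""))
  qpos <- lapply(1:3, function(p) {
    tab <- table(factor(mat[, p], levels = BASES))
    as.vector(tab) / sum(tab)
  })
  lapply(cods, function(cd) {
    aa <- code[cd]
    alts <- fams[[aa]]
    w <- vapply(alts, function(alt) {
      ch <- strsplit(alt, "")[[1]]
      prod(vapply(1:3, function(p) qpos[[p]][match(ch[p], BASES)], numeric(1)))
    }, numeric(1))
    if (sum(w) == 0) w <- rep(1, length(alts))   # degenerate composition
    setNames(w / sum(w), alts)
  })
}

#' Expected dinucleotide frequencies holding the protein fixed
#'
#' The expectation keeps the encoded amino-acid sequence fixed and averages
#' dinucleotide content over synonymous codon assignments, each codon drawn
#' with probability proportional to the sequence's own codon-position base
#' composition.  The default computes the expectation exactly (it factorises
#' over adjacent position pairs); `method = "monte_carlo"` estimates it by
#' simulation instead and is retained as an independent cross-check.
#'
#' @param seq In-frame coding nucleotide string (internal stop codons are
#'   skipped with a warning).
#' @param frame 1-based position of the first codon.
#' @param method `"exact"` or `"monte_carlo"`.
#' @param n_rep Replicates for the Monte-Carlo mode (>= 200 recommended).
#' @param seed Optional seed for the Monte-Carlo mode.
#' @return Named numeric vector of 16 expected dinucleotide frequencies.
#' @export
dinuc_expected_aa_corrected <- function(seq, frame = 1L, method = "exact",
                                        n_rep = 200L, seed = NULL) {
  method <- match.arg(method, c("exact", "monte_carlo"))
  cods <- codons_of(seq, frame)
  code <- genetic_code()
  is_stop <- !is.na(code[cods]) & code[cods] == "*"
  if (any(is_stop[-length(is_stop)])) warning("internal stop codon(s) skipped")
  cods <- cods[!is_stop]
  if (length(cods) < 1L) stop("no usable codons")
  wts <- syn_codon_weights(cods)
  npairs <- 3L * length(cods) - 1L

  if (method == "monte_carlo") {
    if (!is.null(seed)) set.seed(seed)
    acc <- setNames(rep(0, 16L), DINUCS)
    for (r in seq_len(n_rep)) {
      draw <- vapply(wts, function(w) sample(names(w), 1L, prob = w), character(1))
      acc <- acc + dinuc_counts(paste(draw, collapse = ""))
    }
    return(acc / (n_rep * npairs))
  }

  # exact: E[count(xy)] = sum over adjacent position pairs of P(x, y)
  marg <- function(w, pos) {
    ch <- substr(names(w), pos, pos)
    vapply(BASES, function(b) sum(w[ch == b]), numeric(1))
  }
  joint <- function(w, p1, p2) {
    ch1 <- substr(names(w), p1, p1); ch2 <- substr(names(w), p2, p2)
    m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
    for (k in seq_along(w)) m[ch1[k], ch2[k]] <- m[ch1[k], ch2[k]] + w[k]
    m
  }
  acc <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (i in seq_along(wts)) {
    acc <- acc + joint(wts[[i]], 1, 2) + joint(wts[[i]], 2, 3)
    if (i < length(wts)) {
      acc <- acc + outer(marg(wts[[i]], 3), marg(wts[[i + 1]], 1))
    }
  }
  # column-major vectorisation matches DINUCS (first base varies fastest)
  setNames(as.vector(acc) / npairs, DINUCS)
}

#' Amino-acid-corrected dinucleotide ratios
#'
#' Observed dinucleotide frequency divided by the protein-constrained
#' expectation of [dinuc_expected_aa_corrected()].
#'
#' @inheritParams dinuc_expected_aa_corrected
#' @return Named numeric vector of 16 ratios (`NA` where the expectation is 0
#'   and nothing was observed; `Inf` never occurs since observed > 0 implies
#'   expectation > 0 for same-protein assignments).
#' @export
dinuc_aa_corrected_ratio <- function(seq, frame = 1L) {
  cods <- codons_of(seq, frame)
  code <- genetic_code()
  cods <- cods[is.na(code[cods]) | code[cods] != "*"]
  obs <- dinuc_counts(paste(cods, collapse = ""))
  obs_f <- obs / max(sum(obs), 1L)
  expd <- dinuc_expected_aa_corrected(seq, frame)
  ifelse(expd > 0, obs_f / expd, ifelse(obs_f > 0, Inf, NA_real_))
}

#' Full composition report
#'
#' Nucleotide, dinucleotide (all strata), codon-usage (RSCU), effective codon
#' number and synonymous-bias statistics for a selection, per sequence, per
#' tag group (member averages) or pooled over the whole selection.
#'
#' @param aln A nucleotide `tagged_alignment`.
#' @param scope `"per_sequence"`, `"per_group"` or `"whole_selection"`.
#' @param frame 1-based first codon position for codon statistics; `NULL`
#'   skips codon-level output.
#' @param tag_set Tag set used for `scope = "per_group"`.
#' @param rows,columns Optional selection.
#' @return Named list (one element per sequence/group/selection), each with
#'   components `mono`, `dinuc` (list by stratum), `codon` (RSCU table),
#'   `enc`, `syn_bias` and `aa_corrected_ratio`.
#' @export
composition_report <- function(aln, scope = "per_sequence", frame = 1L,
                               tag_set = 1L, rows = NULL, columns = NULL) {
  scope <- match.arg(scope, c("per_sequence", "per_group", "whole_selection"))
  if (aln$alphabet != "nucleotide") stop("composition requires a nucleotide alignment")
  sub <- aln[rows, columns]
  if (n_seq(sub) < 1L) stop("empty selection")
  one <- function(seq) {
    coding <- !is.null(frame) && length(codons_of(seq, frame)) > 0
    list(
      mono = mono_frequencies(seq),
      dinuc = setNames(lapply(c("all", "1-2", "2-3", "3-1"), function(st) {
        dinuc_frequencies(seq, st, if (is.null(frame)) 1L else frame)
      }), c("all", "1-2", "2-3", "3-1")),
      codon = if (coding) rscu(codon_counts(seq, frame, warn_stop = FALSE)) else NULL,
      enc = if (coding) enc(codon_counts(seq, frame, warn_stop = FALSE)) else NA_real_,
      syn_bias = if (coding) synonymous_bias(seq, frame) else NULL,
      aa_corrected_ratio = if (coding) dinuc_aa_corrected_ratio(seq, frame) else NULL
    )
  }
  strs <- aln_strings(sub)
  if (scope == "per_sequence") return(lapply(strs, one))
  if (scope == "whole_selection") {
    return(list(whole_selection = one(paste(gsub("-", "", strs, fixed = TRUE),
                                            collapse = ""))))
  }
  grp <- get_groups(sub, tag_set)
  if (!length(grp)) stop("no tagged groups in tag set ", tag_set)
  lapply(split(names(grp), grp), function(ids) {
    reps <- lapply(strs[ids], one)
    avg <- reps[[1]]
    if (length(reps) > 1L) {
      avg$mono <- Reduce(`+`, lapply(reps, `[[`, "mono")) / length(reps)
      avg$enc <- mean(vapply(reps, `[[`, numeric(1), "enc"))
      for (st in names(avg$dinuc)) {
        avg$dinuc[[st]]$frequency <-
          rowMeans(vapply(reps, function(r) r$dinuc[[st]]$frequency, numeric(16)))
        avg$dinuc[[st]]$ratio <-
          rowMeans(vapply(reps, function(r) r$dinuc[[st]]$ratio, numeric(16)))
      }
    }
    avg$members <- ids
    avg
  })
}
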