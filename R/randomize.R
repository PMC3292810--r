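# Constrained sequence randomisation.  Each scramble algorithm declares the
# attributes it preserves, and check_scramble() verifies the declaration
# post-hoc; the dinucleotide shuffle is the exact Euler-path (doublet-graph)
# method, so dinucleotide counts are preserved exactly, which matters for the
# validity of MFED/Z statistics computed against scrambled controls.

SCRAMBLE_ALGOS <- c("uniform", "dinucleotide", "codon_order",
                    "codon_synonymous", "codon_order_dinucleotide")

#' Scramble a sequence under declared constraints
#'
#' @param seq Ungapped nucleotide string (codon algorithms additionally
#'   require in-frame length, a multiple of 3).
#' @param algorithm One of
#'   `"uniform"` (Fisher-Yates permutation; preserves mononucleotide counts),
#'   `"dinucleotide"` (Euler-path doublet shuffle; preserves the exact
#'   dinucleotide count multiset and the first/last base),
#'   `"codon_order"` (permutes codon triplets; preserves the codon multiset),
#'   `"codon_synonymous"` (replaces each codon by a synonymous codon drawn
#'   from the sequence's own codon pool; preserves the protein), or
#'   `"codon_order_dinucleotide"` (codon permutation accepted only when every
#'   dinucleotide count stays within the certified band of the native count;
#'   best effort, errors after `max_attempts`).
#' @param seed Optional RNG seed.
#' @param max_attempts Attempt cap for the best-effort combined algorithm.
#' @return Scrambled string, with attribute `"preserves"` naming the
#'   certified invariants.
#' @export
scramble <- function(seq, algorithm = "uniform", seed = NULL,
                     max_attempts = 10000L) {
  algorithm <- match.arg(algorithm, SCRAMBLE_ALGOS)
  if (!is.null(seed)) set.seed(seed)
  chars <- as_chars(seq)
  if (any(chars == "-")) stop("scramble requires an ungapped sequence")
  out <- switch(algorithm,
    uniform = paste(sample(chars), collapse = ""),
    dinucleotide = euler_shuffle(chars),
    codon_order = {
      cods <- to_codons(chars)
      paste(sample(cods), collapse = "")
    },
    codon_synonymous = {
      cods <- to_codons(chars)
      code <- genetic_code()
      aa <- code[cods]
      if (anyNA(aa)) stop("codon_synonymous requires unambiguous, gap-free codons")
      pools <- split(cods, aa)
      paste(vapply(seq_along(cods), function(i) {
        pool <- pools[[aa[i]]]
        pool[sample.int(length(pool), 1L)]
      }, character(1)), collapse = "")
    },
    codon_order_dinucleotide = {
      cods <- to_codons(chars)
      native <- dinuc_counts(paste(chars, collapse = ""))
      band <- pmax(1, 0.1 * native)      # +/-10% or +/-1 count
      for (att in seq_len(max_attempts)) {
        cand <- paste(sample(cods), collapse = "")
        if (all(abs(dinuc_counts(cand) - native) <= band)) {
          attr(cand, "attempts") <- att
          return(structure(cand, preserves = c("codon multiset",
                                               "dinucleotide counts (+/-10% or 1)")))
        }
      }
      stop("codon_order_dinucleotide: no permutation within the dinucleotide ",
           "band after ", max_attempts, " attempts (native counts too constrained)")
    }
  )
  preserves <- switch(algorithm,
    uniform = "mononucleotide counts",
    dinucleotide = "exact dinucleotide counts",
    codon_order = "codon multiset",
    codon_synonymous = "encoded protein"
  )
  structure(out, preserves = preserves)
}

to_codons <- function(chars) {
  if (length(chars) %% 3L != 0L) stop("codon algorithms require in-frame length (multiple of 3)")
  paste0(chars[c(TRUE, FALSE, FALSE)], chars[c(FALSE, TRUE, FALSE)],
         chars[c(FALSE, FALSE, TRUE)])
}

# Exact dinucleotide-preserving shuffle: a uniform-ish random Eulerian path
# in the doublet multigraph (random last-exit arborescence, then random
# ordering of the remaining out-edges).
euler_shuffle <- function(chars) {
  n <- length(chars)
  if (n <= 3L) return(paste(chars, collapse = ""))
  verts <- unique(chars)
  if (length(verts) == 1L) return(paste(chars, collapse = ""))
  from <- chars[-n]; to <- chars[-1]
  out_edges <- split(to, factor(from, levels = verts))
  last_v <- chars[n]; first_v <- chars[1]

  pick_arborescence <- function(random = TRUE) {
    last_edge <- setNames(rep(NA_character_, length(verts)), verts)
    for (v in setdiff(verts, last_v)) {
      es <- out_edges[[v]]
      last_edge[v] <- if (random) es[sample.int(length(es), 1L)] else es[length(es)]
    }
    # every vertex must reach last_v following last edges
    for (v in setdiff(verts, last_v)) {
      cur <- v
      for (stp in seq_len(length(verts) + 1L)) {
        cur <- last_edge[[cur]]
        if (is.na(cur)) return(NULL)
        if (cur == last_v) break
        if (stp > length(verts)) return(NULL)
      }
      if (cur != last_v) return(NULL)
    }
    last_edge
  }
  last_edge <- NULL
  for (try in 1:100) {
    last_edge <- pick_arborescence(TRUE)
    if (!is.null(last_edge)) break
  }
  if (is.null(last_edge)) {
    # the original sequence's own last-exit edges always form a valid
    # arborescence; fall back to them
    last_edge <- setNames(rep(NA_character_, length(verts)), verts)
    for (v in setdiff(verts, last_v)) {
      idx <- which(from == v)
      last_edge[v] <- to[idx[length(idx)]]
    }
  }
  # order the out-edges: random permutation of the non-last edges, reserved
  # last edge appended
  queue <- lapply(verts, function(v) {
    es <- out_edges[[v]]
    if (v != last_v && !is.na(last_edge[[v]])) {
      drop <- match(last_edge[[v]], es)
      rest <- es[-drop]
      c(if (length(rest)) sample(rest, length(rest)) else character(0), last_edge[[v]])
    } else {
      if (length(es)) sample(es, length(es)) else character(0)
    }
  })
  names(queue) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  walk <- character(n)
  walk[1] <- first_v
  cur <- first_v
  for (i in 2:n) {
    nxt <- queue[[cur]][ptr[[cur]]]
    if (is.na(nxt)) stop("dinucleotide doublet graph is disconnected; cannot shuffle")
    ptr[cur] <- ptr[[cur]] + 1L
    walk[i] <- nxt
    cur <- nxt
  }
  paste(walk, collapse = "")
}

#' Verify a scramble's declared invariants
#'
#' @param native,scrambled Sequences (strings).
#' @param algorithm The algorithm that produced `scrambled`.
#' @return `TRUE` if every declared invariant holds, otherwise `FALSE` with
#'   attribute `"reason"`.
#' @export
check_scramble <- function(native, scrambled, algorithm) {
  algorithm <- match.arg(algorithm, SCRAMBLE_ALGOS)
  fail <- function(reason) structure(FALSE, reason = reason)
  nc <- as_chars(native); sc <- as_chars(scrambled)
  if (length(nc) != length(sc)) return(fail("length changed"))
  switch(algorithm,
    uniform = if (!identical(sort(nc), sort(sc))) return(fail("mono counts changed")),
    dinucleotide = {
      if (!identical(dinuc_counts(paste(nc, collapse = "")),
                     dinuc_counts(paste(sc, collapse = "")))) {
        return(fail("dinucleotide counts changed"))
      }
    },
    codon_order = {
      if (!identical(sort(to_codons(nc)), sort(to_codons(sc)))) {
        return(fail("codon multiset changed"))
      }
    },
    codon_synonymous = {
      if (!identical(translate_seq(paste(nc, collapse = "")),
                     translate_seq(paste(sc, collapse = "")))) {
        return(fail("protein changed"))
      }
    },
    codon_order_dinucleotide = {
      if (!identical(sort(to_codons(nc)), sort(to_codons(sc)))) {
        return(fail("codon multiset changed"))
      }
      dn <- dinuc_counts(paste(nc, collapse = ""))
      ds <- dinuc_counts(paste(sc, collapse = ""))
      if (any(abs(ds - dn) > pmax(1, 0.1 * dn))) return(fail("dinucleotide band exceeded"))
    }
  )
  TRUE
}

#' Mutate a sequence under a parameterised substitution process
#'
#' The number of substitutions is Poisson-distributed around
#' `target * length`; sites are drawn with probability proportional to their
#' total substitution rate, transitions vs transversions split by
#' `ts_tv_ratio`, and rates can be multiplied in specific neighbour contexts
#' (e.g. C->T when followed by G, mimicking CpG methylation-driven
#' mutation).  Context is evaluated on the ancestral (input) sequence.
#'
#' @param seq Ungapped nucleotide string.
#' @param target Expected substitutions per site.
#' @param ts_tv_ratio Transition:transversion rate ratio (per-substitution
#'   rate of the single transition vs each of the two transversions).
#' @param class_filter `"any"`, `"synonymous_only"` or `"nonsynonymous_only"`
#'   (coding filters require in-frame length; unsatisfiable sites are
#'   skipped).
#' @param context_multipliers Optional data frame with columns `from`, `to`,
#'   `side` (`"up"` or `"down"`), `base`, `multiplier`.
#' @param seed Optional RNG seed.
#' @param frame 1-based first codon position for the class filters.
#' @return Mutated string.
#' @export
mutate_seq <- function(seq, target, ts_tv_ratio = 2, class_filter = "any",
                       context_multipliers = NULL, seed = NULL, frame = 1L) {
  class_filter <- match.arg(class_filter, c("any", "synonymous_only", "nonsynonymous_only"))
  stopifnot(target >= 0)
  if (!is.null(seed)) set.seed(seed)
  chars <- as_chars(seq)
  if (any(chars == "-")) stop("mutate requires an ungapped sequence")
  if (target == 0) return(paste(chars, collapse = ""))
  n <- length(chars)
  ok <- chars %in% BASES
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")

  # per-site, per-target-base weights
  w <- matrix(0, n, 4, dimnames = list(NULL, BASES))
  for (b in BASES) {
    idx <- which(ok & chars != b)
    w[idx, b] <- ifelse(ts_of[chars[idx]] == b, ts_tv_ratio, 1)
  }
  if (!is.null(context_multipliers)) {
    cm <- context_multipliers
    stopifnot(all(c("from", "to", "side", "base", "multiplier") %in% names(cm)))
    if (any(cm$multiplier <= 0)) stop("context multipliers must be positive")
    up <- c(NA, chars[-n]); down <- c(chars[-1], NA)
    for (k in seq_len(nrow(cm))) {
      nb <- if (cm$side[k] == "up") up else down
      idx <- which(ok & chars == cm$from[k] & !is.na(nb) & nb == cm$base[k])
      w[idx, cm$to[k]] <- w[idx, cm$to[k]] * cm$multiplier[k]
    }
  }
  rate <- rowSums(w)
  usable <- which(rate > 0)
  if (!length(usable)) return(paste(chars, collapse = ""))
  # per-site hit probability proportional to the site rate, normalised so the
  # expected substitutions/site equal the target; counts are then
  # binomial/Poisson around target * n
  p_hit <- pmin(target * rate[usable] * length(usable) / sum(rate[usable]), 1)
  sites <- usable[runif(length(usable)) < p_hit]
  if (!length(sites)) return(paste(chars, collapse = ""))

  out <- chars
  code <- genetic_code()
  syn_ok <- function(site, to) {
    ci <- (site - frame) %/% 3L
    start <- frame + 3L * ci
    if (start < 1L || start + 2L > n) return(NA)
    cod <- chars[start:(start + 2L)]
    if (!all(cod %in% BASES)) return(NA)
    mut <- cod; mut[site - start + 1L] <- to
    a1 <- code[[paste(cod, collapse = "")]]; a2 <- code[[paste(mut, collapse = "")]]
    if (is.na(a1) || is.na(a2)) return(NA)
    a1 == a2
  }
  for (site in sites) {
    wts <- w[site, ]
    cand <- BASES[wts > 0]
    if (class_filter != "any") {
      keepers <- vapply(cand, function(b) {
        s <- syn_ok(site, b)
        if (is.na(s)) return(FALSE)
        if (class_filter == "synonymous_only") s else !s
      }, logical(1))
      cand <- cand[keepers]
      if (!length(cand)) next                  # unsatisfiable site skipped
    }
    out[site] <- sample(cand, 1L, prob = w[site, cand])
  }
  paste(out, collapse = "")
}
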