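# RNA secondary-structure scanning.  The builtin folding engine is a
# weighted maximum-pairing dynamic programme (GC = 3, AU = 2, GU = 1, with a
# minimum loop length); thermodynamic folders can be attached through a
# simple external-command contract.  On top of it sit the MFED/Z statistics
# against constrained shuffles, the cross-sequence pairing comparison
# (structure conservation) and the covariance scan.

#' Fold a sequence for minimum "energy"
#'
#' @param seq Ungapped nucleotide string (gaps are removed; U and T are
#'   equivalent).
#' @param engine `"builtin"` (weighted Nussinov maximum pairing; energy is
#'   minus the total pair weight) or `"external"` (see
#'   [external_fold_engine()]).
#' @param min_loop Minimum number of unpaired bases enclosed by a pair.
#' @param external_cmd Command template for the external engine: a string
#'   containing `%s`, replaced by the path of a temporary FASTA file; the
#'   command must print lines `ENERGY <float>` and `PAIR <i> <j>` (1-based).
#' @return A `fold_result`: list with `pairs` (m x 2 matrix, i < j, nested,
#'   each position in at most one pair), `energy` and `engine_id`.
#' @export
fold_mfe <- function(seq, engine = "builtin", min_loop = 3L, external_cmd = NULL) {
  engine <- match.arg(engine, c("builtin", "external"))
  chars <- as_chars(seq)
  chars <- chars[chars != "-"]
  chars[chars == "U"] <- "T"
  if (length(chars) < min_loop + 2L) {
    stop("sequence shorter than min_loop + 2 after degapping")
  }
  if (engine == "external") {
    return(external_fold_engine(paste(chars, collapse = ""), external_cmd))
  }
  codes <- match(chars, c("A", "C", "G", "T")) - 1L
  codes[is.na(codes)] <- -1L
  res <- .nussinov_fold(codes, as.integer(min_loop))
  pairs <- res$pairs
  if (nrow(pairs)) pairs <- pairs[order(pairs[, 1]), , drop = FALSE]
  structure(
    list(pairs = pairs, energy = -res$weight, engine_id = "builtin"),
    class = "fold_result"
  )
}

#' @export
print.fold_result <- function(x, ...) {
  cat(sprintf("fold_result [%s]: energy %.4g, %d pair(s)\n",
              x$engine_id, x$energy, nrow(x$pairs)))
  invisible(x)
}

#' Dot-bracket string of a fold
#' @param fold A `fold_result`.
#' @param n Sequence length.
#' @return Character string of `.`, `(` and `)`.
#' @export
dot_bracket <- function(fold, n) {
  db <- rep(".", n)
  if (nrow(fold$pairs)) {
    db[fold$pairs[, 1]] <- "("
    db[fold$pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' Run an external folding engine
#'
#' Contract: the command template receives the path of a one-record FASTA
#' file (via `%s`) and must emit `ENERGY <float>` and zero or more
#' `PAIR <i> <j>` lines on stdout.
#'
#' @param seq Ungapped nucleotide string.
#' @param cmd Command template containing `%s`.
#' @return A `fold_result` with `engine_id = "external"`.
#' @export
external_fold_engine <- function(seq, cmd) {
  if (is.null(cmd) || !nzchar(cmd)) {
    stop("no external folding command configured; use engine = 'builtin' instead")
  }
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa))
  writeLines(c(">query", seq), fa)
  out <- tryCatch(
    system(sprintf(cmd, fa), intern = TRUE),
    error = function(e) stop("external folding engine failed (", conditionMessage(e),
                             "); fall back to engine = 'builtin'")
  )
  en <- grep("^ENERGY\\s", out, value = TRUE)
  if (!length(en)) {
    stop("external engine produced no ENERGY line; fall back to engine = 'builtin'")
  }
  energy <- as.numeric(strsplit(trimws(en[1]), "\\s+")[[1]][2])
  prs <- grep("^PAIR\\s", out, value = TRUE)
  pairs <- if (length(prs)) {
    do.call(rbind, lapply(strsplit(trimws(prs), "\\s+"), function(f) {
      as.integer(c(f[2], f[3]))
    }))
  } else matrix(integer(), 0, 2)
  structure(list(pairs = pairs, energy = energy, engine_id = "external"),
            class = "fold_result")
}

#' Minimum folding energy difference (MFED) and Z score
#'
#' The native MFE is compared with the MFE distribution of sequence-order
#' randomised controls.  `mfed = mfe_native - mean(controls)`; the percent
#' form expresses it relative to the control mean.  Negative `z` means more
#' predicted structure than the controls (lower MFE).
#'
#' @param seq Ungapped nucleotide string.
#' @param engine,min_loop,external_cmd See [fold_mfe()].
#' @param scramble_algorithm Control randomisation (see [scramble()]);
#'   the dinucleotide-preserving shuffle is the default because folding
#'   energies are strongly dinucleotide-dependent.
#' @param n_controls Number of scrambled controls (>= 10 recommended).
#' @param seed RNG seed.
#' @return An `mfed_result`: `mfe_native`, `mfe_controls`, `mfed`,
#'   `mfed_percent`, `z` (NA, flagged, when the control SD is 0),
#'   `scramble_algorithm`, `n_controls`.
#' @export
mfed <- function(seq, engine = "builtin", scramble_algorithm = "dinucleotide",
                 n_controls = 50L, seed = NULL, min_loop = 3L,
                 external_cmd = NULL) {
  if (n_controls < 10L) warning("fewer than 10 controls; MFED/Z will be unstable")
  if (!is.null(seed)) set.seed(seed)
  chars <- as_chars(seq)
  seq <- paste(chars[chars != "-"], collapse = "")
  native <- fold_mfe(seq, engine, min_loop, external_cmd)$energy
  controls <- vapply(seq_len(n_controls), function(k) {
    fold_mfe(scramble(seq, scramble_algorithm), engine, min_loop, external_cmd)$energy
  }, numeric(1))
  mu <- mean(controls); sdev <- sd(controls)
  structure(
    list(
      mfe_native = native, mfe_controls = controls,
      mfed = native - mu,
      mfed_percent = if (abs(mu) > 0) 100 * (mu - native) / abs(mu) else NA_real_,
      z = if (sdev > 0) (native - mu) / sdev else NA_real_,
      z_flag = if (sdev > 0) "ok" else "sd_zero",
      scramble_algorithm = scramble_algorithm, n_controls = n_controls
    ),
    class = "mfed_result"
  )
}

#' @export
print.mfed_result <- function(x, ...) {
  cat(sprintf("MFE native %.4g vs controls %.4g +/- %.4g (n=%d, %s)\n  MFED %.4g (%.3g%%), z = %.3g%s\n",
              x$mfe_native, mean(x$mfe_controls), sd(x$mfe_controls),
              x$n_controls, x$scramble_algorithm, x$mfed,
              x$mfed_percent, x$z,
              if (x$z_flag != "ok") " [sd = 0]" else ""))
  invisible(x)
}

#' Sliding-window MFED scan
#'
#' Per window and per sequence (or tag-group mean), the MFED and Z score of
#' the degapped window sequence.  Windows shorter than `min_loop + 2` after
#' degapping are omitted.
#'
#' @param aln A `tagged_alignment` (or a single string).
#' @param window,step Window and step in alignment columns.
#' @param by_group Average series over tag groups.
#' @param tag_set Tag set used when `by_group = TRUE`.
#' @param rows,columns Optional selection.
#' @inheritParams mfed
#' @return A `scan_profile` with metrics `"mfed"` and `"z"`.
#' @export
mfed_scan <- function(aln, window = 300L, step = 50L, engine = "builtin",
                      scramble_algorithm = "dinucleotide", n_controls = 50L,
                      seed = NULL, min_loop = 3L, by_group = FALSE,
                      tag_set = 1L, rows = NULL, columns = NULL) {
  if (is.character(aln)) aln <- tagged_alignment(c(seq1 = aln))
  if (!is.null(seed)) set.seed(seed)
  sub <- aln[rows, columns]
  width <- aln_length(sub)
  starts <- if (window >= width) 1L else window_starts(width, window, step)
  window <- min(window, width)
  out <- list()
  for (s in starts) {
    cols <- s:(s + window - 1L)
    mid <- s + (window - 1) / 2
    vals <- list()
    for (i in seq_len(n_seq(sub))) {
      w <- gsub("-", "", paste(sub$mat[i, cols], collapse = ""), fixed = TRUE)
      if (nchar(w) < min_loop + 2L) next
      m <- mfed(w, engine, scramble_algorithm, n_controls, min_loop = min_loop)
      vals[[sub$ids[i]]] <- c(mfed = m$mfed, z = m$z)
    }
    if (!length(vals)) next
    vm <- do.call(rbind, vals)
    if (by_group) {
      grp <- get_groups(sub, tag_set)
      for (g in sort(unique(grp))) {
        ids <- intersect(names(grp)[grp == g], rownames(vm))
        if (!length(ids)) next
        for (metric in c("mfed", "z")) {
          out[[length(out) + 1L]] <- data.frame(
            midpoint = mid, series = paste0("group", g), metric = metric,
            value = mean(vm[ids, metric], na.rm = TRUE), stringsAsFactors = FALSE
          )
        }
      }
    } else {
      for (id in rownames(vm)) {
        for (metric in c("mfed", "z")) {
          out[[length(out) + 1L]] <- data.frame(
            midpoint = mid, series = id, metric = metric,
            value = vm[id, metric], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  scan_profile(do.call(rbind, out), window, step)
}

#' Structure conservation across aligned sequences
#'
#' Each selected sequence is degapped, folded, and its base pairs mapped back
#' to alignment columns; predictions are then aggregated per column pair.
#'
#' @param aln A nucleotide `tagged_alignment` (>= 2 sequences).
#' @param engine,min_loop,external_cmd See [fold_mfe()].
#' @param rows,columns Optional selection.
#' @return A `pairing_matrix`: list with `entries` (data frame `col_i`,
#'   `col_j`, `n_predicted`, `n_foldable`, `frequency`), `conservation`
#'   (per-column fraction of foldable sequences pairing there), and
#'   `folds` (per-sequence `fold_result`s in alignment coordinates).
#' @export
structure_dist <- function(aln, engine = "builtin", min_loop = 3L,
                           rows = NULL, columns = NULL, external_cmd = NULL) {
  sub <- aln[rows, columns]
  n <- n_seq(sub)
  if (n < 2L) stop("structure comparison needs at least two sequences")
  L <- aln_length(sub)
  ungapped <- sub$mat != "-"
  pair_pred <- list()
  col_pairing <- matrix(0, n, L)
  for (i in seq_len(n)) {
    map <- which(ungapped[i, ])          # degapped index -> alignment column
    f <- fold_mfe(paste(sub$mat[i, map], collapse = ""), engine, min_loop,
                  external_cmd)
    if (nrow(f$pairs)) {
      ac <- cbind(map[f$pairs[, 1]], map[f$pairs[, 2]])
      pair_pred[[i]] <- ac
      col_pairing[i, as.vector(ac)] <- 1
    } else pair_pred[[i]] <- matrix(integer(), 0, 2)
  }
  all_pairs <- unique(do.call(rbind, pair_pred))
  entries <- if (!is.null(all_pairs) && nrow(all_pairs)) {
    do.call(rbind, lapply(seq_len(nrow(all_pairs)), function(k) {
      ci <- all_pairs[k, 1]; cj <- all_pairs[k, 2]
      foldable <- which(ungapped[, ci] & ungapped[, cj])
      pred <- sum(vapply(foldable, function(i) {
        any(pair_pred[[i]][, 1] == ci & pair_pred[[i]][, 2] == cj)
      }, logical(1)))
      data.frame(col_i = ci, col_j = cj, n_predicted = pred,
                 n_foldable = length(foldable),
                 frequency = pred / length(foldable))
    }))
  } else data.frame(col_i = integer(), col_j = integer(), n_predicted = integer(),
                    n_foldable = integer(), frequency = numeric())
  entries <- entries[order(entries$col_i, entries$col_j), , drop = FALSE]
  conservation <- data.frame(
    column = seq_len(L),
    fraction_pairing = colSums(col_pairing) / pmax(colSums(ungapped), 1L)
  )
  structure(list(entries = entries, conservation = conservation,
                 folds = pair_pred, ids = sub$ids),
            class = "pairing_matrix")
}

#' @export
print.pairing_matrix <- function(x, ...) {
  cat(sprintf("pairing_matrix: %d column pair(s) predicted across %d sequence(s)\n",
              nrow(x$entries), length(x$ids)))
  conserved <- sum(x$entries$frequency == 1)
  cat(sprintf("  fully concordant pairs: %d\n", conserved))
  invisible(x)
}

#' Covariance scan for conserved duplexes
#'
#' Column pairs are covariant when at least `min_covariants` distinct
#' complementary base combinations occur across sequences (Watson-Crick
#' always, G:U optionally), both columns vary, and non-complementary
#' combinations occur in at most a tolerance fraction of sequences.
#' Covariant pairs are extended in both directions while flanking columns
#' pair in at least `1 - tolerance` of sequences; extended duplexes of at
#' least `min_duplex` pairs are reported.
#'
#' @param aln A nucleotide `tagged_alignment` (>= 3 sequences).
#' @param min_covariants Minimum number of distinct complementary
#'   combinations at the seed pair.
#' @param allow_gu Count G:U (G:T) as pairing.
#' @param min_duplex Minimum extended duplex length (base pairs).
#' @param tolerance Maximum tolerated fraction of non-pairing sequences.
#' @param min_sep Minimum separation between paired columns.
#' @param rows,columns Optional selection.
#' @return Data frame with one row per duplex pair position: `duplex`,
#'   `col_i`, `col_j`, `pair_fraction`, `n_combinations`, `covariant`.
#' @export
covariance_scan <- function(aln, min_covariants = 2L, allow_gu = TRUE,
                            min_duplex = 4L, tolerance = 0.1, min_sep = 4L,
                            rows = NULL, columns = NULL) {
  sub <- aln[rows, columns]
  if (n_seq(sub) < 3L) stop("covariance scan needs at least three sequences")
  m <- sub$mat
  L <- ncol(m)
  comp <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE)
  if (allow_gu) comp <- c(comp, GT = TRUE, TG = TRUE)

  pair_stats <- function(i, j) {
    ok <- m[, i] %in% BASES & m[, j] %in% BASES
    if (sum(ok) < 3L) return(NULL)
    combo <- paste0(m[ok, i], m[ok, j])
    is_c <- !is.na(comp[combo])
    list(
      frac = mean(is_c),
      n_comp_combos = length(unique(combo[is_c])),
      variable = length(unique(m[ok, i])) > 1L && length(unique(m[ok, j])) > 1L
    )
  }
  is_covariant <- function(st) {
    !is.null(st) && st$variable && st$n_comp_combos >= min_covariants &&
      (1 - st$frac) <= tolerance
  }
  pairs_well <- function(st) !is.null(st) && st$frac >= 1 - tolerance

  seeds <- list()
  for (i in seq_len(L - min_sep - 1L)) {
    for (j in (i + min_sep + 1L):L) {
      st <- pair_stats(i, j)
      if (is_covariant(st)) seeds[[length(seeds) + 1L]] <- c(i, j)
    }
  }
  out <- list(); seen <- character(0)
  for (seed_pair in seeds) {
    i0 <- seed_pair[1]; j0 <- seed_pair[2]
    duplex <- list(c(i0, j0))
    i <- i0 - 1L; j <- j0 + 1L            # extend outward
    while (i >= 1L && j <= L && pairs_well(pair_stats(i, j))) {
      duplex <- c(list(c(i, j)), duplex)
      i <- i - 1L; j <- j + 1L
    }
    i <- i0 + 1L; j <- j0 - 1L            # extend inward
    while (j - i > min_sep && pairs_well(pair_stats(i, j))) {
      duplex <- c(duplex, list(c(i, j)))
      i <- i + 1L; j <- j - 1L
    }
    if (length(duplex) < min_duplex) next
    key <- paste(vapply(duplex, paste, character(1), collapse = ":"), collapse = ";")
    if (key %in% seen) next
    seen <- c(seen, key)
    did <- length(out) + 1L
    out[[did]] <- do.call(rbind, lapply(duplex, function(p) {
      st <- pair_stats(p[1], p[2])
      data.frame(duplex = did, col_i = p[1], col_j = p[2],
                 pair_fraction = st$frac, n_combinations = st$n_comp_combos,
                 covariant = is_covariant(st))
    }))
  }
  if (!length(out)) {
    return(data.frame(duplex = integer(), col_i = integer(), col_j = integer(),
                      pair_fraction = numeric(), n_combinations = integer(),
                      covariant = logical()))
  }
  do.call(rbind, out)
}
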