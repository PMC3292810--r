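# Sliding-window scans over alignments.  All scans share the scan_profile
# container: a long data frame of (midpoint, series, metric, value) plus
# window/step attributes, writable as TSV and plottable.

scan_profile <- function(df, window, step) {
  stopifnot(all(c("midpoint", "series", "metric", "value") %in% names(df)))
  structure(df, window = window, step = step,
            class = c("scan_profile", "data.frame"))
}

window_starts <- function(width, window, step) {
  if (window > width) stop("window (", window, ") exceeds selection width (", width, ")")
  starts <- seq(1L, width - window + 1L, by = step)
  starts
}

#' @export
print.scan_profile <- function(x, ...) {
  cat(sprintf("scan_profile: window %d, step %d, %d point(s), series: %s\n",
              attr(x, "window"), attr(x, "step"), nrow(x),
              paste(unique(x$series), collapse = ", ")))
  print.data.frame(head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Plot a scan profile
#'
#' One line per series (per metric panel) against window midpoints.
#' @param x A `scan_profile`.
#' @param metric Which metric to plot (default: first).
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, `x`.
#' @export
plot.scan_profile <- function(x, metric = NULL, ...) {
  df <- as.data.frame(x)
  if (is.null(metric)) metric <- df$metric[1]
  df <- df[df$metric == metric, ]
  wide <- tapply(df$value, list(df$midpoint, df$series), mean)
  graphics::matplot(as.numeric(rownames(wide)), wide, type = "l", lty = 1,
                    xlab = "alignment position (window midpoint)", ylab = metric, ...)
  graphics::legend("topright", legend = colnames(wide), lty = 1,
                   col = seq_len(ncol(wide)), bty = "n", cex = 0.8)
  invisible(x)
}

#' Write a scan profile (or any table) as TSV
#'
#' @param x A data frame.
#' @param path Output path.
#' @param provenance Optional character vector written as `#`-prefixed header
#'   lines (command line, seed, version).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Sliding-window divergence scan
#'
#' Mean pairwise distance per window, for all pairs, within tag groups, or
#' between tag groups (one series per group pair).
#'
#' @param aln A `tagged_alignment`.
#' @param model Distance model (see [nt_distance()] / [aa_distance()]).
#' @param window,step Window width and step, in alignment columns.
#' @param mode `"all_pairs"`, `"within_groups"` or `"between_groups"`.
#' @param tag_set Tag set used for group modes.
#' @param rows,columns Optional selection.
#' @return A `scan_profile` (metric `"distance"`).  Windows with no usable
#'   site in a series are omitted with a message; single-member groups are
#'   dropped from `within_groups` with a warning.
#' @export
distance_scan <- function(aln, model = "p", window = 300L, step = 30L,
                          mode = "all_pairs", tag_set = 1L,
                          rows = NULL, columns = NULL) {
  mode <- match.arg(mode, c("all_pairs", "within_groups", "between_groups"))
  sub <- aln[rows, columns]
  starts <- window_starts(aln_length(sub), window, step)
  fun <- if (sub$alphabet == "nucleotide") nt_distance else aa_distance

  pair_sets <- list()
  if (mode == "all_pairs") {
    if (n_seq(sub) < 2L) stop("need at least two sequences")
    pair_sets[["all"]] <- t(combn(n_seq(sub), 2L))
  } else {
    grp <- get_groups(sub, tag_set)
    if (length(unique(grp)) < 1L) stop("no tagged groups in tag set ", tag_set)
    idx <- split(match(names(grp), sub$ids), grp)
    if (mode == "within_groups") {
      for (g in names(idx)) {
        if (length(idx[[g]]) < 2L) {
          warning("group ", g, " has a single member; series omitted")
          next
        }
        pair_sets[[paste0("group", g)]] <- t(combn(idx[[g]], 2L))
      }
    } else {
      gs <- names(idx)
      if (length(gs) < 2L) stop("between_groups needs at least two groups")
      for (i in 1:(length(gs) - 1)) for (j in (i + 1):length(gs)) {
        pair_sets[[paste0("group", gs[i], "-group", gs[j])]] <-
          as.matrix(expand.grid(idx[[gs[i]]], idx[[gs[j]]]))
      }
    }
    if (!length(pair_sets)) stop("no usable group series")
  }

  out <- list()
  for (s in starts) {
    cols <- s:(s + window - 1L)
    for (series in names(pair_sets)) {
      prs <- pair_sets[[series]]
      vals <- apply(prs, 1, function(ij) {
        fun(sub$mat[ij[1], cols], sub$mat[ij[2], cols], model)$value
      })
      vals <- vals[is.finite(vals)]
      if (!length(vals)) {
        message("window at ", s, ": no usable sites for series ", series, "; point omitted")
        next
      }
      out[[length(out) + 1L]] <- data.frame(
        midpoint = s + (window - 1) / 2, series = series,
        metric = "distance", value = mean(vals), stringsAsFactors = FALSE
      )
    }
  }
  scan_profile(do.call(rbind, out), window, step)
}

# compile an IUPAC motif into a list of allowed-base sets
compile_motif <- function(motif) {
  chars <- strsplit(toupper(motif), "")[[1]]
  if (!length(chars)) stop("motif must be non-empty")
  sets <- iupac_sets()
  lapply(seq_along(chars), function(i) {
    s <- sets[[chars[i]]]
    if (is.null(s)) stop("invalid IUPAC symbol '", chars[i], "' at motif position ", i)
    s
  })
}

#' Count motif occurrences per sequence
#'
#' @param seq Nucleotide string (may contain gaps).
#' @param motif IUPAC motif (U allowed).  Overlapping matches are counted;
#'   a gap anywhere in the footprint breaks the match.
#' @return Integer count.
#' @export
count_motif <- function(seq, motif) {
  pat <- compile_motif(motif)
  chars <- as_chars(seq)
  chars[chars == "U"] <- "T"
  m <- length(pat); n <- length(chars)
  if (n < m) return(0L)
  hit <- rep(TRUE, n - m + 1L)
  for (k in seq_len(m)) {
    hit <- hit & chars[k:(n - m + k)] %in% pat[[k]]
  }
  sum(hit)
}

#' Sliding-window motif scan
#'
#' Per window and per sequence, the number of (possibly overlapping) motif
#' matches whose footprint starts inside the window.
#'
#' @inheritParams distance_scan
#' @param motif IUPAC motif string (U allowed).
#' @return A `scan_profile` (metric `"count"`, one series per sequence).
#' @export
motif_scan <- function(aln, motif, window = 300L, step = 30L,
                       rows = NULL, columns = NULL) {
  sub <- aln[rows, columns]
  compile_motif(motif)   # validate before scanning
  starts <- window_starts(aln_length(sub), window, step)
  out <- list()
  for (s in starts) {
    cols <- s:(s + window - 1L)
    for (i in seq_len(n_seq(sub))) {
      out[[length(out) + 1L]] <- data.frame(
        midpoint = s + (window - 1) / 2, series = sub$ids[i], metric = "count",
        value = count_motif(paste(sub$mat[i, cols], collapse = ""), motif),
        stringsAsFactors = FALSE
      )
    }
  }
  scan_profile(do.call(rbind, out), window, step)
}

#' Similarity dot-plot
#'
#' All window placements `(i, j)` between two sequences whose similarity score
#' meets `min_matches`.  Nucleotide scoring: identities count 1, transitions
#' count `transition_score`.  Amino-acid scoring: identities count 1, or
#' matrix scores when `matrix_table` is given.  With `kind = "aa"` and
#' nucleotide input, sequences are first translated in the stated frames.
#'
#' @param a,b Sequences (strings); `b` defaults to `a` (self-comparison).
#' @param window Window length (residues of the compared alphabet).
#' @param min_matches Minimum window score to report.
#' @param kind `"nt"` or `"aa"`.
#' @param transition_score Fractional score for transitions, in `[0, 1]`.
#' @param frame_a,frame_b Reading frames (0-2) used when translating.
#' @param matrix_table Optional similarity matrix for amino-acid scoring.
#' @return Data frame with columns `pos_a`, `pos_b` (window start positions,
#'   1-based) and `score`.
#' @export
similarity_dotplot <- function(a, b = a, window = 10L, min_matches = window,
                               kind = "nt", transition_score = 0,
                               frame_a = 0L, frame_b = 0L, matrix_table = NULL) {
  kind <- match.arg(kind, c("nt", "aa"))
  stopifnot(window >= 1L, transition_score >= 0, transition_score <= 1)
  ca <- as_chars(a); cb <- as_chars(b)
  if (kind == "aa" && all(c(ca, cb) %in% c("A", "C", "G", "T", "U", "-", "N"))) {
    ca <- as_chars(translate_seq(paste(ca, collapse = ""), frame = frame_a))
    cb <- as_chars(translate_seq(paste(cb, collapse = ""), frame = frame_b))
  }
  na <- length(ca); nb <- length(cb)
  max_score <- if (kind == "aa" && !is.null(matrix_table)) {
    window * max(matrix_table)
  } else window
  if (min_matches > max_score) {
    warning("min_matches exceeds the maximum attainable window score; empty result")
    return(data.frame(pos_a = integer(), pos_b = integer(), score = numeric()))
  }
  score_pos <- function(x, y) {
    if (kind == "nt") {
      s <- as.numeric(x == y & x %in% c("A", "C", "G", "T"))
      s[x != y & is_transition(x, y)] <- transition_score
    } else if (is.null(matrix_table)) {
      s <- as.numeric(x == y & x != "-" & x != "X")
    } else {
      s <- rep(0, length(x))
      ok <- x %in% rownames(matrix_table) & y %in% colnames(matrix_table)
      s[ok] <- matrix_table[cbind(x[ok], y[ok])]
    }
    s
  }
  out <- list()
  for (d in (-(na - window)):(nb - window)) {   # diagonal offset j - i
    i0 <- max(1L, 1L - d); j0 <- i0 + d
    len <- min(na - i0, nb - j0) + 1L
    if (len < window) next
    s <- score_pos(ca[i0:(i0 + len - 1L)], cb[j0:(j0 + len - 1L)])
    win <- as.numeric(stats::filter(s, rep(1, window), sides = 1))
    win <- win[window:len]
    keep <- which(win >= min_matches - 1e-9)
    if (length(keep)) {
      out[[length(out) + 1L]] <- data.frame(
        pos_a = i0 + keep - 1L, pos_b = j0 + keep - 1L, score = win[keep]
      )
    }
  }
  if (!length(out)) return(data.frame(pos_a = integer(), pos_b = integer(), score = numeric()))
  do.call(rbind, out)
}
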