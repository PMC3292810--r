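# The tagged_alignment container: a gapped residue matrix plus four
# independent tag sets that classify rows into groups 1..26 (0 = unassigned),
# mirroring the grouped-alignment model used throughout the scanning methods.

N_TAG_SETS <- 4L
MAX_GROUP <- 26L

#' Construct a tagged alignment
#'
#' The central data container: an aligned set of sequences (equal gapped
#' length) together with up to four independent tag sets, each assigning every
#' row to one of 26 groups (0 = unassigned).  Tag sets let the same alignment
#' be partitioned along independent axes (e.g. genotype, host, year).
#'
#' @param seqs Character vector of aligned sequences (strings, one per row),
#'   or a character matrix (rows = sequences, columns = alignment positions).
#' @param ids Unique sequence identifiers; defaults to names of `seqs`.
#' @param alphabet `"nucleotide"` or `"amino_acid"`; auto-detected if `NULL`.
#' @param descriptions Optional free-text descriptions, one per row.
#' @param pad If `TRUE`, right-pad unequal-length input with gaps (the
#'   alignment is then flagged as padded) instead of erroring.
#' @return An object of class `tagged_alignment`.
#' @export
tagged_alignment <- function(seqs, ids = NULL, alphabet = NULL,
                             descriptions = NULL, pad = FALSE) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
    if (is.null(ids)) ids <- rownames(seqs)
  } else {
    if (is.null(ids)) ids <- names(seqs)
    seqs <- toupper(as.character(seqs))
    lens <- nchar(seqs)
    padded <- FALSE
    if (length(unique(lens)) > 1L) {
      if (!pad) {
        stop("sequences have unequal lengths (", paste(range(lens), collapse = "-"),
             "); use pad = TRUE to right-pad with gaps")
      }
      seqs <- vapply(seqs, function(s) {
        paste0(s, strrep("-", max(lens) - nchar(s)))
      }, character(1))
      padded <- TRUE
    }
    mat <- do.call(rbind, strsplit(seqs, ""))
    attr(mat, "padded") <- padded
  }
  n <- nrow(mat)
  if (n < 1L) stop("alignment must contain at least one sequence")
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("sequence ids must be unique")
  if (length(ids) != n) stop("ids must match the number of sequences")
  if (is.null(descriptions)) descriptions <- rep("", n)

  # normalise U -> T for nucleotide data, remembering the input convention
  u_as_t <- rep(FALSE, n)
  if (is.null(alphabet)) alphabet <- detect_alphabet(mat)
  if (alphabet == "nucleotide") {
    u_as_t <- apply(mat == "U", 1, any)
    mat[mat == "U"] <- "T"
    bad <- setdiff(unique(as.vector(mat)), c(names(iupac_sets()), "-", "?"))
    if (length(bad)) {
      stop("invalid nucleotide symbol(s): ", paste(bad, collapse = ", "))
    }
  } else {
    valid <- c(strsplit("ACDEFGHIKLMNPQRSTVWYXBZJUO*", "")[[1]], "-", "?")
    bad <- setdiff(unique(as.vector(mat)), valid)
    if (length(bad)) {
      stop("invalid amino-acid symbol(s): ", paste(bad, collapse = ", "))
    }
  }
  rownames(mat) <- ids

  structure(
    list(
      mat = mat,
      ids = ids,
      descriptions = descriptions,
      alphabet = alphabet,
      tags = matrix(0L, n, N_TAG_SETS, dimnames = list(ids, NULL)),
      group_meta = data.frame(
        tag_set = integer(), group = integer(),
        label = character(), annotation = character(),
        stringsAsFactors = FALSE
      ),
      features = setNames(vector("list", n), ids),
      u_as_t = u_as_t,
      padded = isTRUE(attr(mat, "padded"))
    ),
    class = "tagged_alignment"
  )
}

detect_alphabet <- function(mat) {
  res <- as.vector(mat)
  res <- res[!res %in% c("-", "?", "N", "X")]
  if (!length(res)) return("nucleotide")
  frac_nt <- mean(res %in% c("A", "C", "G", "T", "U"))
  if (frac_nt >= 0.9) "nucleotide" else "amino_acid"
}

#' @export
print.tagged_alignment <- function(x, ...) {
  cat(sprintf(
    "tagged_alignment: %d %s sequence(s) x %d column(s)\n",
    n_seq(x), x$alphabet, aln_length(x)
  ))
  tagged <- colSums(x$tags > 0L)
  for (s in which(tagged > 0L)) {
    cat(sprintf(
      "  tag set %d: %d tagged row(s) in %d group(s)\n",
      s, tagged[s], length(unique(x$tags[x$tags[, s] > 0L, s]))
    ))
  }
  invisible(x)
}

#' Number of sequences in an alignment
#' @param aln A `tagged_alignment`.
#' @return Integer.
#' @export
n_seq <- function(aln) nrow(aln$mat)

#' Alignment length (gapped columns)
#' @param aln A `tagged_alignment`.
#' @return Integer.
#' @export
aln_length <- function(aln) ncol(aln$mat)

#' Sequences as character strings
#' @param aln A `tagged_alignment`.
#' @param rows Optional row indices or ids.
#' @param degap Drop gap characters if `TRUE`.
#' @return Named character vector.
#' @export
aln_strings <- function(aln, rows = NULL, degap = FALSE) {
  rows <- resolve_rows(aln, rows)
  out <- apply(aln$mat[rows, , drop = FALSE], 1, paste, collapse = "")
  if (degap) out <- gsub("-", "", out, fixed = TRUE)
  out
}

resolve_rows <- function(aln, rows) {
  if (is.null(rows)) return(seq_len(n_seq(aln)))
  if (is.character(rows)) {
    idx <- match(rows, aln$ids)
    if (anyNA(idx)) stop("unknown sequence id(s): ", paste(rows[is.na(idx)], collapse = ", "))
    return(idx)
  }
  rows <- as.integer(rows)
  if (any(rows < 1L | rows > n_seq(aln))) stop("row index out of range")
  rows
}

resolve_columns <- function(aln, columns) {
  if (is.null(columns)) return(seq_len(aln_length(aln)))
  columns <- as.integer(columns)
  if (any(columns < 1L | columns > aln_length(aln))) stop("column index out of range")
  columns
}

#' Subset an alignment
#'
#' Row/column subsetting keeps tags, group metadata and features in step.
#' Columns are 1-based inclusive alignment coordinates.
#'
#' @param x A `tagged_alignment`.
#' @param i Row indices or ids.
#' @param j Column indices.
#' @param ... Ignored.
#' @return A `tagged_alignment`.
#' @export
`[.tagged_alignment` <- function(x, i = NULL, j = NULL, ...) {
  i <- resolve_rows(x, i)
  j <- resolve_columns(x, j)
  out <- x
  out$mat <- x$mat[i, j, drop = FALSE]
  out$ids <- x$ids[i]
  out$descriptions <- x$descriptions[i]
  out$tags <- x$tags[i, , drop = FALSE]
  out$features <- x$features[i]
  out$u_as_t <- x$u_as_t[i]
  out
}

#' Assign rows to a tag group
#'
#' @param aln A `tagged_alignment`.
#' @param tag_set Tag set index (1-4).
#' @param rows Row indices or sequence ids.
#' @param group Group number 0-26 (0 clears the assignment).
#' @param label Optional group label stored in the group metadata.
#' @param annotation Optional free-text annotation for the group.
#' @return The updated alignment.
#' @export
set_tags <- function(aln, tag_set, rows, group, label = NULL, annotation = NULL) {
  tag_set <- as.integer(tag_set)
  if (tag_set < 1L || tag_set > N_TAG_SETS) stop("tag_set must be in 1..", N_TAG_SETS)
  group <- as.integer(group)
  if (group < 0L || group > MAX_GROUP) stop("group must be in 0..", MAX_GROUP)
  aln$tags[resolve_rows(aln, rows), tag_set] <- group
  if (!is.null(label) || !is.null(annotation)) {
    keep <- !(aln$group_meta$tag_set == tag_set & aln$group_meta$group == group)
    aln$group_meta <- rbind(
      aln$group_meta[keep, , drop = FALSE],
      data.frame(
        tag_set = tag_set, group = group,
        label = if (is.null(label)) "" else label,
        annotation = if (is.null(annotation)) "" else annotation,
        stringsAsFactors = FALSE
      )
    )
  }
  aln
}

#' Group membership for one tag set
#'
#' @param aln A `tagged_alignment`.
#' @param tag_set Tag set index (1-4).
#' @param drop_unassigned Drop rows with group 0.
#' @return Named integer vector (names = sequence ids) of group numbers.
#' @export
get_groups <- function(aln, tag_set = 1L, drop_unassigned = TRUE) {
  g <- setNames(aln$tags[, as.integer(tag_set)], aln$ids)
  if (drop_unassigned) g <- g[g > 0L]
  g
}
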