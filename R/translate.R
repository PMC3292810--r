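# Translation of nucleotide alignments.  Codons containing gaps or ambiguity
# codes translate to 'X'; a trailing partial codon is dropped.

#' Translate a nucleotide sequence
#'
#' @param seq Character string (gapped or ungapped nucleotides).
#' @param frame Reading-frame offset 0, 1 or 2.
#' @param reverse_complement Translate the reverse complement instead.
#' @return Amino-acid string; codons containing a gap or ambiguity code give
#'   `"X"`, stop codons give `"*"`.
#' @export
translate_seq <- function(seq, frame = 0L, reverse_complement = FALSE) {
  if (reverse_complement) seq <- reverse_complement(seq)
  chars <- strsplit(toupper(seq), "")[[1]]
  chars[chars == "U"] <- "T"
  frame <- as.integer(frame)
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2")
  if (frame > 0L) chars <- chars[-seq_len(frame)]
  ncod <- length(chars) %/% 3L
  if (ncod == 0L) return("")
  chars <- chars[seq_len(3L * ncod)]
  codons <- paste0(chars[c(TRUE, FALSE, FALSE)],
                   chars[c(FALSE, TRUE, FALSE)],
                   chars[c(FALSE, FALSE, TRUE)])
  aa <- translate_codons(codons)
  aa[is.na(aa)] <- "X"      # gap or ambiguity in codon
  paste(aa, collapse = "")
}

#' Translate a nucleotide alignment
#'
#' Each row is translated in place (column-wise codons), so the result is an
#' amino-acid alignment in the same coordinate system / 3.
#'
#' @param aln A nucleotide `tagged_alignment`.
#' @inheritParams translate_seq
#' @return An amino-acid `tagged_alignment`; tags are carried over.
#' @export
translate_alignment <- function(aln, frame = 0L, reverse_complement = FALSE) {
  stopifnot(inherits(aln, "tagged_alignment"))
  if (aln$alphabet != "nucleotide") stop("translate requires a nucleotide alignment")
  seqs <- vapply(aln_strings(aln), translate_seq, character(1),
                 frame = frame, reverse_complement = reverse_complement)
  # all-gap codons ("---") give X too under the gap rule; keep as produced
  out <- tagged_alignment(setNames(seqs, aln$ids), alphabet = "amino_acid",
                          descriptions = aln$descriptions)
  out$tags <- aln$tags
  out$group_meta <- aln$group_meta
  out
}
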