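# Genetic-code and IUPAC tables.  The standard code is derived once from
# seqinr's translation machinery and cached; degeneracy tables and synonymous
# families are derived from it.

#' IUPAC nucleotide ambiguity sets
#'
#' Mapping from each IUPAC nucleotide symbol (T and U both accepted) to the
#' set of unambiguous bases it denotes.
#' @return Named list of character vectors.
#' @export
iupac_sets <- function() {
  list(
    A = "A", C = "C", G = "G", T = "T", U = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T")
  )
}

# reverse lookup: sorted base set -> ambiguity symbol
iupac_code_for <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  codes <- c(
    A = "A", C = "C", G = "G", T = "T",
    AG = "R", CT = "Y", CG = "S", AT = "W", GT = "K", AC = "M",
    CGT = "B", AGT = "D", ACT = "H", ACG = "V", ACGT = "N"
  )
  unname(codes[key])
}

#' The standard genetic code
#'
#' @return Named character vector mapping the 64 codons (T alphabet) to
#'   one-letter amino acids, with `"*"` for stop codons.
#' @export
genetic_code <- function() {
  if (is.null(.seqscan$code)) {
    bases <- c("T", "C", "A", "G")
    codons <- apply(expand.grid(bases, bases, bases)[, 3:1], 1, paste, collapse = "")
    aa <- vapply(codons, function(cd) {
      seqinr::translate(strsplit(tolower(cd), "")[[1]])
    }, character(1))
    .seqscan$code <- setNames(aa, codons)
  }
  .seqscan$code
}

# sense codons grouped into synonymous families
codon_families <- function() {
  if (is.null(.seqscan$families)) {
    code <- genetic_code()
    sense <- code[code != "*"]
    .seqscan$families <- split(names(sense), sense)
  }
  .seqscan$families
}

# codon -> amino acid, vectorised; invalid codons -> NA
translate_codons <- function(codons) {
  code <- genetic_code()
  unname(code[codons])
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Reverse complement of a nucleotide sequence
#'
#' Gaps are preserved; ambiguity codes are complemented (e.g. R -> Y).
#' @param x Character string (or vector of single characters).
#' @return Character string.
#' @export
reverse_complement <- function(x) {
  chars <- if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else x
  comp <- c(
    A = "T", C = "G", G = "C", T = "A", U = "A",
    R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
    B = "V", D = "H", H = "D", V = "B", N = "N", `-` = "-"
  )
  out <- comp[toupper(chars)]
  out[is.na(out)] <- "N"
  paste(rev(out), collapse = "")
}
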