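# Alignment readers/writers.  FASTA/CLUSTAL/PHYLIP reading is delegated to
# seqinr, NEXUS to ape; PHYLIP/CLUSTAL writers are implemented here to honour
# the strict-id truncation contract.  GenBank/EMBL flat files are parsed
# locally (sequence + feature table import, read-only).

#' Read a multiple alignment
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"fasta"`, `"phylip"`, `"nexus"`,
#'   `"clustal"`, `"genbank"`, `"embl"`.  `"auto"` sniffs the first
#'   non-blank line.
#' @param alphabet Optional `"nucleotide"`/`"amino_acid"` override.
#' @param tags Optional path to a sidecar tag TSV (see [read_tags()]); when
#'   `NULL`, `<path>.tags` is loaded if it exists.
#' @return A [tagged_alignment()].  Unequal-length input (e.g. unaligned
#'   GenBank records) is right-padded with gaps and flagged via `$padded`.
#' @export
read_alignment <- function(path, format = "auto", alphabet = NULL, tags = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  format <- match.arg(format, c("auto", "fasta", "phylip", "nexus", "clustal",
                                "genbank", "embl"))
  if (format == "auto") format <- sniff_format(path)
  aln <- switch(format,
    fasta = read_aln_seqinr(path, "fasta"),
    clustal = read_aln_clustal(path),
    phylip = read_aln_phylip(path),
    nexus = read_aln_nexus(path),
    genbank = read_flatfile(path, "genbank"),
    embl = read_flatfile(path, "embl")
  )
  if (!is.null(alphabet)) {
    aln <- tagged_alignment(aln$mat, ids = aln$ids, alphabet = alphabet,
                            descriptions = aln$descriptions)
  }
  tag_path <- if (is.null(tags)) paste0(path, ".tags") else tags
  if (file.exists(tag_path)) aln <- read_tags(aln, tag_path)
  aln
}

sniff_format <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("cannot read '", path, "': file is empty (line 1)")
  first <- lines[[1]]
  if (grepl("^>", first)) return("fasta")
  if (grepl("^CLUSTAL", first, ignore.case = TRUE)) return("clustal")
  if (grepl("^#NEXUS", first, ignore.case = TRUE)) return("nexus")
  if (grepl("^LOCUS", first)) return("genbank")
  if (grepl("^ID ", first)) return("embl")
  if (grepl("^\\s*\\d+\\s+\\d+\\s*$", first)) return("phylip")
  stop("cannot auto-detect format of '", path, "' (line 1: '",
       substr(first, 1, 40), "')")
}

read_aln_seqinr <- function(path, fmt) {
  a <- tryCatch(
    seqinr::read.alignment(path, format = fmt, forceToLower = FALSE),
    error = function(e) stop("failed to parse '", path, "' as ", fmt, ": ",
                             conditionMessage(e))
  )
  seqs <- toupper(unlist(a$seq))
  tagged_alignment(setNames(seqs, a$nam), pad = TRUE)
}

# CLUSTAL blocks: "name  residues" lines, conservation lines start with a
# space.  (Parsed here because single-block CLUSTAL files are legal; package
# readers that infer the name column from repeated blocks reject them.)
read_aln_clustal <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!grepl("^CLUSTAL", lines[1], ignore.case = TRUE)) {
    stop("failed to parse '", path, "' as clustal: missing CLUSTAL header (line 1)")
  }
  seqs <- list()
  for (line in lines[-1]) {
    if (!nzchar(trimws(line)) || grepl("^\\s", line)) next   # blank/conservation
    m <- regexec("^(\\S+)\\s+(\\S+)\\s*\\d*$", line)[[1]]
    if (m[1] == -1) stop("failed to parse '", path, "' as clustal: bad line '",
                         substr(line, 1, 40), "'")
    id <- regmatches(line, regexec("^(\\S+)", line))[[1]][1]
    res <- strsplit(trimws(sub("^\\S+", "", line)), "\\s+")[[1]][1]
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], res)
  }
  if (!length(seqs)) stop("failed to parse '", path, "' as clustal: no sequences")
  tagged_alignment(unlist(seqs))
}

# PHYLIP, sequential or interleaved, auto-detected from the block structure.
read_aln_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- regmatches(lines[1], regexec("^\\s*(\\d+)\\s+(\\d+)", lines[1]))[[1]]
  if (length(hdr) < 3) stop("failed to parse '", path, "' as phylip: bad header (line 1)")
  n <- as.integer(hdr[2]); len <- as.integer(hdr[3])
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (length(body) < n) stop("failed to parse '", path, "' as phylip: too few sequence lines")
  parse_first <- function(line) {
    # id = first token (relaxed PHYLIP); remainder = residues
    m <- regexec("^\\s*(\\S+)\\s*(.*)$", line)[[1]]
    id <- regmatches(line, regexec("^\\s*(\\S+)", line))[[1]][2]
    rest <- sub("^\\s*\\S+\\s*", "", line)
    list(id = id, res = gsub("[[:space:]]", "", rest))
  }
  first <- lapply(body[seq_len(n)], parse_first)
  ids <- vapply(first, `[[`, character(1), "id")
  seqs <- vapply(first, `[[`, character(1), "res")
  extra <- body[-seq_len(n)]
  i <- 0L
  for (line in extra) {
    i <- i %% n + 1L
    seqs[i] <- paste0(seqs[i], gsub("[[:space:]]", "", line))
  }
  if (any(nchar(seqs) != len)) {
    stop("failed to parse '", path, "' as phylip: sequence length mismatch ",
         "(expected ", len, ", got ", paste(unique(nchar(seqs)), collapse = "/"), ")")
  }
  tagged_alignment(setNames(seqs, ids))
}

read_aln_nexus <- function(path) {
  x <- tryCatch(ape::read.nexus.data(path),
                error = function(e) stop("failed to parse '", path, "' as nexus: ",
                                         conditionMessage(e)))
  seqs <- vapply(x, function(s) paste(toupper(s), collapse = ""), character(1))
  tagged_alignment(seqs)
}

# Minimal GenBank/EMBL flat-file reader: ids, definition, ORIGIN sequence and
# the feature table (key, location string, qualifier list) per record.
read_flatfile <- function(path, flavour) {
  lines <- readLines(path, warn = FALSE)
  recs <- split(lines, cumsum(grepl(if (flavour == "genbank") "^LOCUS" else "^ID ", lines)))
  recs <- recs[names(recs) != "0"]
  if (!length(recs)) stop("failed to parse '", path, "' as ", flavour,
                          ": no record header found (line 1)")
  parsed <- lapply(recs, parse_flat_record, flavour = flavour)
  ids <- vapply(parsed, `[[`, character(1), "id")
  seqs <- vapply(parsed, `[[`, character(1), "seq")
  if (any(!nzchar(seqs))) stop("record without sequence data in '", path, "'")
  aln <- tagged_alignment(setNames(seqs, ids),
                          descriptions = vapply(parsed, `[[`, character(1), "desc"),
                          pad = TRUE)
  aln$features <- setNames(lapply(parsed, `[[`, "features"), ids)
  aln
}

parse_flat_record <- function(lines, flavour) {
  if (flavour == "genbank") {
    id <- strsplit(trimws(sub("^LOCUS", "", lines[1])), "\\s+")[[1]][1]
    desc_i <- grep("^DEFINITION", lines)
    desc <- if (length(desc_i)) trimws(sub("^DEFINITION", "", lines[desc_i[1]])) else ""
    feat_start <- grep("^FEATURES", lines)
    seq_start <- grep("^ORIGIN", lines)
    feat_lines <- if (length(feat_start) && length(seq_start)) {
      lines[(feat_start[1] + 1L):(seq_start[1] - 1L)]
    } else character()
    seq_lines <- if (length(seq_start)) lines[(seq_start[1] + 1L):length(lines)] else character()
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    res <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    feats <- parse_feature_table(feat_lines, key_end = 20L)
  } else {
    id <- strsplit(trimws(sub("^ID", "", lines[1])), "[;\\s]+")[[1]][1]
    desc_i <- grep("^DE ", lines)
    desc <- if (length(desc_i)) trimws(sub("^DE ", "", lines[desc_i[1]])) else ""
    ft <- grep("^FT ", lines, value = TRUE)
    feat_lines <- substring(ft, 3L)
    sq <- grep("^SQ", lines)
    seq_lines <- if (length(sq)) lines[(sq[1] + 1L):length(lines)] else character()
    seq_lines <- seq_lines[!grepl("^//", seq_lines)]
    res <- toupper(gsub("[^A-Za-z]", "", gsub("[0-9]", "", paste(seq_lines, collapse = ""))))
    feats <- parse_feature_table(feat_lines, key_end = 18L)   # FT prefix stripped

  }
  list(id = id, desc = desc, seq = res, features = feats)
}

parse_feature_table <- function(lines, key_end) {
  feats <- list()
  cur <- NULL
  for (line in lines) {
    if (!nzchar(trimws(line))) next
    key <- trimws(substr(line, 1L, key_end))
    rest <- trimws(substring(line, key_end + 1L))
    if (nzchar(key)) {            # new feature
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      cur <- list(key = key, location = rest, qualifiers = list())
    } else if (!is.null(cur)) {
      if (grepl("^/", rest)) {    # qualifier
        q <- sub("^/", "", rest)
        kv <- strsplit(q, "=", fixed = TRUE)[[1]]
        val <- if (length(kv) > 1) gsub('^"|"$', "", paste(kv[-1], collapse = "=")) else TRUE
        cur$qualifiers[[kv[1]]] <- val
      } else {                    # location continuation
        cur$location <- paste0(cur$location, rest)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
  feats
}

#' Write a multiple alignment
#'
#' @param aln A `tagged_alignment`.
#' @param path Output file.
#' @param format `"fasta"`, `"phylip"`, `"nexus"` or `"clustal"`.
#' @param tags If `TRUE` and any tags are assigned, a sidecar TSV
#'   `<path>.tags` is written alongside (see [write_tags()]).
#' @param interleaved Use interleaved layout for PHYLIP.
#' @param strict_ids Truncate ids to 10 characters for PHYLIP (with
#'   uniqueness repair and a warning), the strict-format convention.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = "fasta", tags = TRUE,
                            interleaved = FALSE, strict_ids = TRUE) {
  stopifnot(inherits(aln, "tagged_alignment"))
  if (n_seq(aln) < 1L) stop("alignment is empty")
  format <- match.arg(format, c("fasta", "phylip", "nexus", "clustal"))
  seqs <- aln_strings(aln)
  # restore the input U convention per record
  if (aln$alphabet == "nucleotide" && any(aln$u_as_t)) {
    seqs[aln$u_as_t] <- chartr("T", "U", seqs[aln$u_as_t])
  }
  switch(format,
    fasta = {
      hdr <- ifelse(nzchar(aln$descriptions), paste(aln$ids, aln$descriptions), aln$ids)
      writeLines(as.vector(rbind(paste0(">", hdr), seqs)), path)
    },
    phylip = write_phylip(aln$ids, seqs, path, interleaved, strict_ids),
    clustal = write_clustal(aln$ids, seqs, path),
    nexus = {
      ape::write.nexus.data(
        setNames(strsplit(tolower(seqs), ""), aln$ids), path,
        format = if (aln$alphabet == "nucleotide") "dna" else "protein",
        interleaved = FALSE
      )
    }
  )
  if (isTRUE(tags) && any(aln$tags > 0L)) write_tags(aln, paste0(path, ".tags"))
  invisible(path)
}

repair_ids <- function(ids, width = 10L) {
  short <- substr(ids, 1L, width)
  if (anyDuplicated(short)) {
    warning("ids truncated to ", width, " characters are not unique; repairing")
    for (i in which(duplicated(short) | duplicated(short, fromLast = TRUE))) {
      suffix <- sprintf("_%d", i)
      short[i] <- paste0(substr(short[i], 1L, width - nchar(suffix)), suffix)
    }
  }
  if (any(nchar(ids) > width)) warning("ids longer than ", width,
                                       " characters truncated for strict PHYLIP")
  short
}

write_phylip <- function(ids, seqs, path, interleaved, strict_ids) {
  if (strict_ids) ids <- repair_ids(ids)
  len <- nchar(seqs[1])
  out <- sprintf(" %d %d", length(ids), len)
  namef <- formatC(ids, width = max(10L, max(nchar(ids))) + 2L, flag = "-")
  if (!interleaved || len <= 60L) {
    out <- c(out, paste0(namef, seqs))
  } else {
    starts <- seq(1L, len, by = 60L)
    for (k in seq_along(starts)) {
      chunk <- substr(seqs, starts[k], min(starts[k] + 59L, len))
      lead <- if (k == 1L) namef else strrep(" ", nchar(namef[1]))
      out <- c(out, paste0(lead, chunk), "")
    }
  }
  writeLines(out, path)
}

write_clustal <- function(ids, seqs, path) {
  len <- nchar(seqs[1])
  namef <- formatC(ids, width = max(nchar(ids)) + 3L, flag = "-")
  out <- c("CLUSTAL W multiple sequence alignment (seqscan)", "")
  for (start in seq(1L, len, by = 60L)) {
    chunk <- substr(seqs, start, min(start + 59L, len))
    out <- c(out, paste0(namef, chunk), "")
  }
  writeLines(out, path)
}

#' Write the sidecar tag file
#'
#' TSV with columns `tag_set` (1-4), `sequence_id`, `group` (1-26) and an
#' optional `label`; `#`-prefixed lines are comments.
#'
#' @param aln A `tagged_alignment`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_tags <- function(aln, path) {
  rows <- which(aln$tags > 0L, arr.ind = TRUE)
  lab <- function(s, g) {
    m <- aln$group_meta
    hit <- m$label[m$tag_set == s & m$group == g]
    if (length(hit)) hit[1] else ""
  }
  lines <- "# seqscan tag sidecar: tag_set<TAB>sequence_id<TAB>group<TAB>label"
  if (nrow(rows)) {
    ord <- order(rows[, 2], rows[, 1])
    lines <- c(lines, vapply(ord, function(k) {
      r <- rows[k, 1]; s <- rows[k, 2]; g <- aln$tags[r, s]
      paste(s, aln$ids[r], g, lab(s, g), sep = "\t")
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sidecar tag file into an alignment
#'
#' @param aln A `tagged_alignment`.
#' @param path Tag TSV path (format of [write_tags()]).
#' @return The alignment with tags applied; ids absent from the alignment are
#'   skipped with a warning.
#' @export
read_tags <- function(aln, path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  for (line in lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed tag line: '", line, "'")
    if (!f[2] %in% aln$ids) {
      warning("tag for unknown sequence id '", f[2], "' skipped")
      next
    }
    aln <- set_tags(aln, as.integer(f[1]), f[2], as.integer(f[3]),
                    label = if (length(f) >= 4 && nzchar(f[4])) f[4] else NULL)
  }
  aln
}
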