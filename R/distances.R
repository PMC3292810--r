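# Pairwise evolutionary distances with standard errors.  All models use
# pairwise deletion: sites with a gap or ambiguity code in either sequence are
# excluded.  Log-domain failures are flagged "saturated" (value NaN), never
# raised as errors, so sliding scans can keep going.

NT_MODELS <- c("p", "jukes_cantor", "kimura2p", "tajima_nei")
AA_MODELS <- c("p", "kimura", "matrix")

distance_result <- function(value, std_error, model, sites_used,
                            flag = "ok") {
  structure(
    list(value = value, std_error = std_error, model = model,
         sites_used = sites_used, flag = flag),
    class = "distance_result"
  )
}

#' @export
print.distance_result <- function(x, ...) {
  cat(sprintf("distance_result [%s]: %.6g (SE %.4g), %d sites%s\n",
              x$model, x$value, x$std_error, x$sites_used,
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}

saturated <- function(model, sites) distance_result(NaN, NaN, model, sites, "saturated")
inapplicable <- function(model, sites = 0L) distance_result(NaN, NaN, model, sites, "inapplicable")

as_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(toupper(x), "")[[1]] else toupper(x)
}

#' Pairwise nucleotide distance
#'
#' Uncorrected (p), Jukes-Cantor, Kimura two-parameter or Tajima-Nei distance
#' between two aligned sequences, with delta-method standard errors.  Sites
#' with a gap or ambiguity code in either sequence are excluded (pairwise
#' deletion).
#'
#' @param a,b Aligned nucleotide strings of equal gapped length.
#' @param model `"p"`, `"jukes_cantor"`, `"kimura2p"` or `"tajima_nei"`.
#' @return A `distance_result` with fields `value`, `std_error`, `model`,
#'   `sites_used` and `flag` (`"ok"`, `"saturated"` or `"inapplicable"`).
#' @export
nt_distance <- function(a, b, model = "p") {
  model <- match.arg(model, NT_MODELS)
  a <- as_chars(a); b <- as_chars(b)
  a[a == "U"] <- "T"; b[b == "U"] <- "T"
  if (length(a) != length(b)) stop("sequences must have equal gapped length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  L <- sum(ok)
  if (L < 1L) return(inapplicable(model))
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  p <- mean(diff)
  P <- mean(diff & is_transition(a, b))
  Q <- p - P

  if (model == "p") {
    return(distance_result(p, sqrt(p * (1 - p) / L), model, L))
  }
  if (model == "jukes_cantor") {
    arg <- 1 - 4 * p / 3
    if (arg <= 0) return(saturated(model, L))
    d <- -0.75 * log(arg)
    se <- sqrt(p * (1 - p) / L) / arg
    return(distance_result(d, se, model, L))
  }
  if (model == "kimura2p") {
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    if (w1 <= 0 || w2 <= 0) return(saturated(model, L))
    d <- -0.5 * log(w1) - 0.25 * log(w2)
    c1 <- 1 / w1; c2 <- 1 / w2; c3 <- (c1 + c2) / 2
    v <- (c1^2 * P + c3^2 * Q - (c1 * P + c3 * Q)^2) / L
    return(distance_result(d, sqrt(max(v, 0)), model, L))
  }
  # Tajima-Nei (1984), full b term with base frequencies and the
  # mismatch-pair table
  if (p == 0) return(distance_result(0, 0, model, L))
  pool <- c(a, b)
  g <- table(factor(pool, levels = c("A", "C", "G", "T"))) / length(pool)
  pairs <- table(factor(pmin(a, b)[diff], levels = c("A", "C", "G", "T")),
                 factor(pmax(a, b)[diff], levels = c("A", "C", "G", "T"))) / L
  h <- 0
  bases <- c("A", "C", "G", "T")
  for (i in 1:3) for (j in (i + 1):4) {
    if (g[i] > 0 && g[j] > 0) h <- h + pairs[i, j]^2 / (2 * g[i] * g[j])
  }
  if (h <= 0) return(saturated(model, L))
  bterm <- 0.5 * (1 - sum(g^2) + p^2 / h)
  arg <- 1 - p / bterm
  if (arg <= 0) return(saturated(model, L))
  d <- -bterm * log(arg)
  v <- bterm^2 * p * (1 - p) / ((bterm - p)^2 * L)
  distance_result(d, sqrt(v), model, L)
}

#' Pairwise amino-acid distance
#'
#' @param a,b Aligned amino-acid strings of equal gapped length.
#' @param model `"p"`, `"kimura"` (d = -ln(1 - p - 0.2 p^2)) or `"matrix"`
#'   (similarity-matrix normalised, see Details).
#' @param matrix_table Similarity matrix for `model = "matrix"`; defaults to
#'   PAM250 from Biostrings.
#' @details The matrix-normalised distance is
#'   `1 - (S_obs - S_exp)/(S_max - S_exp)` where `S_obs` is the mean matrix
#'   score of the aligned residue pairs, `S_max` the mean self-score and
#'   `S_exp` the expected score under the pooled residue frequencies of the
#'   two sequences.
#' @return A `distance_result`.
#' @export
aa_distance <- function(a, b, model = "p", matrix_table = NULL) {
  model <- match.arg(model, AA_MODELS)
  a <- as_chars(a); b <- as_chars(b)
  if (length(a) != length(b)) stop("sequences must have equal gapped length")
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ok <- a %in% aas & b %in% aas
  L <- sum(ok)
  if (L < 1L) return(inapplicable(model))
  a <- a[ok]; b <- b[ok]
  p <- mean(a != b)
  if (model == "p") return(distance_result(p, sqrt(p * (1 - p) / L), model, L))
  if (model == "kimura") {
    arg <- 1 - p - 0.2 * p^2
    if (arg <= 0) return(saturated(model, L))
    d <- -log(arg)
    se <- sqrt(p * (1 - p) / L) * (1 + 0.4 * p) / arg
    return(distance_result(d, se, model, L))
  }
  m <- matrix_table
  if (is.null(m)) m <- default_aa_matrix()
  s_obs <- mean(m[cbind(a, b)])
  s_max <- mean((m[cbind(a, a)] + m[cbind(b, b)]) / 2)
  f <- table(factor(c(a, b), levels = aas)) / (2 * L)
  s_exp <- as.numeric(t(f) %*% m[aas, aas] %*% f)
  if (s_max <= s_exp) return(inapplicable(model, L))
  d <- 1 - (s_obs - s_exp) / (s_max - s_exp)
  distance_result(d, NA_real_, model, L)
}

default_aa_matrix <- function() {
  if (is.null(.seqscan$pam)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      stop("model = 'matrix' needs the Biostrings package (for PAM250) or an ",
           "explicit matrix_table")
    }
    e <- new.env()
    utils::data("PAM250", package = "Biostrings", envir = e)
    .seqscan$pam <- e$PAM250
  }
  .seqscan$pam
}

# ---- codon-level (synonymous / non-synonymous) distances --------------------

# NG86 site counts for one codon: expected numbers of synonymous positions,
# counting mutations to stop codons as non-synonymous.
ng86_sites <- function(codon) {
  code <- genetic_code()
  aa <- code[codon]
  if (is.na(aa) || aa == "*") return(NA_real_)
  chars <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- alt
      maa <- code[paste(mut, collapse = "")]
      if (!is.na(maa) && maa != "*" && maa == aa) s <- s + 1 / 3
    }
  }
  s
}

# average synonymous/non-synonymous differences between two codons over all
# minimal-change pathways (equal weighting; steps to/from stops count by
# amino-acid change)
ng86_diffs <- function(c1, c2) {
  code <- genetic_code()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  perms <- if (k == 1L) list(pos) else {
    idx <- if (k == 2L) list(1:2, 2:1) else {
      unlist(lapply(1:3, function(i) lapply(setdiff(1:3, i), function(j) c(i, j, setdiff(1:3, c(i, j))))), recursive = FALSE)
    }
    lapply(idx, function(o) pos[o])
  }
  sdn <- c(0, 0)
  for (path in perms) {
    cur <- strsplit(c1, "")[[1]]
    tgt <- strsplit(c2, "")[[1]]
    for (p in path) {
      nxt <- cur; nxt[p] <- tgt[p]
      syn <- code[[paste(cur, collapse = "")]] == code[[paste(nxt, collapse = "")]]
      sdn <- sdn + if (isTRUE(syn)) c(1, 0) else c(0, 1)
      cur <- nxt
    }
  }
  sdn / length(perms)
}

clean_codon_pairs <- function(a, b) {
  a <- as_chars(a); b <- as_chars(b)
  a[a == "U"] <- "T"; b[b == "U"] <- "T"
  if (length(a) != length(b)) stop("sequences must have equal gapped length")
  ncod <- length(a) %/% 3L
  if (ncod == 0L) stop("sequences shorter than one codon")
  code <- genetic_code()
  keep_a <- keep_b <- character(0)
  for (i in seq_len(ncod)) {
    ca <- paste(a[(3 * i - 2):(3 * i)], collapse = "")
    cb <- paste(b[(3 * i - 2):(3 * i)], collapse = "")
    if (is.na(code[ca]) || is.na(code[cb])) next        # gap/ambiguity
    if (code[ca] == "*" || code[cb] == "*") next        # stop codons skipped
    keep_a <- c(keep_a, ca); keep_b <- c(keep_b, cb)
  }
  list(a = keep_a, b = keep_b)
}

#' Synonymous and non-synonymous codon distances
#'
#' Nei-Gojobori (1986) synonymous/non-synonymous p-distances (optionally
#' Jukes-Cantor corrected per class) or the Li-Pamilo-Bianchi degeneracy-class
#' method.  Codons containing gaps, ambiguity codes or stops (in either
#' sequence) are skipped.
#'
#' @param a,b Aligned, in-frame nucleotide strings.
#' @param method `"ng86_p"`, `"ng86_jc"` or `"li_pb"`.
#' @return List with elements `syn` and `nonsyn`, each a `distance_result`.
#' @export
codon_distance <- function(a, b, method = "ng86_p") {
  method <- match.arg(method, c("ng86_p", "ng86_jc", "li_pb"))
  cp <- clean_codon_pairs(a, b)
  if (!length(cp$a)) return(list(syn = inapplicable(method), nonsyn = inapplicable(method)))
  if (method == "li_pb") return(li_pb_distance(cp))

  S <- sum(vapply(cp$a, ng86_sites, numeric(1)) + vapply(cp$b, ng86_sites, numeric(1))) / 2
  N <- 3 * length(cp$a) - S
  d <- rowSums(vapply(seq_along(cp$a), function(i) ng86_diffs(cp$a[i], cp$b[i]),
                      numeric(2)))
  mk <- function(num, den) {
    if (den <= 0) return(inapplicable(method))
    p <- num / den
    se <- sqrt(max(p * (1 - p), 0) / den)
    if (method == "ng86_jc") {
      arg <- 1 - 4 * p / 3
      if (arg <= 0) return(saturated(method, round(den)))
      return(distance_result(-0.75 * log(arg), se / arg, method, round(den)))
    }
    distance_result(p, se, method, round(den))
  }
  list(syn = mk(d[[1]], S), nonsyn = mk(d[[2]], N))
}

# Li (1993) / Pamilo-Bianchi (1993): 0-, 2-, 4-fold degenerate site classes
# with Kimura-type transition/transversion corrections per class.
li_pb_distance <- function(cp) {
  degclass <- function(codon) {
    chars <- strsplit(codon, "")[[1]]
    code <- genetic_code()
    aa <- code[codon]
    vapply(1:3, function(pos) {
      nsyn <- sum(vapply(setdiff(c("A", "C", "G", "T"), chars[pos]), function(alt) {
        mut <- chars; mut[pos] <- alt
        maa <- code[paste(mut, collapse = "")]
        !is.na(maa) && maa != "*" && maa == aa
      }, logical(1)))
      if (nsyn == 0L) 0L else if (nsyn == 3L) 4L else 2L
    }, integer(1))
  }
  L <- c(`0` = 0, `2` = 0, `4` = 0)
  Pc <- Qc <- c(`0` = 0, `2` = 0, `4` = 0)
  for (i in seq_along(cp$a)) {
    da <- degclass(cp$a[i]); db <- degclass(cp$b[i])
    ca <- strsplit(cp$a[i], "")[[1]]; cb <- strsplit(cp$b[i], "")[[1]]
    for (pos in 1:3) {
      for (cls in c(da[pos], db[pos])) {            # half weight to each seq's class
        key <- as.character(cls)
        L[key] <- L[key] + 0.5
        if (ca[pos] != cb[pos]) {
          if (is_transition(ca[pos], cb[pos])) Pc[key] <- Pc[key] + 0.5
          else Qc[key] <- Qc[key] + 0.5
        }
      }
    }
  }
  AB <- function(cls) {
    if (L[cls] <= 0) return(c(A = NA, B = NA))
    P <- unname(Pc[cls] / L[cls]); Q <- unname(Qc[cls] / L[cls])
    a <- 1 - 2 * P - Q; b <- 1 - 2 * Q
    if (a <= 0 || b <= 0) return(c(A = NaN, B = NaN))
    c(A = 0.5 * log(1 / a) - 0.25 * log(1 / b), B = 0.5 * log(1 / b))
  }
  v0 <- AB("0"); v2 <- AB("2"); v4 <- AB("4")
  Ls <- L[c("2", "4")]
  Ks <- (Ls[1] * v2["A"] + Ls[2] * v4["A"]) / sum(Ls) + v4["B"]
  La <- L[c("0", "2")]
  Ka <- v0["A"] + (La[1] * v0["B"] + La[2] * v2["B"]) / sum(La)
  mk <- function(val, sites) {
    if (!is.finite(val)) {
      if (is.nan(val)) saturated("li_pb", round(unname(sites)))
      else inapplicable("li_pb", round(unname(sites)))
    } else distance_result(max(val, 0), NA_real_, "li_pb", round(unname(sites)))
  }
  list(syn = mk(unname(Ks), L["2"] / 3 + L["4"]),
       nonsyn = mk(unname(Ka), L["0"] + 2 * L["2"] / 3))
}

# ---- alignment-level distance matrix ---------------------------------------

#' Pairwise distance matrix for an alignment
#'
#' @param aln A `tagged_alignment`.
#' @param model A nucleotide model (see [nt_distance()]) or, for amino-acid
#'   alignments, an amino-acid model (see [aa_distance()]).
#' @param rows,columns Optional selection (row ids/indices; 1-based inclusive
#'   column indices).
#' @return Symmetric numeric matrix of distances (NaN where saturated or
#'   inapplicable), with sequence ids as dimnames.
#' @export
dist_matrix <- function(aln, model = "jukes_cantor", rows = NULL, columns = NULL) {
  sub <- aln[rows, columns]
  n <- n_seq(sub)
  mat <- sub$mat
  d <- matrix(0, n, n, dimnames = list(sub$ids, sub$ids))
  if (n < 2L) return(d)
  if (sub$alphabet == "nucleotide" && model %in% c("p", "jukes_cantor", "kimura2p")) {
    # vectorised fast path (same formulas as nt_distance), heavily exercised
    # by the bootstrap scans
    codes <- matrix(match(mat, c("A", "C", "G", "T")), n)
    codes[is.na(codes)] <- 0L
    for (i in 1:(n - 1)) {
      a <- codes[i, ]
      for (j in (i + 1):n) {
        b <- codes[j, ]
        ok <- a > 0L & b > 0L
        L <- sum(ok)
        if (L < 1L) { d[i, j] <- d[j, i] <- NaN; next }
        aa <- a[ok]; bb <- b[ok]
        p <- sum(aa != bb) / L
        val <- if (model == "p") p
        else if (model == "jukes_cantor") {
          arg <- 1 - 4 * p / 3
          if (arg <= 0) NaN else -0.75 * log(arg)
        } else {
          P <- sum(aa != bb & abs(aa - bb) == 2L) / L
          Q <- p - P
          w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
          if (w1 <= 0 || w2 <= 0) NaN else -0.5 * log(w1) - 0.25 * log(w2)
        }
        d[i, j] <- d[j, i] <- val
      }
    }
    return(d)
  }
  fun <- if (sub$alphabet == "nucleotide") nt_distance else aa_distance
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- fun(mat[i, ], mat[j, ], model)
    d[i, j] <- d[j, i] <- r$value
  }
  d
}
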