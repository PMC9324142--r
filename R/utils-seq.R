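## Low-level sequence helpers. Sequences are carried internally as plain
## upper-case character scalars (fast substring/utf8ToInt vector ops) and
## converted to Biostrings objects only at I/O and alignment boundaries.
## Coordinates are 0-based half-open internally; converted at I/O (GFF3
## 1-based inclusive, BED 0-based half-open).

DNA_BASES4 <- c("A", "C", "G", "T")

#' @keywords internal
random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

#' Reverse complement of plain character DNA (vectorized)
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## A=0 C=1 G=2 T=3; anything else -> NA
.DNA_LOOKUP <- local({
  v <- rep(NA_integer_, 127)
  v[utf8ToInt("A")] <- 0L; v[utf8ToInt("C")] <- 1L
  v[utf8ToInt("G")] <- 2L; v[utf8ToInt("T")] <- 3L
  v
})

#' @keywords internal
dna_ints <- function(x) .DNA_LOOKUP[utf8ToInt(x)]

#' @keywords internal
ints_dna <- function(v) paste(DNA_BASES4[v + 1L], collapse = "")

#' Rolling base-4 k-mer codes (doubles; exact for k <= 26)
#'
#' Codes containing non-ACGT bases come out NA.
#' @keywords internal
kmer_codes <- function(ints, k) {
  n <- length(ints)
  if (n < k) return(numeric(0))
  m <- n - k + 1L
  codes <- numeric(m)
  for (j in seq_len(k)) {
    codes <- codes * 4 + ints[j:(m + j - 1L)]
  }
  codes
}

#' Mismatch positions between two equal-length strings (1-based)
#' @keywords internal
mismatch_positions <- function(a, b) {
  ia <- utf8ToInt(a); ib <- utf8ToInt(b)
  stopifnot(length(ia) == length(ib))
  which(ia != ib)
}

#' Highest-scoring contiguous span under a match/mismatch score (Kadane)
#'
#' Scores +1 per match and `-penalty` per mismatch; used to separate the
#' aligned core of a read from soft-clipped tails at breakpoints/junctions.
#'
#' @param mism 1-based mismatch positions within the comparison window.
#' @param len window length.
#' @return list(start, end, mismatches, score); 1-based inclusive span,
#'   start = 0 when every position is best left unaligned.
#' @keywords internal
best_match_span <- function(mism, len, penalty = 4) {
  if (length(mism) == 0) {
    return(list(start = 1L, end = len, mismatches = 0L, score = len))
  }
  score <- rep(1, len)
  score[mism] <- -penalty
  cs <- cumsum(score)
  pre <- cummin(c(0, cs[-len]))       # min prefix sum before each end
  vals <- cs - pre
  e <- which.max(vals)
  best <- vals[e]
  if (best <= 0) {
    return(list(start = 0L, end = -1L, mismatches = 0L, score = 0))
  }
  s <- which.min(c(0, cs)[seq_len(e)]) # prefix index; span starts after it
  nm <- sum(mism >= s & mism <= e)
  list(start = as.integer(s), end = as.integer(e),
       mismatches = as.integer(nm), score = best)
}

## Deterministic reverse translation (one fixed codon per amino acid);
## used when planting protein-domain coding sequence into synthetic elements.
.AA_CODON <- c(
  A = "GCT", R = "CGT", N = "AAT", D = "GAT", C = "TGT", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAA",
  M = "ATG", F = "TTT", P = "CCT", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAT", V = "GTT", `*` = "TAA"
)

#' @keywords internal
reverse_translate <- function(peptide) {
  paste(.AA_CODON[strsplit(peptide, "")[[1]]], collapse = "")
}

#' Six-frame translation of a nucleotide string
#'
#' @return data.frame(frame, peptide); frames +1..+3 and -1..-3. Each row
#'   also records the nucleotide offset of the frame start on the plus
#'   strand coordinate system of the input.
#' @keywords internal
six_frame_translate <- function(seq) {
  n <- nchar(seq)
  fwd <- Biostrings::DNAString(seq)
  rev <- Biostrings::reverseComplement(fwd)
  out <- vector("list", 6)
  k <- 1
  for (f in 1:3) {
    len <- ((n - f + 1L) %/% 3L) * 3L
    pep <- if (len >= 3) as.character(Biostrings::translate(
      Biostrings::subseq(fwd, f, f + len - 1L), no.init.codon = TRUE
    )) else ""
    out[[k]] <- data.frame(frame = f, offset = f - 1L, peptide = pep,
                           stringsAsFactors = FALSE)
    k <- k + 1
  }
  for (f in 1:3) {
    len <- ((n - f + 1L) %/% 3L) * 3L
    pep <- if (len >= 3) as.character(Biostrings::translate(
      Biostrings::subseq(rev, f, f + len - 1L), no.init.codon = TRUE
    )) else ""
    out[[k]] <- data.frame(frame = -f, offset = f - 1L, peptide = pep,
                           stringsAsFactors = FALSE)
    k <- k + 1
  }
  do.call(rbind, out)
}
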