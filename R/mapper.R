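## Minimal read mapper: exact k-mer seeding (default k = 21) on both
## strands, gapless verification on the seed diagonal, soft-clips for
## prefixes/suffixes that fail to extend. Substitutions are the only edit
## operation scored inside the matched span -- the error model of the
## simulated libraries; indels surface as soft-clips and are resolved by
## the junction/breakpoint logic downstream. External SAM alignments can be
## imported with [read_sam_alignments()].

#' Build a k-mer index over a reference set
#'
#' @param refs named character vector of reference sequences.
#' @param k k-mer size (exact for k <= 26).
#' @return a `ref_index` list (codes table, reference ints, k).
#' @export
build_ref_index <- function(refs, k = 21L) {
  stopifnot(length(refs) > 0, !is.null(names(refs)))
  ints <- lapply(refs, dna_ints)
  tabs <- lapply(seq_along(refs), function(i) {
    codes <- kmer_codes(ints[[i]], k)
    data.table::data.table(code = codes, ref = i,
                           pos = seq_along(codes))[!is.na(code)]
  })
  idx <- data.table::rbindlist(tabs)
  data.table::setkey(idx, code)
  structure(list(idx = idx, ints = ints, names = names(refs), k = k),
            class = "ref_index")
}

## k-mer codes for a read matrix (reads x positions) at given offsets
.read_seed_codes <- function(mat, offsets, k) {
  out <- vector("list", length(offsets))
  for (oi in seq_along(offsets)) {
    o <- offsets[oi]
    codes <- numeric(nrow(mat))
    for (j in 0:(k - 1L)) codes <- codes * 4 + mat[, o + j]
    out[[oi]] <- data.table::data.table(
      read = seq_len(nrow(mat)), offset = o, code = codes
    )
  }
  data.table::rbindlist(out)[!is.na(code)]
}

#' Map reads against a reference set
#'
#' Seeds at regular offsets are matched exactly against the reference
#' index; candidate (reference, diagonal) placements are voted on, and the
#' best placements are verified gaplessly: the highest-scoring contiguous
#' span (match +1 / mismatch -4) becomes the aligned core and its flanks
#' become soft-clips. The best alignment per read maximizes
#' (span - mismatches); ties go to the lowest reference id, then position.
#' Reads shorter than k, or with no qualifying placement, are unmapped.
#'
#' @param reads named character vector (all reads the same length is not
#'   required).
#' @param refs named character vector, or a prebuilt [build_ref_index()].
#' @param k seed length.
#' @param seed_step distance between seed offsets along the read.
#' @param min_span minimum aligned-core length to report.
#' @param max_mismatch_frac maximum mismatch fraction within the span.
#' @param max_hits_per_seed seeds occurring more often are ignored
#'   (repeat shielding).
#' @return data.frame, one row per mapped read: read_id, ref, pos (0-based
#'   start of the aligned core on the reference), strand, span, nm
#'   (mismatches in the core), clip_left, clip_right, clip_seq_left,
#'   clip_seq_right, score, n_best (number of equally good placements).
#' @export
map_reads <- function(reads, refs, k = 21L, seed_step = 12L,
                      min_span = 25L, max_mismatch_frac = 0.1,
                      max_hits_per_seed = 64L) {
  index <- if (inherits(refs, "ref_index")) refs else build_ref_index(refs, k)
  k <- index$k
  empty <- data.frame(
    read_id = character(0), ref = character(0), pos = integer(0),
    strand = character(0), span = integer(0), nm = integer(0),
    clip_left = integer(0), clip_right = integer(0),
    clip_seq_left = character(0), clip_seq_right = character(0),
    score = numeric(0), n_best = integer(0), stringsAsFactors = FALSE
  )
  if (length(reads) == 0) return(empty)
  stopifnot(!is.null(names(reads)))
  lens <- nchar(reads)
  usable <- lens >= k
  if (!any(usable)) return(empty)
  # process per distinct read length (vectorized within each)
  res <- list()
  for (L in unique(lens[usable])) {
    sel <- which(lens == L & usable)
    sub <- reads[sel]
    for (strand in c("+", "-")) {
      sseq <- if (strand == "+") sub else revcomp(sub)
      mat <- matrix(.DNA_LOOKUP[utf8ToInt(paste(sseq, collapse = ""))],
                    nrow = length(sseq), ncol = L, byrow = TRUE)
      offsets <- unique(pmin(seq(1L, L - k + 1L, by = seed_step),
                             L - k + 1L))
      seeds <- .read_seed_codes(mat, offsets, k)
      if (nrow(seeds) == 0) next
      m <- index$idx[seeds, on = "code", nomatch = NULL,
                     allow.cartesian = TRUE]
      if (nrow(m) == 0) next
      m[, nhit := .N, by = c("read", "offset")]
      m <- m[nhit <= max_hits_per_seed]
      if (nrow(m) == 0) next
      m[, diag := pos - offset]
      votes <- m[, .N, by = c("read", "ref", "diag")]
      data.table::setorder(votes, read, ref, diag)
      nc <- nrow(votes)
      # verify every voted placement (vote count is advisory only);
      # columns preallocated, one pass, results collected per read below
      v_read <- votes$read; v_ref <- votes$ref; v_diag <- votes$diag
      c_pos <- integer(nc); c_qs <- integer(nc); c_qe <- integer(nc)
      c_span <- integer(nc); c_nm <- integer(nc); c_ok <- logical(nc)
      for (ci in seq_len(nc)) {
        rints <- index$ints[[v_ref[ci]]]
        d <- v_diag[ci]
        lo <- max(1L, 1L + d); hi <- min(length(rints), L + d)
        if (hi - lo + 1L < min_span) next
        q1 <- lo - d; q2 <- hi - d
        cmp <- mat[v_read[ci], q1:q2] != rints[lo:hi]
        cmp[is.na(cmp)] <- TRUE
        sp <- best_match_span(which(cmp), q2 - q1 + 1L)
        if (sp$start == 0L) next
        span <- sp$end - sp$start + 1L
        if (span < min_span || sp$mismatches > max_mismatch_frac * span)
          next
        c_ok[ci] <- TRUE
        c_pos[ci] <- lo + sp$start - 2L        # 0-based ref start
        c_qs[ci] <- q1 + sp$start - 1L         # 1-based on read
        c_qe[ci] <- q1 + sp$end - 1L
        c_span[ci] <- span
        c_nm[ci] <- sp$mismatches
      }
      if (!any(c_ok)) next
      cdt <- data.table::data.table(
        read = v_read[c_ok], ref = v_ref[c_ok], pos = c_pos[c_ok],
        q_start = c_qs[c_ok], q_end = c_qe[c_ok], span = c_span[c_ok],
        nm = c_nm[c_ok]
      )
      cdt[, score := span - nm]
      # best per read: score desc, then ref id, then position
      data.table::setorder(cdt, read, -score, ref, pos)
      nb <- cdt[, list(n_best = sum(score == score[1L])), by = "read"]
      bst <- cdt[!duplicated(read)]
      bst <- nb[bst, on = "read"]
      rs <- sseq[bst$read]
      res[[length(res) + 1L]] <- data.table::data.table(
        read_id = names(sub)[bst$read], ref = index$names[bst$ref],
        pos = bst$pos, strand = strand, span = bst$span, nm = bst$nm,
        clip_left = bst$q_start - 1L, clip_right = L - bst$q_end,
        clip_seq_left = substr(rs, 1L, bst$q_start - 1L),
        clip_seq_right = substr(rs, bst$q_end + 1L, L),
        score = as.numeric(bst$score), n_best = bst$n_best
      )
    }
  }
  if (length(res) == 0) return(empty)
  df <- data.table::rbindlist(res)
  # one best record per read across strands; deterministic tie-break;
  # n_best accumulates equally-good placements from both strands
  data.table::setorder(df, read_id, -score, ref, pos, strand)
  df[, n_best := sum(n_best[score == max(score)]), by = "read_id"]
  df <- df[!duplicated(df$read_id)]
  as.data.frame(df)
}

#' Import alignments from a SAM file into the internal alignment table
#'
#' Minimal mapped-record import (via Rsamtools when available): read id,
#' reference, 0-based position, strand, aligned span and soft-clip lengths
#' parsed from the CIGAR string.
#'
#' @param path SAM/BAM file path.
#' @return data.frame in the [map_reads()] output layout (score and nm NA).
#' @export
read_sam_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to import SAM/BAM")
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "seq"))
  b <- Rsamtools::scanBam(path, param = p)[[1]]
  keep <- !is.na(b$pos)
  cig <- b$cigar[keep]
  cl <- ifelse(grepl("^([0-9]+)S", cig),
               as.integer(sub("^([0-9]+)S.*$", "\\1", cig)), 0L)
  cr <- ifelse(grepl("([0-9]+)S$", cig),
               as.integer(sub("^.*?([0-9]+)S$", "\\1", cig)), 0L)
  span <- vapply(cig, function(cc) {
    ops <- regmatches(cc, gregexpr("[0-9]+[MIDNSHP=X]", cc))[[1]]
    sum(as.integer(sub("[A-Z=]", "", ops[grepl("[M=X]", ops)])))
  }, integer(1), USE.NAMES = FALSE)
  sq <- as.character(b$seq[keep])
  data.frame(
    read_id = b$qname[keep], ref = as.character(b$rname[keep]),
    pos = b$pos[keep] - 1L, strand = as.character(b$strand[keep]),
    span = span, nm = NA_integer_, clip_left = cl, clip_right = cr,
    clip_seq_left = substr(sq, 1L, cl),
    clip_seq_right = substr(sq, nchar(sq) - cr + 1L, nchar(sq)),
    score = NA_real_, n_best = 1L, stringsAsFactors = FALSE
  )
}
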