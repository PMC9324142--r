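## Structural detection of intact LTR retrotransposons and solo LTRs.
## Candidates are seeded by maximal exact repeats (>= seed_len), extended by
## gapless X-drop on the seed diagonal, boundary-adjusted to the terminal
## motif, and validated for LTR similarity, LTR-start distance and
## target-site duplication -- the decision surface of de novo LTR detectors
## (seed 80, LTR length 100-4000, start distance 3000-15000, TSD 2-20,
## motif TG...CA).

#' Structural-miner parameters
#'
#' Defaults follow standard de novo LTR-detector settings: exact seed 80 bp,
#' LTR length 100-4000 bp, LTR-start distance 3000-15000 bp ("distance" is
#' the distance between the two LTR *start* positions), TSD 2-20 bp and
#' terminal motif searched within 60 bp of the extension boundaries, motif
#' TG/CA required exactly, minimum LTR-pair identity 0.85.
#'
#' @param seed_len minimum exact-repeat seed (bp).
#' @param min_ltr_len,max_ltr_len LTR length bounds (bp).
#' @param min_dist,max_dist bounds on the distance between LTR starts (bp).
#' @param min_tsd,max_tsd TSD length bounds (bp).
#' @param motif terminal dinucleotides (5' LTR start, 3' LTR end).
#' @param motif_mismatches allowed motif mismatches (default exact).
#' @param min_ltr_similarity minimum LTR-pair identity fraction.
#' @param tsd_vicinity motif/TSD search radius around boundaries (bp).
#' @return a `miner_params` list.
#' @export
miner_params <- function(seed_len = 80L, min_ltr_len = 100L,
                         max_ltr_len = 4000L, min_dist = 3000L,
                         max_dist = 15000L, min_tsd = 2L, max_tsd = 20L,
                         motif = c("TG", "CA"), motif_mismatches = 0L,
                         min_ltr_similarity = 0.85, tsd_vicinity = 60L) {
  stopifnot(min_ltr_len <= max_ltr_len, min_dist <= max_dist,
            min_tsd <= max_tsd, min_ltr_similarity > 0,
            min_ltr_similarity <= 1)
  structure(as.list(environment()), class = "miner_params")
}

## Maximal exact repeat seeds on one chromosome: pairs of equal k-mers at
## start-distance D in [min_dist, max_dist], chained along diagonals.
## Returns data.table(D, a, b): exact repeat seq[a..b] == seq[(a+D)..(b+D)]
## (1-based inclusive) with b - a + 1 >= seed_len.
.exact_repeat_seeds <- function(ints, params, k = 20L) {
  empty <- data.table::data.table(D = integer(0), a = integer(0),
                                  b = integer(0))
  codes <- kmer_codes(ints, k)
  dt <- data.table::data.table(code = codes,
                               pos = seq_along(codes))[!is.na(code)]
  dup <- dt[, .N, by = "code"][N > 1L & N <= 50L] # cap pathological k-mers
  if (nrow(dup) == 0) return(empty)
  dd <- dt[dup, on = "code"]
  pairs <- dd[, {
    cmb <- utils::combn(sort(pos), 2L)
    list(p1 = cmb[1L, ], p2 = cmb[2L, ])
  }, by = "code"]
  pairs[, D := p2 - p1]
  pairs <- pairs[D >= params$min_dist & D <= params$max_dist]
  if (nrow(pairs) == 0) return(empty)
  data.table::setorder(pairs, D, p1)
  pairs[, run := cumsum(c(1L, diff(p1) != 1L)), by = "D"]
  seeds <- pairs[, list(a = min(p1), b = max(p1) + k - 1L),
                 by = c("D", "run")]
  seeds <- seeds[b - a + 1L >= params$seed_len, c("D", "a", "b")]
  unique(seeds)
}

## Gapless X-drop extension of seq[a..b] vs seq[(a+D)..(b+D)]: walk
## outwards scoring +1/match, -3/mismatch, stop when the running score
## falls more than `xdrop` below its maximum; return the argmax bounds.
.xdrop_extend <- function(ints, a, b, D, xdrop = 10) {
  n <- length(ints)
  # left
  best <- 0; cur <- 0; ea <- a; i <- a - 1L
  while (i >= 1L && i + D >= 1L && best - cur <= xdrop) {
    x <- ints[i]; y <- ints[i + D]
    cur <- cur + if (!is.na(x) && !is.na(y) && x == y) 1 else -3
    if (cur > best) { best <- cur; ea <- i }
    i <- i - 1L
  }
  # right
  best <- 0; cur <- 0; eb <- b; i <- b + 1L
  while (i <= n && i + D <= n && best - cur <= xdrop) {
    x <- ints[i]; y <- ints[i + D]
    cur <- cur + if (!is.na(x) && !is.na(y) && x == y) 1 else -3
    if (cur > best) { best <- cur; eb <- i }
    i <- i + 1L
  }
  c(ea, eb)
}

## Positions i in [lo, hi] where the dinucleotide at i..i+1 matches `dinuc`
## (a 2-character string) with at most mm mismatches.
.dinuc_hits <- function(ints, dinuc, mm, lo, hi) {
  lo <- max(1L, lo); hi <- min(length(ints) - 1L, hi)
  if (hi < lo) return(integer(0))
  m <- dna_ints(dinuc)
  idx <- lo:hi
  d1 <- ints[idx] != m[1L]; d2 <- ints[idx + 1L] != m[2L]
  bad <- is.na(d1) | is.na(d2)
  d <- ifelse(bad, 3L, d1 + d2)
  idx[d <= mm]
}

## TSD search around fixed element boundaries: adjacency first (smallest
## symmetric displacement from the boundary), longest duplication within
## each displacement. Element occupies [i, e] 1-based inclusive.
.find_tsd <- function(ints, i, e, params) {
  for (s in 0:(params$tsd_vicinity - 1L)) {
    for (t in seq(params$max_tsd, params$min_tsd)) {
      l0 <- i - s - t; r0 <- e + s + 1L
      if (l0 < 1L || r0 + t - 1L > length(ints)) next
      la <- ints[l0:(l0 + t - 1L)]; ra <- ints[r0:(r0 + t - 1L)]
      if (!anyNA(la) && !anyNA(ra) && all(la == ra)) {
        return(list(seq = ints_dna(la), len = t, shift = s))
      }
    }
  }
  NULL
}

#' Detect intact LTR-retrotransposon candidates
#'
#' Scans each chromosome for maximal exact repeats of at least
#' `params$seed_len` bp whose start distance lies within
#' `[min_dist, max_dist]`, extends each seed gaplessly along its diagonal
#' (X-drop), adjusts boundaries to the nearest terminal-motif occurrence
#' present in *both* repeat copies (5' LTR starting with `motif[1]`, 3' LTR
#' ending with `motif[2]`, within `tsd_vicinity` of the extension
#' boundary), then requires LTR length within bounds, LTR-pair identity of
#' at least `min_ltr_similarity`, and an identical flanking target-site
#' duplication of `min_tsd`-`max_tsd` bp within `tsd_vicinity` of the
#' element boundaries. Overlapping candidates are resolved greedily by
#' (identity desc, element length desc, leftmost start).
#'
#' LTR pairs are compared on a single diagonal (substitution divergence),
#' the model the downstream K80 dating assumes. Nested insertions are not
#' resolved. Strand is "+" throughout: the TG...CA motif is its own reverse
#' complement, so structural detection is strand-symmetric.
#'
#' @param genome named character vector of chromosome sequences (or an
#'   `AnnotatedGenome`, whose `$genome` is used).
#' @param params a [miner_params()].
#' @return data.frame of candidates: chrom, start, end (0-based half-open
#'   element interval), ltr5_start/ltr5_end, ltr3_start/ltr3_end, strand,
#'   ltr_len, dist, ltr_identity, tsd, tsd_len, motif_ok, id.
#' @export
find_ltr_candidates <- function(genome, params = miner_params()) {
  if (inherits(genome, "AnnotatedGenome")) genome <- genome$genome
  stopifnot(length(genome) > 0, all(nchar(genome) > 0))
  out <- list()
  for (cn in names(genome)) {
    ints <- dna_ints(genome[[cn]])
    n <- length(ints)
    seeds <- .exact_repeat_seeds(ints, params)
    if (nrow(seeds) == 0) next
    cand <- list()
    for (si in seq_len(nrow(seeds))) {
      D <- seeds$D[si]; a <- seeds$a[si]; b <- seeds$b[si]
      ext <- .xdrop_extend(ints, a, b, D)
      ea <- ext[1L]; eb <- ext[2L]
      mm <- params$motif_mismatches
      # 5' boundary: motif[1] at i and i + D, closest to the extension edge
      is <- .dinuc_hits(ints, params$motif[1], mm,
                        ea - params$tsd_vicinity, ea + params$tsd_vicinity)
      is <- is[is + D + 1L <= n]
      if (length(is) > 0) {
        m1 <- dna_ints(params$motif[1])
        d1 <- (ints[is + D] != m1[1L]) + (ints[is + D + 1L] != m1[2L])
        is <- is[!is.na(d1) & d1 <= mm]
      }
      # 3' boundary: motif[2] ending at e (at e-1..e), in both copies
      es <- .dinuc_hits(ints, params$motif[2], mm,
                        eb - params$tsd_vicinity, eb + params$tsd_vicinity)
      es <- es + 1L # position of the last motif base = LTR end
      es <- es[es + D <= n]
      if (length(es) > 0) {
        m2 <- dna_ints(params$motif[2])
        d2 <- (ints[es - 1L + D] != m2[1L]) + (ints[es + D] != m2[2L])
        es <- es[!is.na(d2) & d2 <= mm]
      }
      if (length(is) == 0 || length(es) == 0) next
      # rank boundary combinations by a composite of repeat-pair alignment
      # score (match +1 / mismatch -3 over the LTR pair) and TSD support
      # (+4 per duplicated base, -4 per base of displacement from the
      # boundary): the integration-site duplication pins the true element
      # boundaries while the pair score vetoes extensions into flank
      best <- NULL
      for (i in is) {
        for (e in es) {
          ltr_len <- e - i + 1L
          if (ltr_len < params$min_ltr_len || ltr_len > params$max_ltr_len)
            next
          if (i + D + ltr_len - 1L > n) next
          x <- ints[i:e]; y <- ints[(i + D):(e + D)]
          nmis <- sum(x != y, na.rm = TRUE)
          ident <- 1 - nmis / ltr_len
          if (ident < params$min_ltr_similarity) next
          tsd <- .find_tsd(ints, i, e + D, params)
          if (is.null(tsd)) next
          prox <- abs(i - ea) + abs(e - eb)
          # pair extent dominates; a chance duplication can only displace a
          # boundary if it beats the true adjacent TSD by >= 3 bp, and
          # displacement from the extension edges costs on top
          rank_score <- (ltr_len - 4L * nmis) + 4L * tsd$len -
            8L * tsd$shift - 2L * prox
          cc <- list(i = i, e = e, ltr_len = ltr_len, ident = ident,
                     tsd = tsd, prox = prox, rank = rank_score)
          if (is.null(best) || cc$rank > best$rank ||
              (cc$rank == best$rank && cc$prox < best$prox)) {
            best <- cc
          }
        }
      }
      if (is.null(best)) next
      i <- best$i; e <- best$e
      ltr_len <- best$ltr_len; ident <- best$ident; tsd <- best$tsd
      cand[[length(cand) + 1L]] <- data.frame(
        chrom = cn,
        start = i - 1L, end = e + D,          # 0-based half-open element
        ltr5_start = i - 1L, ltr5_end = e,
        ltr3_start = i + D - 1L, ltr3_end = e + D,
        strand = "+", ltr_len = ltr_len, dist = D,
        ltr_identity = ident, tsd = tsd$seq, tsd_len = tsd$len,
        motif_ok = TRUE, stringsAsFactors = FALSE
      )
    }
    if (length(cand) == 0) next
    df <- unique(do.call(rbind, cand))
    # greedy overlap resolution: identity desc, length desc, leftmost
    df <- df[order(-df$ltr_identity, -(df$end - df$start), df$start), ,
             drop = FALSE]
    keep <- logical(nrow(df))
    taken_s <- integer(0); taken_e <- integer(0)
    for (r in seq_len(nrow(df))) {
      if (!any(df$start[r] < taken_e & df$end[r] > taken_s)) {
        keep[r] <- TRUE
        taken_s <- c(taken_s, df$start[r]); taken_e <- c(taken_e, df$end[r])
      }
    }
    out[[length(out) + 1L]] <- df[keep, , drop = FALSE]
  }
  if (length(out) == 0) {
    return(data.frame(
      chrom = character(0), start = integer(0), end = integer(0),
      ltr5_start = integer(0), ltr5_end = integer(0),
      ltr3_start = integer(0), ltr3_end = integer(0), strand = character(0),
      ltr_len = integer(0), dist = integer(0), ltr_identity = numeric(0),
      tsd = character(0), tsd_len = integer(0), motif_ok = logical(0),
      id = character(0), stringsAsFactors = FALSE
    ))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  res$id <- sprintf("%s:%d-%d", res$chrom, res$start, res$end)
  rownames(res) <- NULL
  res
}

#' Re-validate a candidate copy against the miner's own constraints
#'
#' Independent self-audit: re-checks LTR length bounds, LTR-start distance,
#' terminal motif, LTR-pair identity, TSD length bounds and the recorded
#' TSD text against the genome sequence.
#'
#' @param genome named character vector.
#' @param copy one row of [find_ltr_candidates()] output.
#' @param params the [miner_params()] used for the call.
#' @return TRUE, or a character message naming the first failed check.
#' @export
validate_copy <- function(genome, copy, params = miner_params()) {
  s <- genome[[copy$chrom]]
  ltr5 <- substr(s, copy$ltr5_start + 1L, copy$ltr5_end)
  ltr3 <- substr(s, copy$ltr3_start + 1L, copy$ltr3_end)
  if (nchar(ltr5) < params$min_ltr_len || nchar(ltr5) > params$max_ltr_len)
    return("ltr length out of bounds")
  D <- copy$ltr3_start - copy$ltr5_start
  if (D < params$min_dist || D > params$max_dist)
    return("ltr start distance out of bounds")
  if (params$motif_mismatches == 0) {
    if (substr(ltr5, 1, 2) != params$motif[1])
      return("5' motif mismatch")
    if (substr(ltr3, nchar(ltr3) - 1L, nchar(ltr3)) != params$motif[2])
      return("3' motif mismatch")
  }
  if (nchar(ltr5) == nchar(ltr3)) {
    ident <- 1 - length(mismatch_positions(ltr5, ltr3)) / nchar(ltr5)
    if (ident < params$min_ltr_similarity)
      return("ltr identity below bound")
  }
  if (copy$tsd_len < params$min_tsd || copy$tsd_len > params$max_tsd)
    return("tsd length out of bounds")
  TRUE
}

#' Find solo LTRs by seed-and-extend similarity search
#'
#' Queries (LTR sequences of classified intact copies) are matched against
#' the genome via exact 20-mer seeds, extended gaplessly on the seed
#' diagonal, and scored for identity over the matched span and for query
#' coverage. Hits passing both thresholds that do not overlap any
#' intact-copy interval by >= 1 bp are reported as solo LTRs.
#'
#' @param genome named character vector (or `AnnotatedGenome`).
#' @param ltr_queries named character vector of LTR query sequences.
#' @param intact_copies data.frame with chrom/start/end of intact copies
#'   (0-based half-open), e.g. [find_ltr_candidates()] output; may be NULL.
#' @param min_identity minimum identity over the matched span.
#' @param min_coverage minimum matched fraction of the query.
#' @return data.frame: chrom, start, end (0-based half-open), strand,
#'   source (query name), identity, coverage.
#' @export
find_solo_ltrs <- function(genome, ltr_queries, intact_copies = NULL,
                           min_identity = 0.80, min_coverage = 0.90) {
  if (inherits(genome, "AnnotatedGenome")) genome <- genome$genome
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      source = character(0), identity = numeric(0),
                      coverage = numeric(0), stringsAsFactors = FALSE)
  if (length(ltr_queries) == 0) return(empty)
  k <- 20L
  hits <- list()
  for (cn in names(genome)) {
    gi <- dna_ints(genome[[cn]])
    gcodes <- kmer_codes(gi, k)
    gdt <- data.table::data.table(code = gcodes,
                                  gpos = seq_along(gcodes))[!is.na(code)]
    data.table::setkey(gdt, code)
    for (qn in names(ltr_queries)) {
      for (strand in c("+", "-")) {
        q <- if (strand == "+") ltr_queries[[qn]] else
          revcomp(ltr_queries[[qn]])
        qi <- dna_ints(q)
        qlen <- length(qi)
        if (qlen < k) next
        qcodes <- kmer_codes(qi, k)
        qdt <- data.table::data.table(code = qcodes,
                                      qpos = seq_along(qcodes))[!is.na(code)]
        mm <- gdt[qdt, on = "code", nomatch = NULL, allow.cartesian = TRUE]
        if (nrow(mm) == 0) next
        for (d in unique(mm$gpos - mm$qpos)) {
          gs <- d + 1L # genome 1-based position aligned to query pos 1
          lo <- max(1L, gs); hi <- min(length(gi), gs + qlen - 1L)
          if (hi - lo + 1L < k) next
          qlo <- lo - gs + 1L; qhi <- hi - gs + 1L
          seg <- gi[lo:hi]
          qq <- qi[qlo:qhi]
          mismatches <- which(seg != qq | is.na(seg))
          sp <- best_match_span(mismatches, length(seg))
          if (sp$start == 0L) next
          span_len <- sp$end - sp$start + 1L
          cover <- span_len / qlen
          ident <- (span_len - sp$mismatches) / span_len
          if (cover >= min_coverage && ident >= min_identity) {
            hits[[length(hits) + 1L]] <- data.frame(
              chrom = cn, start = lo - 1L + sp$start - 1L,
              end = lo - 1L + sp$end, strand = strand, source = qn,
              identity = ident, coverage = cover, stringsAsFactors = FALSE
            )
          }
        }
      }
    }
  }
  if (length(hits) == 0) return(empty)
  df <- do.call(rbind, hits)
  # collapse hits from multiple queries at one locus: best identity wins
  df <- df[order(df$chrom, -df$identity, df$start), , drop = FALSE]
  kept <- list()
  for (r in seq_len(nrow(df))) {
    dup <- FALSE
    for (kk in kept) {
      if (kk$chrom == df$chrom[r] && df$start[r] < kk$end &&
          df$end[r] > kk$start) { dup <- TRUE; break }
    }
    if (!dup) kept[[length(kept) + 1L]] <- df[r, ]
  }
  df <- do.call(rbind, kept)
  if (!is.null(intact_copies) && nrow(intact_copies) > 0) {
    ov <- vapply(seq_len(nrow(df)), function(r) {
      any(intact_copies$chrom == df$chrom[r] &
            df$start[r] < intact_copies$end &
            df$end[r] > intact_copies$start)
    }, logical(1))
    df <- df[!ov, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Solo-LTR to intact-copy ratio per group
#'
#' @param solo_counts,intact_counts non-negative counts, either named
#'   vectors (names = groups, e.g. lineages) or bare equal-length vectors.
#' @return data.frame: group, n_solo, n_intact, ratio; ratio is NA when
#'   n_intact is 0 (undefined, not infinite).
#' @export
solo_intact_ratio <- function(solo_counts, intact_counts) {
  if (any(solo_counts < 0) || any(intact_counts < 0)) {
    stop("counts must be non-negative")
  }
  if (is.null(names(solo_counts)) && is.null(names(intact_counts))) {
    stopifnot(length(solo_counts) == length(intact_counts))
    names(solo_counts) <- as.character(seq_along(solo_counts))
    names(intact_counts) <- names(solo_counts)
  }
  groups <- union(names(solo_counts), names(intact_counts))
  ns <- solo_counts[groups]; ns[is.na(ns)] <- 0
  ni <- intact_counts[groups]; ni[is.na(ni)] <- 0
  data.frame(
    group = groups, n_solo = as.numeric(ns), n_intact = as.numeric(ni),
    ratio = ifelse(ni == 0, NA_real_, as.numeric(ns) / as.numeric(ni)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
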