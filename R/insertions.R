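## Non-reference LTR-RT insertion calling from paired-end WGS reads:
## windowed discordant-pair signatures (a window is a candidate when enough
## reads whose mates hit the element library anchor uniquely inside it),
## soft-clip breakpoint refinement to <= 200 bp, cross-sample comparison,
## and the mask-and-revalidate accuracy harness.

#' Fold coverage from mapped read counts
#'
#' `coverage = mapped read count * read length / genome size`.
#'
#' @param n_mapped mapped read count.
#' @param read_len read length (bp).
#' @param genome_size total genome size (bp).
#' @return fold coverage (numeric).
#' @export
estimate_coverage <- function(n_mapped, read_len, genome_size) {
  if (genome_size <= 0) stop("genome size must be positive")
  stopifnot(n_mapped >= 0, read_len > 0)
  n_mapped * read_len / genome_size
}

#' Call candidate insertion windows from paired-end reads
#'
#' The genome is partitioned into fixed non-overlapping windows (default
#' 10 kb). A window is a candidate for element subfamily S when at least
#' `min_support` read pairs have one mate hitting S in the element library
#' and the other mate mapping *uniquely* (single best placement) into the
#' window. Multi-mapping anchor mates are dropped, so insertions into
#' repetitive regions go unreported. Reads shorter than `min_read_len` are
#' discarded up front (QC length floor).
#'
#' @param r1,r2 named character vectors of mates (shared names).
#' @param te_library named character vector: element/subfamily references.
#' @param genome named character vector, or a prebuilt [build_ref_index()].
#' @param window window size (bp).
#' @param min_support minimum supporting pairs per window.
#' @param min_read_len minimum read length.
#' @param min_te_span minimum aligned span to count a library hit.
#' @param min_anchor_frac minimum aligned fraction for a unique genome
#'   anchor.
#' @return list: `windows` (data.frame subfamily/chrom/win_start/win_end/
#'   support), `genome_aln` (all genome alignments, for refinement),
#'   `te_hits` (read id -> subfamily).
#' @export
call_windows <- function(r1, r2, te_library, genome, window = 10000L,
                         min_support = 2L, min_read_len = 50L,
                         min_te_span = 30L, min_anchor_frac = 0.6) {
  stopifnot(identical(names(r1), names(r2)))
  keep <- nchar(r1) >= min_read_len & nchar(r2) >= min_read_len
  r1 <- r1[keep]; r2 <- r2[keep]
  reads <- c(stats::setNames(r1, paste0(names(r1), "/1")),
             stats::setNames(r2, paste0(names(r2), "/2")))
  te_aln <- map_reads(reads, te_library, min_span = min_te_span)
  te_hits <- stats::setNames(te_aln$ref, te_aln$read_id)
  g_aln <- map_reads(reads, genome)
  win <- data.frame(subfamily = character(0), chrom = character(0),
                    win_start = integer(0), win_end = integer(0),
                    support = integer(0), stringsAsFactors = FALSE)
  if (length(te_hits) > 0 && nrow(g_aln) > 0) {
    ga <- g_aln
    rl <- ga$span + ga$clip_left + ga$clip_right
    ga <- ga[ga$n_best == 1L & ga$span >= min_anchor_frac * rl, ,
             drop = FALSE]
    if (nrow(ga) > 0) {
      base <- sub("/[12]$", "", ga$read_id)
      mate_id <- paste0(base, ifelse(grepl("/1$", ga$read_id), "/2", "/1"))
      subfam <- te_hits[mate_id]
      anchored <- !is.na(subfam)
      if (any(anchored)) {
        dt <- data.table::data.table(
          pair = base[anchored],
          subfamily = unname(subfam[anchored]),
          chrom = ga$ref[anchored],
          win_start = (ga$pos[anchored] %/% window) * window
        )
        dt <- unique(dt) # a pair supports a window once
        agg <- dt[, list(support = .N),
                  by = c("subfamily", "chrom", "win_start")]
        agg <- agg[support >= min_support]
        if (nrow(agg) > 0) {
          win <- data.frame(
            subfamily = agg$subfamily, chrom = agg$chrom,
            win_start = agg$win_start,
            win_end = agg$win_start + window,
            support = agg$support, stringsAsFactors = FALSE
          )
          win <- win[order(win$chrom, win$win_start, win$subfamily), ,
                     drop = FALSE]
          rownames(win) <- NULL
        }
      }
    }
  }
  list(windows = win, genome_aln = g_aln, te_hits = te_hits,
       window = window)
}

## Match a clipped sequence against an LTR terminus, tolerating a small
## boundary shift: bases of the element terminus that happen to match the
## reference flank are absorbed into the aligned core, so the clip can
## start `s` bases inside the element (s = 0..max_shift). Returns the best
## such shift, or NA when no orientation reaches `min_ident`.
## side "right": clip extends rightwards into the element -- its head is
## compared with the LTR start (or reverse-complemented LTR end);
## side "left": clip extends leftwards -- its tail is compared with the LTR
## end (or reverse-complemented LTR start).
.clip_terminus_shift <- function(clip, ltr_seqs, side, min_ident = 0.8,
                                 max_cmp = 30L, max_shift = 6L) {
  n <- nchar(clip)
  m <- min(n, max_cmp)
  if (m == 0L) return(NA_integer_)
  probe <- if (side == "right") substr(clip, 1L, m) else
    substr(clip, n - m + 1L, n)
  best_s <- NA_integer_; best_ident <- -1
  for (ltr in ltr_seqs) {
    for (term0 in c(ltr, revcomp(ltr))) {
      L <- nchar(term0)
      for (s in 0:max_shift) {
        mm <- min(m, L - s)
        if (mm < 5L) next
        tt <- if (side == "right") substr(term0, 1L + s, s + mm) else
          substr(term0, L - s - mm + 1L, L - s)
        pr <- if (side == "right") substr(probe, 1L, mm) else
          substr(probe, m - mm + 1L, m)
        ident <- 1 - length(mismatch_positions(pr, tt)) / mm
        if (ident >= min_ident &&
            (ident > best_ident ||
               (ident == best_ident && s < best_s))) {
          best_ident <- ident; best_s <- s
        }
      }
    }
  }
  best_s
}

## qualifying soft-clip breakpoints within a region: data.frame(pos, side)
.softclip_breakpoints <- function(genome_aln, chrom, lo, hi, ltr_seqs,
                                  min_clip = 8L, min_ident = 0.8) {
  ga <- genome_aln[genome_aln$ref == chrom, , drop = FALSE]
  out <- list()
  if (nrow(ga) > 0) {
    rc <- ga$clip_right >= min_clip
    bp_r <- ga$pos + ga$span
    sel_r <- which(rc & bp_r >= lo - 6L & bp_r <= hi + 6L)
    for (i in sel_r) {
      s <- .clip_terminus_shift(ga$clip_seq_right[i], ltr_seqs, "right",
                                min_ident)
      if (!is.na(s)) {
        # the core absorbed s element bases: true breakpoint is s left
        out[[length(out) + 1L]] <- data.frame(pos = bp_r[i] - s,
                                              side = "right",
                                              stringsAsFactors = FALSE)
      }
    }
    lc <- ga$clip_left >= min_clip
    sel_l <- which(lc & ga$pos >= lo - 6L & ga$pos <= hi + 6L)
    for (i in sel_l) {
      s <- .clip_terminus_shift(ga$clip_seq_left[i], ltr_seqs, "left",
                                min_ident)
      if (!is.na(s)) {
        out[[length(out) + 1L]] <- data.frame(pos = ga$pos[i] + s,
                                              side = "left",
                                              stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(pos = integer(0), side = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Refine a candidate window to a breakpoint interval
#'
#' Soft-clipped reads in the window (extended by one window on each side)
#' whose clipped sequence matches an LTR terminus of the subfamily (>= 80%
#' identity by default) define the breakpoint cluster. The refined interval
#' is the min-max of qualifying clip positions and is reported only when
#' its span is at most `max_span` bp (the window-level call is retained
#' either way). When the left- and right-clip clusters overlap by 2-20 bp
#' the overlap is reported as the target-site duplication.
#'
#' @param win one row of `call_windows()$windows`.
#' @param genome_aln genome alignments (from [call_windows()]).
#' @param ltr_seqs character vector of LTR sequence(s) of the subfamily.
#' @param max_span maximum refined-interval span (bp).
#' @param min_clip minimum clip length considered.
#' @param min_ident minimum clip-terminus identity.
#' @return list(start, end, n_clip, tsd_len); start/end NA when no
#'   qualifying cluster (or span > max_span).
#' @export
refine_breakpoints <- function(win, genome_aln, ltr_seqs, max_span = 200L,
                               min_clip = 8L, min_ident = 0.8) {
  wsize <- win$win_end - win$win_start
  bps <- .softclip_breakpoints(
    genome_aln, win$chrom, win$win_start - wsize, win$win_end + wsize,
    ltr_seqs, min_clip, min_ident
  )
  if (nrow(bps) == 0) {
    return(list(start = NA_integer_, end = NA_integer_, n_clip = 0L,
                tsd_len = NA_integer_))
  }
  # breakpoints from neighbouring sites can fall inside the padded search
  # region: single-linkage cluster the positions (gap > max_span separates)
  # and take the largest cluster touching the window proper
  bps <- bps[order(bps$pos), , drop = FALSE]
  cl <- cumsum(c(1L, diff(bps$pos) > max_span))
  in_win <- vapply(split(bps$pos, cl), function(p) {
    any(p >= win$win_start & p <= win$win_end)
  }, logical(1))
  sizes <- tabulate(cl)
  sizes[!in_win] <- 0L
  if (all(sizes == 0L)) {
    return(list(start = NA_integer_, end = NA_integer_,
                n_clip = nrow(bps), tsd_len = NA_integer_))
  }
  bps <- bps[cl == which.max(sizes), , drop = FALSE]
  span_lo <- min(bps$pos); span_hi <- max(bps$pos)
  if (span_hi - span_lo > max_span) {
    return(list(start = NA_integer_, end = NA_integer_,
                n_clip = nrow(bps), tsd_len = NA_integer_))
  }
  tsd <- NA_integer_
  lmode <- .mode_int(bps$pos[bps$side == "left"])
  rmode <- .mode_int(bps$pos[bps$side == "right"])
  if (!is.na(lmode) && !is.na(rmode)) {
    t <- rmode - lmode
    if (t >= 2L && t <= 20L) tsd <- as.integer(t)
  }
  list(start = as.integer(span_lo), end = as.integer(span_hi),
       n_clip = nrow(bps), tsd_len = tsd)
}

.mode_int <- function(x) {
  if (length(x) == 0) return(NA_integer_)
  tab <- table(x)
  as.integer(names(tab)[which.max(tab)])
}

#' Merge per-sample insertion calls into status-labeled sites
#'
#' Calls whose intervals (refined when available, windows otherwise) lie
#' within `merge_dist` of each other are the same site (single linkage per
#' chromosome and subfamily). Site status: `reference` when overlapping an
#' annotated reference copy (padded by `merge_dist`); otherwise
#' `shared-non-reference` when called in two or more samples, `private`
#' when called in one.
#'
#' @param calls data.frame: sample, subfamily, chrom, start, end.
#' @param reference_copies data.frame chrom/start/end of annotated copies
#'   (may be NULL).
#' @param merge_dist maximum gap between merged intervals (bp).
#' @return list: `sites` (site_id, subfamily, chrom, start, end, status,
#'   n_samples), `presence` (logical site x sample matrix).
#' @export
compare_samples <- function(calls, reference_copies = NULL,
                            merge_dist = 200L) {
  samples <- sort(unique(calls$sample))
  if (nrow(calls) == 0) {
    return(list(sites = data.frame(), presence = matrix(logical(0), 0, 0)))
  }
  calls <- calls[order(calls$subfamily, calls$chrom, calls$start), ,
                 drop = FALSE]
  site_id <- integer(nrow(calls))
  cur <- 0L; cur_end <- -Inf; cur_key <- ""
  for (i in seq_len(nrow(calls))) {
    key <- paste(calls$subfamily[i], calls$chrom[i])
    if (key != cur_key || calls$start[i] > cur_end + merge_dist) {
      cur <- cur + 1L
      cur_key <- key
      cur_end <- calls$end[i]
    } else {
      cur_end <- max(cur_end, calls$end[i])
    }
    site_id[i] <- cur
  }
  calls$site <- site_id
  sites <- do.call(rbind, lapply(split(calls, calls$site), function(g) {
    data.frame(
      site_id = g$site[1], subfamily = g$subfamily[1], chrom = g$chrom[1],
      start = min(g$start), end = max(g$end),
      n_samples = length(unique(g$sample)), stringsAsFactors = FALSE
    )
  }))
  is_ref <- rep(FALSE, nrow(sites))
  if (!is.null(reference_copies) && nrow(reference_copies) > 0) {
    for (i in seq_len(nrow(sites))) {
      is_ref[i] <- any(
        reference_copies$chrom == sites$chrom[i] &
          sites$start[i] < reference_copies$end + merge_dist &
          sites$end[i] > reference_copies$start - merge_dist
      )
    }
  }
  sites$status <- ifelse(is_ref, "reference",
                         ifelse(sites$n_samples >= 2,
                                "shared-non-reference", "private"))
  presence <- matrix(FALSE, nrow(sites), length(samples),
                     dimnames = list(sites$site_id, samples))
  for (i in seq_len(nrow(calls))) {
    presence[as.character(calls$site[i]), calls$sample[i]] <- TRUE
  }
  rownames(sites) <- NULL
  list(sites = sites, presence = presence)
}

#' Mask reference insertion sites in a genome
#'
#' Two modes. `excise` (default) removes the element *plus one TSD copy*,
#' restoring the pre-insertion empty allele -- reads from an element-bearing
#' sample then soft-clip informatively at the empty site. `nmask` replaces
#' the element bases with N, keeping coordinates unchanged.
#'
#' @param genome named character vector.
#' @param sites data.frame: chrom, start, end (element interval, 0-based
#'   half-open) and tsd_len (required for excision).
#' @param mode "excise" or "nmask".
#' @return list(genome, sites) where sites gains `masked_pos`: the
#'   breakpoint coordinate of each site on the masked genome.
#' @export
mask_genome <- function(genome, sites, mode = c("excise", "nmask")) {
  mode <- match.arg(mode)
  if (mode == "excise" &&
      (is.null(sites$tsd_len) || any(is.na(sites$tsd_len)))) {
    stop("excise mode requires a tsd_len annotation for every site")
  }
  sites$masked_pos <- NA_integer_
  if (mode == "nmask") {
    for (i in seq_len(nrow(sites))) {
      cn <- sites$chrom[i]
      s <- genome[[cn]]
      substr(s, sites$start[i] + 1L, sites$end[i]) <-
        paste(rep("N", sites$end[i] - sites$start[i]), collapse = "")
      genome[[cn]] <- s
      sites$masked_pos[i] <- sites$start[i]
    }
    return(list(genome = genome, sites = sites))
  }
  for (cn in unique(sites$chrom)) {
    idx <- which(sites$chrom == cn)
    idx <- idx[order(sites$start[idx])]
    shift <- 0L
    s <- genome[[cn]]
    pieces <- character(0); at <- 1L
    for (i in idx) {
      # remove element plus the right-hand TSD copy
      cut_s <- sites$start[i]; cut_e <- sites$end[i] + sites$tsd_len[i]
      pieces <- c(pieces, substr(s, at, cut_s))
      # breakpoint on masked coords: insertion point = left-TSD start
      sites$masked_pos[i] <- cut_s - shift - sites$tsd_len[i]
      shift <- shift + (cut_e - cut_s)
      at <- cut_e + 1L
    }
    pieces <- c(pieces, substr(s, at, nchar(s)))
    genome[[cn]] <- paste(pieces, collapse = "")
  }
  list(genome = genome, sites = sites)
}

#' Validation-design call table size and error rates
#'
#' The mask-and-revalidate design evaluates every (reference site, read
#' set) cell: `n_calls = n_sites * n_samples`. Rates are percentages of
#' `n_calls`, rounded to one decimal (round-half-even); the raw counts are
#' always carried so any rounding convention can be audited.
#'
#' @param n_sites,n_samples design dimensions.
#' @param fp_count soft-clip calls at reference sites in the unmasked run.
#' @param fn_count masked sites without a soft-clip call.
#' @return list(n_sites, n_samples, n_calls, fp_count, fn_count, fp_rate,
#'   fn_rate).
#' @export
validation_report <- function(n_sites, n_samples, fp_count, fn_count) {
  n_calls <- n_sites * n_samples
  stopifnot(fp_count >= 0, fn_count >= 0,
            fp_count <= n_calls, fn_count <= n_calls)
  list(n_sites = n_sites, n_samples = n_samples, n_calls = n_calls,
       fp_count = fp_count, fn_count = fn_count,
       fp_rate = round(100 * fp_count / n_calls, 1),
       fn_rate = round(100 * fn_count / n_calls, 1))
}

#' Mask-and-revalidate accuracy harness
#'
#' Builds the original and masked references, maps every read set against
#' both, and scores each (site, sample) cell: a false positive is a
#' qualifying soft-clip call at a reference site on the *unmasked* genome
#' (where the site is still occupied, so no breakpoint should be visible);
#' a false negative is a masked (empty) site with *no* soft-clip call. A
#' qualifying call is at least one read with a clip of `min_clip`+ bp
#' within `tol` bp of the site breakpoint whose clipped sequence matches an
#' LTR terminus.
#'
#' @param genome named character vector.
#' @param sites reference insertion sites (chrom, start, end, tsd_len).
#' @param read_sets named list; each entry a list(r1, r2).
#' @param ltr_seqs LTR sequence(s) of the masked element subfamily.
#' @param mode masking mode, see [mask_genome()].
#' @param tol breakpoint matching tolerance (bp).
#' @param min_clip,min_ident soft-clip qualification parameters.
#' @return a [validation_report()], plus `cells`: the per-cell data.frame
#'   (site, sample, fp, fn).
#' @export
mask_and_validate <- function(genome, sites, read_sets, ltr_seqs,
                              mode = "excise", tol = 200L, min_clip = 8L,
                              min_ident = 0.8) {
  masked <- mask_genome(genome, sites, mode)
  idx_un <- build_ref_index(genome)
  idx_ma <- build_ref_index(masked$genome)
  cells <- list()
  fp <- 0L; fn <- 0L
  for (sample in names(read_sets)) {
    rs <- read_sets[[sample]]
    reads <- c(stats::setNames(rs$r1, paste0(names(rs$r1), "/1")),
               stats::setNames(rs$r2, paste0(names(rs$r2), "/2")))
    aln_un <- map_reads(reads, idx_un)
    aln_ma <- map_reads(reads, idx_ma)
    for (i in seq_len(nrow(sites))) {
      st <- sites[i, ]
      # unmasked: any qualifying clip at either element boundary is a FP
      bp_un <- .softclip_breakpoints(
        aln_un, st$chrom, st$start - tol, st$start + tol, ltr_seqs,
        min_clip, min_ident)
      bp_un2 <- .softclip_breakpoints(
        aln_un, st$chrom, st$end - tol, st$end + tol, ltr_seqs,
        min_clip, min_ident)
      is_fp <- nrow(bp_un) + nrow(bp_un2) > 0
      mp <- masked$sites$masked_pos[i]
      pad <- tol + max(0L, st$tsd_len, na.rm = TRUE)
      bp_ma <- .softclip_breakpoints(
        aln_ma, st$chrom, mp - pad, mp + pad, ltr_seqs,
        min_clip, min_ident)
      is_fn <- nrow(bp_ma) == 0
      fp <- fp + is_fp; fn <- fn + is_fn
      cells[[length(cells) + 1L]] <- data.frame(
        site = i, sample = sample, fp = is_fp, fn = is_fn,
        stringsAsFactors = FALSE
      )
    }
  }
  rep <- validation_report(nrow(sites), length(read_sets), fp, fn)
  rep$cells <- do.call(rbind, cells)
  rep
}
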