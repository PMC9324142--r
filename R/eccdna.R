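## Mobilome (eccDNA-seq) profiling: organelle-read removal, mapping against
## an LTR-RT reference library, RPKM normalization, enrichment testing,
## candidate-subfamily retention, and circle-junction detection with NHEJ
## indel signatures.

#' Remove read pairs of organellar origin
#'
#' Pairs with either mate mapping to a chloroplast/mitochondrial reference
#' are dropped. An empty organelle set is the identity.
#'
#' @param r1,r2 named character vectors (mates share names).
#' @param organelle_refs named character vector of organelle genomes; may
#'   be NULL or empty.
#' @return list(r1, r2) of retained pairs.
#' @export
filter_organelle_reads <- function(r1, r2, organelle_refs = NULL) {
  stopifnot(identical(names(r1), names(r2)))
  if (is.null(organelle_refs) || length(organelle_refs) == 0) {
    return(list(r1 = r1, r2 = r2))
  }
  al <- map_reads(c(stats::setNames(r1, paste0(names(r1), "/1")),
                    stats::setNames(r2, paste0(names(r2), "/2"))),
                  organelle_refs)
  hit <- unique(sub("/[12]$", "", al$read_id))
  keep <- !(names(r1) %in% hit)
  list(r1 = r1[keep], r2 = r2[keep])
}

#' Per-subfamily read profile with RPKM
#'
#' RPKM = count * 1e9 / (reference length * total mapped reads). The hit
#' fraction is the fraction of a subfamily's reads whose aligned core
#' covers at least `hit_cover` of the read -- the mapping-based analogue of
#' "reads with hits to the LTR-RT database" within a read cluster.
#'
#' @param alignments [map_reads()] output against the LTR-RT library.
#' @param ref_lengths named vector: reference (subfamily) lengths in bp.
#' @param total_mapped total mapped reads in the library (normalization
#'   denominator); must be > 0.
#' @param hit_cover aligned-core coverage defining a "hit" read.
#' @return data.frame: subfamily, n_reads, ref_len, rpkm, hit_fraction.
#' @export
profile_subfamilies <- function(alignments, ref_lengths, total_mapped,
                                hit_cover = 0.8) {
  if (total_mapped <= 0) stop("total mapped reads must be positive")
  out <- data.frame(
    subfamily = names(ref_lengths),
    n_reads = 0L, ref_len = as.numeric(ref_lengths), rpkm = 0,
    hit_fraction = NA_real_, stringsAsFactors = FALSE
  )
  if (nrow(alignments) > 0) {
    rl <- alignments$span + alignments$clip_left + alignments$clip_right
    is_hit <- alignments$span >= hit_cover * rl
    agg <- stats::aggregate(
      cbind(n = rep(1L, nrow(alignments)), hit = as.integer(is_hit)),
      by = list(subfamily = alignments$ref), FUN = sum
    )
    i <- match(agg$subfamily, out$subfamily)
    ok <- !is.na(i)
    out$n_reads[i[ok]] <- agg$n[ok]
    out$hit_fraction[i[ok]] <- agg$hit[ok] / agg$n[ok]
  }
  out$rpkm <- out$n_reads * 1e9 / (out$ref_len * total_mapped)
  rownames(out) <- NULL
  out
}

#' Pairwise chi-squared enrichment test
#'
#' 2x2 chi-squared test without continuity correction on
#' `[count, total - count]` across two samples; when any expected cell is
#' below 5 the P value is obtained by Monte-Carlo simulation instead.
#'
#' @param count_a,total_a reads in the cluster / total reads, sample A.
#' @param count_b,total_b the same for sample B.
#' @param mc_reps Monte-Carlo replicates for small expected counts.
#' @param seed seed for the Monte-Carlo path (determinism).
#' @return list(chi2, p, simulated).
#' @export
test_enrichment <- function(count_a, total_a, count_b, total_b,
                            mc_reps = 10000, seed = 1) {
  stopifnot(total_a >= count_a, total_b >= count_b,
            count_a >= 0, count_b >= 0)
  m <- matrix(c(count_a, total_a - count_a,
                count_b, total_b - count_b), nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(list(chi2 = NA_real_, p = NA_real_, simulated = FALSE))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected < 5)) {
    res <- with_seed(derive_seed(seed, "mc-chisq"), {
      stats::chisq.test(m, simulate.p.value = TRUE, B = mc_reps)
    })
    return(list(chi2 = unname(res$statistic), p = res$p.value,
                simulated = TRUE))
  }
  res <- stats::chisq.test(m, correct = FALSE)
  list(chi2 = unname(res$statistic), p = res$p.value, simulated = FALSE)
}

#' Retain candidate-active subfamilies
#'
#' Keeps subfamilies with more than `min_reads` mapped reads and an LTR-RT
#' hit fraction above `min_hit_fraction` -- the cluster-retention criteria
#' (cluster size > 500, over 50% reads with database hits). The read-count
#' threshold is calibrated to a 500 000-read comparative sample; scale it
#' for other library sizes.
#'
#' @param profiles [profile_subfamilies()] output.
#' @param min_reads cluster-size threshold (exclusive).
#' @param min_hit_fraction hit-fraction threshold (exclusive).
#' @return the retained rows of `profiles`.
#' @export
filter_candidates <- function(profiles, min_reads = 500,
                              min_hit_fraction = 0.5) {
  keep <- profiles$n_reads > min_reads &
    !is.na(profiles$hit_fraction) & profiles$hit_fraction > min_hit_fraction
  profiles[keep, , drop = FALSE]
}

## Junction references for the two circle topologies. The two-LTR junction
## (element 3' end joined to element 5' start, the CA|TG adjacency) occurs
## nowhere in the linear element, so any read spanning it is circle
## evidence. The one-LTR circle carries no locally unique junction -- its
## LTR/internal boundaries also exist in the linear element -- so its
## reference is internal-end + one full LTR + internal-start, and evidence
## requires matched anchors in the *internal* arms on both sides: the read
## must bridge the whole LTR, which no linear-element read can do.
.junction_refs <- function(element, arm = 150L) {
  seq <- element$seq
  ltr <- element$ltr5
  internal <- element$internal
  two <- paste0(substr(seq, nchar(seq) - arm + 1L, nchar(seq)),
                substr(seq, 1L, arm))
  one <- paste0(substr(internal, nchar(internal) - arm + 1L,
                       nchar(internal)),
                ltr, substr(internal, 1L, arm))
  list(
    `two-LTR` = list(seq = two, left_end = arm, right_start = arm,
                     center = arm),
    `one-LTR` = list(seq = one, left_end = arm,
                     right_start = arm + nchar(ltr),
                     center = arm + nchar(ltr))
  )
}

#' Detect circle junctions with NHEJ indel signatures
#'
#' Builds the junction reference of each eccDNA topology from the element
#' model -- two-LTR: element 3' end joined to element 5' start (the NHEJ
#' product of a full linear extrachromosomal copy); one-LTR: a single LTR
#' joined to the internal-region start (the LTR-LTR recombination product)
#' -- and screens reads against both. Reads whose aligned core or
#' clip boundary touches the junction are realigned with affine gaps and
#' accepted as junction evidence when at least `min_anchor` bp match on
#' both sides of the junction and the net indel at the junction is at most
#' `max_indel` bp. Duplicate read sequences are collapsed first (circle
#' amplification bias) unless `dedup = FALSE`.
#'
#' @param reads named character vector (typically both mates pooled).
#' @param element a built element model (entry of `AnnotatedGenome$elements`)
#'   or a list with `seq`, `ltr5`, `internal`, `spec`.
#' @param min_anchor minimum matched bases on each side of the junction.
#' @param max_indel maximum absolute junction indel (bp).
#' @param arm junction-reference arm length (bp).
#' @param dedup collapse duplicate read sequences before counting.
#' @return data.frame: read_id, element, topology, junction_offset (0-based
#'   position of the junction on the read), indel, anchor_left,
#'   anchor_right, score.
#' @export
detect_junctions <- function(reads, element, min_anchor = 15L,
                             max_indel = 20L, arm = 150L, dedup = TRUE) {
  empty <- data.frame(
    read_id = character(0), element = character(0), topology = character(0),
    junction_offset = integer(0), indel = integer(0),
    anchor_left = integer(0), anchor_right = integer(0), score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (length(reads) == 0) return(empty)
  if (dedup) reads <- reads[!duplicated(unname(reads))]
  refs <- .junction_refs(element, arm)
  seqs <- vapply(refs, `[[`, character(1), "seq")
  al <- map_reads(reads, seqs, min_span = min_anchor)
  if (nrow(al) == 0) return(empty)
  # loose screen: the gapless core reaches one anchor region and either
  # crosses towards the other or is clipped (possible junction indel)
  touches <- logical(nrow(al))
  for (i in seq_len(nrow(al))) {
    jr <- refs[[al$ref[i]]]
    core_s <- al$pos[i]; core_e <- al$pos[i] + al$span[i] # 0-based ho
    reach_l <- core_s <= jr$left_end - min_anchor || al$clip_left[i] > 0
    reach_r <- core_e >= jr$right_start + min_anchor || al$clip_right[i] > 0
    touches[i] <- reach_l && reach_r
  }
  cand <- al[touches, , drop = FALSE]
  if (nrow(cand) == 0) return(empty)
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -2)
  out <- list()
  for (i in seq_len(nrow(cand))) {
    rid <- cand$read_id[i]
    rseq <- reads[[rid]]
    if (cand$strand[i] == "-") rseq <- revcomp(rseq)
    best <- NULL
    for (topo in names(refs)) {
      jr <- refs[[topo]]
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(rseq), Biostrings::DNAString(jr$seq),
        type = "local", substitutionMatrix = sm,
        gapOpening = 6, gapExtension = 1
      )
      ev <- .junction_evidence(aln, jr$left_end, jr$right_start, jr$center,
                               min_anchor, max_indel)
      if (is.null(ev)) next
      ev$topology <- topo
      if (is.null(best) || ev$score > best$score) best <- ev
    }
    if (!is.null(best)) {
      out[[length(out) + 1L]] <- data.frame(
        read_id = rid, element = element$spec$name, topology = best$topology,
        junction_offset = best$junction_offset, indel = best$indel,
        anchor_left = best$anchor_left, anchor_right = best$anchor_right,
        score = best$score, stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0) return(empty)
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

## Parse one read-vs-junction-reference alignment: matched anchors within
## the two anchor regions (reference columns <= left_end and > right_start)
## and the net indel within a window around the circularization point.
.junction_evidence <- function(aln, left_end, right_start, center,
                               min_anchor, max_indel) {
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  s_start <- Biostrings::start(Biostrings::subject(aln))
  p_start <- Biostrings::start(Biostrings::pattern(aln))
  # reference/read position per column; gap columns carry the previous pos
  s_pos <- s_start - 1L + cumsum(s != "-")
  p_pos <- p_start - 1L + cumsum(p != "-")
  match_col <- p == s & p != "-"
  anchor_left <- sum(match_col & s_pos <= left_end)
  anchor_right <- sum(match_col & s_pos > right_start)
  if (anchor_left < min_anchor || anchor_right < min_anchor) return(NULL)
  win <- s_pos >= center - max_indel - 2L & s_pos <= center + max_indel + 2L
  ins <- sum(s[win] == "-")
  del <- sum(p[win] == "-" & s[win] != "-")
  indel <- ins - del
  if (abs(indel) > max_indel) return(NULL)
  jcols <- which(s_pos >= center)
  junction_offset <- if (length(jcols) == 0) NA_integer_ else
    p_pos[jcols[1L]] - 1L
  list(junction_offset = junction_offset, indel = as.integer(indel),
       anchor_left = anchor_left, anchor_right = anchor_right,
       score = Biostrings::score(aln))
}
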