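## Protein-domain detection and lineage assignment. Superfamily and lineage
## labels come from best hits of six-frame translated copy sequence against
## a lineage-tagged protein-domain reference set (headers LINEAGE#DOMAIN#id).

#' Default domain score threshold
#'
#' 60% of the self-alignment score of the shortest reference peptide, the
#' most permissive self-consistent bound for the supplied database.
#' @param domain_db named character vector of reference peptides.
#' @return numeric score threshold.
#' @export
domain_score_min <- function(domain_db) {
  shortest <- domain_db[[which.min(nchar(domain_db))]]
  self <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(shortest), Biostrings::AAString(shortest),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE
  )
  0.6 * self
}

## cheap exact-seed prefilter: does any of a few 10-aa words of the
## reference peptide occur verbatim in the frame translation?
.peptide_prefilter <- function(ref, frame_peps) {
  L <- nchar(ref)
  if (L < 10L) return(rep(TRUE, length(frame_peps)))
  at <- unique(pmax(1L, c(1L, L %/% 2L - 4L, L - 9L)))
  words <- vapply(at, function(i) substr(ref, i, i + 9L), character(1))
  res <- rep(FALSE, length(frame_peps))
  for (w in words) {
    res <- res | vapply(frame_peps, function(p) {
      grepl(w, p, fixed = TRUE)
    }, logical(1), USE.NAMES = FALSE)
  }
  res
}

#' Detect conserved protein domains in an element copy
#'
#' Six-frame translated search of the copy sequence against a
#' lineage-tagged protein-domain reference set (FASTA header contract
#' `LINEAGE#DOMAIN#id`, domain one of GAG/PR/INT/RT/RH). Local alignment
#' under BLOSUM62 (gap opening 10, extension 0.5); the best hit per domain
#' type is kept if its score reaches `score_min`. An exact 10-mer peptide
#' seed prefilter skips references with no verbatim word in any frame;
#' heavily diverged domains (no intact 10-mer) are therefore not recovered,
#' which mirrors the detection floor of seed-based domain searches.
#'
#' @param copy_seq element nucleotide sequence (character scalar).
#' @param domain_db named character vector of peptides, names
#'   `LINEAGE#DOMAIN#id`.
#' @param score_min minimum alignment score; default
#'   [domain_score_min()] of the database.
#' @return data.frame: domain, lineage, frame, start, end (0-based
#'   half-open nucleotide interval on the element, plus strand), score.
#' @export
detect_domains <- function(copy_seq, domain_db, score_min = NULL) {
  bad <- !grepl("^[^#]+#(GAG|PR|INT|RT|RH)#", names(domain_db))
  if (any(bad)) {
    stop("malformed domain-db header(s): ",
         paste(names(domain_db)[bad], collapse = ", "),
         " (expected LINEAGE#DOMAIN#id)")
  }
  if (is.null(score_min)) score_min <- domain_score_min(domain_db)
  frames <- six_frame_translate(copy_seq)
  n <- nchar(copy_seq)
  lineages <- sub("#.*$", "", names(domain_db))
  domains <- sub("^[^#]+#([^#]+)#.*$", "\\1", names(domain_db))
  hits <- list()
  pre <- lapply(domain_db, .peptide_prefilter, frame_peps = frames$peptide)
  for (ri in seq_along(domain_db)) {
    keep_frames <- which(pre[[ri]])
    if (length(keep_frames) == 0) next
    for (fi in keep_frames) {
      pep <- frames$peptide[fi]
      if (nchar(pep) < 5L) next
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pep), Biostrings::AAString(domain_db[[ri]]),
        type = "local", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5
      )
      sc <- Biostrings::score(aln)
      if (sc < score_min) next
      aa_s <- Biostrings::start(Biostrings::pattern(aln))
      aa_e <- Biostrings::end(Biostrings::pattern(aln))
      f <- frames$frame[fi]; off <- frames$offset[fi]
      if (f > 0) {
        nt_s <- off + 3L * (aa_s - 1L)
        nt_e <- off + 3L * aa_e
      } else { # coordinates on the reverse strand, mirrored to plus
        nt_e <- n - (off + 3L * (aa_s - 1L))
        nt_s <- n - (off + 3L * aa_e)
      }
      hits[[length(hits) + 1L]] <- data.frame(
        domain = domains[ri], lineage = lineages[ri], frame = f,
        start = nt_s, end = nt_e, score = sc, stringsAsFactors = FALSE
      )
    }
  }
  if (length(hits) == 0) {
    return(data.frame(domain = character(0), lineage = character(0),
                      frame = integer(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, hits)
  # best hit per domain type
  df <- df[order(df$domain, -df$score), , drop = FALSE]
  df <- df[!duplicated(df$domain), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Assign a lineage (and superfamily) to a subfamily
#'
#' A subfamily is classified if at least one domain was identified in at
#' least one member copy; the label is the majority best-hit lineage across
#' all members' hits. A tie between lineages yields "unclassified" with a
#' warning (reproducibility over coverage). Superfamily follows from the
#' fixed lineage table ([lineage_table()]).
#'
#' @param member_hits list of [detect_domains()] data.frames, one per
#'   member copy of the subfamily.
#' @return list(lineage, superfamily).
#' @export
assign_lineage <- function(member_hits) {
  all_hits <- do.call(rbind, member_hits)
  if (is.null(all_hits) || nrow(all_hits) == 0) {
    return(list(lineage = "unclassified", superfamily = "unclassified"))
  }
  tab <- sort(table(all_hits$lineage), decreasing = TRUE)
  if (length(tab) > 1 && tab[1] == tab[2]) {
    warning("lineage tie (", paste(names(tab)[tab == tab[1]],
                                   collapse = " vs "),
            "); subfamily left unclassified")
    return(list(lineage = "unclassified", superfamily = "unclassified"))
  }
  lin <- names(tab)[1]
  lt <- lineage_table()
  sf <- lt$superfamily[match(lin, lt$lineage)]
  list(lineage = lin,
       superfamily = if (is.na(sf)) "unclassified" else sf)
}
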