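## End-to-end classification of mined copies: subfamily clustering of LTRs,
## domain-based lineage assignment, per-lineage rt-domain family trees with
## the support/branch-length cut, and canonical naming.

#' Classify mined LTR-RT copies
#'
#' Runs the full hierarchical classification over [find_ltr_candidates()]
#' output: (i) one representative LTR per copy is clustered into
#' subfamilies (identity 0.6 / overlap 0.7 single linkage); (ii) protein
#' domains are detected in each copy and each subfamily is assigned the
#' majority best-hit lineage (superfamily follows from the lineage table);
#' (iii) within each lineage, rt-domain nucleotide sequences are aligned,
#' low-occupancy columns dropped, and a neighbor-joining K80 tree with
#' column-resampling bootstrap is cut into families (support > 70, branch
#' length >= 0.3); copies without an rt domain form family f0; (iv) each
#' copy receives its canonical name.
#'
#' @param genome named character vector (or `AnnotatedGenome`).
#' @param copies data.frame from [find_ltr_candidates()].
#' @param domain_db lineage-tagged peptide set (default the synthetic
#'   [domain_reference_db()]).
#' @param n_bootstrap bootstrap replicates for family trees.
#' @param seed integer seed (bootstrap resampling).
#' @param species_prefix prefix for canonical names.
#' @return data.frame: copy id, chrom, start, end, subfamily, lineage,
#'   superfamily, family, name; plus attributes `partition` and `trees`.
#' @export
classify_copies <- function(genome, copies,
                            domain_db = domain_reference_db(),
                            n_bootstrap = 100, seed = 1,
                            species_prefix = "Dc") {
  if (inherits(genome, "AnnotatedGenome")) genome <- genome$genome
  if (nrow(copies) == 0) {
    return(data.frame(id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      subfamily = character(0), lineage = character(0),
                      superfamily = character(0), family = character(0),
                      name = character(0), stringsAsFactors = FALSE))
  }
  ids <- copies$id
  ltrs <- stats::setNames(vapply(seq_len(nrow(copies)), function(i) {
    substr(genome[[copies$chrom[i]]], copies$ltr5_start[i] + 1L,
           copies$ltr5_end[i])
  }, character(1)), ids)
  seqs <- stats::setNames(vapply(seq_len(nrow(copies)), function(i) {
    substr(genome[[copies$chrom[i]]], copies$start[i] + 1L, copies$end[i])
  }, character(1)), ids)

  part <- cluster_subfamilies(ltrs)
  hits <- lapply(seqs, detect_domains, domain_db = domain_db)

  subfam <- part$membership[ids]
  lin <- stats::setNames(rep("unclassified", length(ids)), ids)
  sf <- lin
  for (sub in unique(subfam)) {
    members <- ids[subfam == sub]
    lab <- assign_lineage(hits[members])
    lin[members] <- lab$lineage
    sf[members] <- lab$superfamily
  }

  # rt-domain nucleotide sequence per copy (NA when absent)
  rt_seq <- stats::setNames(rep(NA_character_, length(ids)), ids)
  for (id in ids) {
    h <- hits[[id]]
    h <- h[h$domain == "RT", , drop = FALSE]
    if (nrow(h) == 1) {
      s <- substr(seqs[[id]], h$start + 1L, h$end)
      if (h$frame < 0) s <- revcomp(s)
      rt_seq[id] <- s
    }
  }

  fam <- stats::setNames(rep("f0", length(ids)), ids)
  trees <- list()
  for (lg in setdiff(unique(lin), "unclassified")) {
    members <- ids[lin == lg]
    with_rt <- members[!is.na(rt_seq[members])]
    no_rt <- setdiff(members, with_rt)
    if (length(with_rt) >= 2) {
      aln <- align_and_filter(rt_seq[with_rt])
      ft <- build_family_tree(aln, n_bootstrap = n_bootstrap,
                              seed = derive_seed(seed, "tree", lg))
      fam[c(with_rt, no_rt)] <-
        cut_families(ft, no_rt = no_rt)[c(with_rt, no_rt)]
      trees[[lg]] <- ft
    } else if (length(with_rt) == 1) {
      fam[with_rt] <- "f1"
    }
  }

  out <- data.frame(
    id = ids, chrom = copies$chrom, start = copies$start, end = copies$end,
    subfamily = unname(subfam), lineage = unname(lin),
    superfamily = unname(sf), family = unname(fam),
    stringsAsFactors = FALSE
  )
  out$name <- vapply(seq_len(nrow(out)), function(i) {
    canonical_name(out$superfamily[i], out$lineage[i], out$family[i],
                   out$subfamily[i], out$chrom[i], out$start[i], out$end[i],
                   species_prefix = species_prefix)
  }, character(1))
  attr(out, "partition") <- part
  attr(out, "trees") <- trees
  out
}
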