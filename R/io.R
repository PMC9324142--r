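## I/O boundaries. Internal coordinates are 0-based half-open; GFF3 is
## written 1-based inclusive, BED 0-based half-open. Standard formats go
## through Biostrings (FASTA/FASTQ) and rtracklayer (GFF3/BED).

#' Read a FASTA file into a named character vector
#' @param path FASTA file.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write reads to FASTQ (constant quality)
#' @param reads named character vector.
#' @param path output file.
#' @param qual single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, qual = "I") {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), function(n) {
    paste(rep(qual, n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' Read FASTQ into a named character vector
#' @param path FASTQ file.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Export an annotated genome to disk
#'
#' Writes `genome.fa`, `genes.gff3`, `elements.gff3` (planted intact copies
#' as `LTR_retrotransposon` with child `long_terminal_repeat` features,
#' solo LTRs as standalone `long_terminal_repeat`), and a JSON ground-truth
#' manifest.
#'
#' @param ag an `AnnotatedGenome` from [build_genome()].
#' @param dir output directory (created if missing).
#' @export
write_genome <- function(ag, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(ag$genome, file.path(dir, "genome.fa"))

  gr_genes <- GenomicRanges::GRanges(
    ag$genes$chrom,
    IRanges::IRanges(ag$genes$start + 1L, ag$genes$end),
    type = "gene", ID = ag$genes$gene_id
  )
  rtracklayer::export(gr_genes, file.path(dir, "genes.gff3"), format = "gff3")

  cp <- ag$truth$copies
  rows <- list()
  if (nrow(cp) > 0) {
    for (i in seq_len(nrow(cp))) {
      id <- sprintf("%s_%d", cp$name[i], cp$copy[i])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cp$chrom[i], start = cp$start[i] + 1L, end = cp$end[i],
        type = "LTR_retrotransposon", strand = cp$strand[i], ID = id,
        Parent = NA_character_, stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cp$chrom[i], start = cp$start[i] + 1L,
        end = cp$start[i] + cp$ltr_len[i], type = "long_terminal_repeat",
        strand = cp$strand[i], ID = paste0(id, "_ltr5"), Parent = id,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = cp$chrom[i], start = cp$end[i] - cp$ltr_len[i] + 1L,
        end = cp$end[i], type = "long_terminal_repeat",
        strand = cp$strand[i], ID = paste0(id, "_ltr3"), Parent = id,
        stringsAsFactors = FALSE
      )
    }
  }
  so <- ag$truth$solo
  if (nrow(so) > 0) {
    for (i in seq_len(nrow(so))) {
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = so$chrom[i], start = so$start[i] + 1L, end = so$end[i],
        type = "long_terminal_repeat", strand = so$strand[i],
        ID = sprintf("%s_solo_%d", so$name[i], so$copy[i]),
        Parent = NA_character_, stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) > 0) {
    tab <- do.call(rbind, rows)
    gr <- GenomicRanges::GRanges(
      tab$chrom, IRanges::IRanges(tab$start, tab$end), strand = tab$strand,
      type = tab$type, ID = tab$ID,
      Parent = ifelse(is.na(tab$Parent), "", tab$Parent)
    )
    rtracklayer::export(gr, file.path(dir, "elements.gff3"), format = "gff3")
  }

  jsonlite::write_json(
    list(copies = ag$truth$copies, solo = ag$truth$solo),
    file.path(dir, "truth.json"), digits = NA
  )
  invisible(dir)
}
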