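## Insertion dating from LTR divergence under the Kimura two-parameter
## (K80) model, plus the genomic-context and lineage-level statistics.
## At integration the two LTRs of a copy are identical; their divergence K
## accumulates at twice the substitution rate, so the insertion age is
## T = K / (2r).

## transition partner of each base code (A<->G, C<->T); 0-based codes
.TRANSITION <- c(2L, 3L, 0L, 1L)

## P, Q, K from two aligned character vectors (columns may contain "-");
## gap and ambiguous columns are excluded from the denominators
.k80_from_columns <- function(x, y) {
  ok <- x %in% DNA_BASES4 & y %in% DNA_BASES4
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0) return(c(P = NA_real_, Q = NA_real_, K = NA_real_))
  xi <- match(x, DNA_BASES4) - 1L
  yi <- match(y, DNA_BASES4) - 1L
  diff <- xi != yi
  ts <- diff & (yi == .TRANSITION[xi + 1L])
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  a1 <- 1 - 2 * P - Q
  a2 <- 1 - 2 * Q
  K <- if (a1 <= 0 || a2 <= 0) NA_real_ else
    -0.5 * log(a1) - 0.25 * log(a2)
  c(P = P, Q = Q, K = K)
}

#' K80 (Kimura two-parameter) distance between two LTRs
#'
#' The LTR pair is globally aligned (affine gaps); transition (P) and
#' transversion (Q) proportions are computed over ungapped columns and the
#' distance follows the closed form
#' `K = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`. Saturated pairs (either log
#' argument <= 0) are reported as missing rather than clamped, with a
#' warning, and are excluded from downstream means.
#'
#' @param ltr5,ltr3 the two LTR sequences (character scalars).
#' @return named numeric vector c(P, Q, K); K is NA when undefined.
#' @export
k80_distance <- function(ltr5, ltr3) {
  stopifnot(nchar(ltr5) > 0, nchar(ltr3) > 0)
  if (ltr5 == ltr3) return(c(P = 0, Q = 0, K = 0))
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(ltr5), Biostrings::DNAString(ltr3),
    type = "global", substitutionMatrix = sm,
    gapOpening = 10, gapExtension = 0.5
  )
  x <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  y <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out <- .k80_from_columns(x, y)
  if (all(!(x %in% DNA_BASES4 & y %in% DNA_BASES4))) {
    warning("no ungapped columns in the LTR alignment; distance missing")
  } else if (is.na(out["K"])) {
    warning("K80 distance saturated (log argument <= 0); reported missing")
  }
  out
}

#' Insertion age from LTR divergence
#'
#' `T = K / (2r)`, reported in Myr. The default substitution rate is
#' 1.3e-8 substitutions per site per year, the standard plant LTR clock.
#'
#' @param K K80 distance (substitutions/site); may be a vector.
#' @param r substitution rate per site per year.
#' @return age(s) in Myr.
#' @export
estimate_age <- function(K, r = 1.3e-8) {
  if (r <= 0) stop("substitution rate r must be positive")
  K / (2 * r) / 1e6
}

#' Histogram of insertion ages
#'
#' Half-open bins `[k*w, (k+1)*w)`.
#'
#' @param ages non-negative ages (Myr); NAs dropped.
#' @param bin_width bin width (Myr), default 0.1.
#' @return data.frame: bin (0-based index), lower, upper, count.
#' @export
age_histogram <- function(ages, bin_width = 0.1) {
  ages <- ages[!is.na(ages)]
  stopifnot(all(ages >= 0))
  if (length(ages) == 0) {
    return(data.frame(bin = integer(0), lower = numeric(0),
                      upper = numeric(0), count = integer(0)))
  }
  idx <- floor(ages / bin_width)
  tab <- table(idx)
  bin <- as.integer(names(tab))
  data.frame(bin = bin, lower = bin * bin_width,
             upper = (bin + 1) * bin_width,
             count = as.integer(tab), row.names = NULL)
}

#' Genomic context of element copies relative to genes
#'
#' Distance to the nearest gene is 0 for copies overlapping a gene,
#' otherwise the gap to the closest gene. Copies more than `flank` bp from
#' the closest gene are classed intergenic, others genic. Distances of
#' 1..10000 bp are additionally assigned to 1-kb bins
#' (`bin = ceiling(distance/1000)`).
#'
#' @param copies data.frame with chrom/start/end (0-based half-open).
#' @param genes data.frame with chrom/start/end (0-based half-open).
#' @param flank genic/intergenic cutoff (bp).
#' @return `copies` with added columns distance, class, bin (NA outside
#'   1-10 kb). Copies on chromosomes without genes get NA distance and
#'   class "intergenic".
#' @export
gene_context <- function(copies, genes, flank = 1000) {
  n <- nrow(copies)
  if (n == 0) {
    copies$distance <- numeric(0); copies$class <- character(0)
    copies$bin <- integer(0)
    return(copies)
  }
  dist <- rep(NA_real_, n)
  if (nrow(genes) > 0) {
    gr_c <- GenomicRanges::GRanges(
      copies$chrom, IRanges::IRanges(copies$start + 1L, copies$end))
    gr_g <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))
    # chromosomes absent from the gene set are legitimate (distance NA)
    hit <- suppressWarnings(GenomicRanges::distanceToNearest(gr_c, gr_g))
    dist[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  }
  copies$distance <- dist
  copies$class <- ifelse(is.na(dist) | dist > flank, "intergenic", "genic")
  copies$bin <- ifelse(!is.na(dist) & dist >= 1 & dist <= 10000,
                       ceiling(dist / 1000), NA_integer_)
  copies
}

#' Compare two genomic-context distributions
#'
#' Chi-squared goodness-of-fit of the binned counts of group A against
#' expectations formed from group B's bin proportions, and (when the
#' underlying distance samples are supplied) a two-sample
#' Kolmogorov-Smirnov test on the distances. Both tests are two-sided; raw
#' P values are reported without multiple-testing correction.
#'
#' @param counts_a,counts_b binned counts (e.g. 1-kb bins over 1-10 kb).
#' @param dist_a,dist_b optional raw distance samples for the KS test.
#' @return list(chi2, chi2_df, chi2_p, ks_stat, ks_p); KS entries NA when
#'   samples are not supplied.
#' @export
compare_context_distributions <- function(counts_a, counts_b,
                                          dist_a = NULL, dist_b = NULL) {
  stopifnot(length(counts_a) == length(counts_b))
  if (sum(counts_a) == 0 || sum(counts_b) == 0) {
    stop("zero total counts in one of the groups")
  }
  keep <- counts_b > 0
  gof <- stats::chisq.test(counts_a[keep], p = counts_b[keep] /
                             sum(counts_b[keep]))
  ks_stat <- NA_real_; ks_p <- NA_real_
  if (!is.null(dist_a) && !is.null(dist_b)) {
    ks <- suppressWarnings(stats::ks.test(dist_a, dist_b))
    ks_stat <- unname(ks$statistic); ks_p <- ks$p.value
  }
  list(chi2 = unname(gof$statistic), chi2_df = unname(gof$parameter),
       chi2_p = gof$p.value, ks_stat = ks_stat, ks_p = ks_p)
}

#' Pairwise Pearson correlations across lineage summary features
#'
#' For every pair of numeric columns reports Pearson r, R-squared and the
#' (two-sided) P value. Columns with zero variance yield NA with a warning.
#'
#' @param summary_table data.frame; one row per lineage, numeric feature
#'   columns (e.g. n_copies, n_solo, mean_age).
#' @return data.frame: feature_x, feature_y, r, r2, p.
#' @export
lineage_correlations <- function(summary_table) {
  num <- vapply(summary_table, is.numeric, logical(1))
  vars <- names(summary_table)[num]
  if (nrow(summary_table) < 3) stop("need at least 3 lineages")
  out <- list()
  for (i in seq_along(vars)[-length(vars)]) {
    for (j in (i + 1):length(vars)) {
      x <- summary_table[[vars[i]]]; y <- summary_table[[vars[j]]]
      ok <- !is.na(x) & !is.na(y)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        warning("zero variance in '", vars[i], "' or '", vars[j],
                "'; correlation missing")
        r <- NA_real_; p <- NA_real_
      } else {
        ct <- stats::cor.test(x[ok], y[ok])
        r <- unname(ct$estimate); p <- ct$p.value
      }
      out[[length(out) + 1L]] <- data.frame(
        feature_x = vars[i], feature_y = vars[j], r = r, r2 = r^2, p = p,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
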