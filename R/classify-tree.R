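## Family definition from the reverse-transcriptase (rt) domain phylogeny:
## multiple alignment, low-occupancy column filtering, neighbor-joining on
## K80 distances, column-resampling bootstrap, and a support/branch-length
## tree cut. Families are labeled f1..fn by size; copies without an rt
## domain form the artificial per-lineage family f0.

#' Align rt-domain sequences and drop low-occupancy columns
#'
#' Multiple alignment is delegated to the MAFFT command-line aligner (the
#' standard tool for this step; it must be on PATH). Alignment columns with
#' less than `min_occupancy` non-gap characters -- i.e. more than 10% gaps,
#' missing or ambiguous data by default -- are then discarded.
#'
#' @param seqs named character vector (>= 2 nucleotide sequences).
#' @param min_occupancy minimum non-gap fraction per retained column.
#' @return named character vector of equal-length aligned sequences, with
#'   attribute `dropped` giving the number of removed columns.
#' @export
align_and_filter <- function(seqs, min_occupancy = 0.9) {
  if (length(seqs) < 2) stop("need at least 2 sequences to align")
  stopifnot(!is.null(names(seqs)))
  if (length(unique(nchar(seqs))) == 1L &&
      length(unique(substr(seqs, 1, 10))) == 1L && all(nchar(seqs) > 0)) {
    # equal-length, shared prefix: already effectively aligned; still run
    # the occupancy filter for interface parity
    mat <- do.call(rbind, strsplit(seqs, ""))
  } else {
    mat <- .run_mafft(seqs)
  }
  occ <- colMeans(mat != "-" & mat != "n" & mat != "N")
  keep <- occ >= min_occupancy
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  out <- toupper(out)
  names(out) <- names(seqs)
  attr(out, "dropped") <- sum(!keep)
  out
}

.run_mafft <- function(seqs) {
  if (Sys.which("mafft") == "") {
    stop("the 'mafft' executable is required for multiple alignment ",
         "but was not found on PATH")
  }
  fa <- tempfile(fileext = ".fa")
  on.exit(unlink(fa))
  write_fasta(seqs, fa)
  out <- system2("mafft", c("--auto", "--quiet", shQuote(fa)),
                 stdout = TRUE, stderr = FALSE)
  con <- textConnection(paste(out, collapse = "\n"))
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  idx <- grep("^>", lines)
  nm <- sub("^>", "", lines[idx])
  starts <- idx + 1L
  ends <- c(idx[-1L] - 1L, length(lines))
  al <- vapply(seq_along(idx), function(i) {
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  al <- toupper(al)[match(names(seqs), nm)]
  do.call(rbind, strsplit(al, ""))
}

## pairwise K80 distance matrix over aligned sequences; gap columns are
## excluded per pair; NA where the K80 log arguments are non-positive
.k80_matrix <- function(aln_mat) {
  n <- nrow(aln_mat)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      k <- .k80_from_columns(aln_mat[i, ], aln_mat[j, ])
      d[i, j] <- d[j, i] <- k["K"]
    }
  }
  d
}

#' Build a neighbor-joining family tree with bootstrap support
#'
#' Pairwise K80 distances over the filtered alignment feed a
#' neighbor-joining tree; branch support is the percentage of
#' column-resampled bootstrap replicates containing each internal
#' bipartition. Pairs with undefined (saturated) K80 distance route their
#' copies to the artificial family f0 with a warning, and the tree is built
#' on the remaining sequences.
#'
#' @param alignment named character vector from [align_and_filter()].
#' @param n_bootstrap bootstrap replicates.
#' @param seed integer seed for column resampling.
#' @return a `family_tree`: list(tree = ape phylo with `node.label` =
#'   support, support (per internal node, percent), f0_members, labels).
#' @export
build_family_tree <- function(alignment, n_bootstrap = 1000, seed = 1) {
  labels <- names(alignment)
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- labels
  d <- .k80_matrix(mat)
  f0 <- character(0)
  # drop rows involved in saturated pairs until the matrix is complete
  while (anyNA(d) && nrow(d) > 2) {
    worst <- which.max(rowSums(is.na(d)))
    f0 <- c(f0, rownames(mat)[worst])
    warning("K80 distance undefined (saturation) for '",
            rownames(mat)[worst], "'; routed to family f0")
    mat <- mat[-worst, , drop = FALSE]
    d <- d[-worst, -worst, drop = FALSE]
  }
  if (anyNA(d)) stop("K80 saturation leaves fewer than 3 usable sequences")
  keep <- rownames(mat)
  if (length(keep) < 3) {
    return(structure(list(tree = NULL, support = numeric(0),
                          f0_members = f0, labels = keep),
                     class = "family_tree"))
  }
  dimnames(d) <- list(keep, keep)
  tree <- ape::nj(stats::as.dist(d))
  nboot_ok <- 0L
  counts <- numeric(tree$Nnode)
  with_seed(derive_seed(seed, "bootstrap"), {
    ncol_a <- ncol(mat)
    boots <- vector("list", n_bootstrap)
    for (b in seq_len(n_bootstrap)) {
      cols <- sample.int(ncol_a, ncol_a, replace = TRUE)
      db <- .k80_matrix(mat[, cols, drop = FALSE])
      if (anyNA(db)) next
      dimnames(db) <- list(keep, keep)
      boots[[b]] <- ape::nj(stats::as.dist(db))
    }
    boots <- boots[!vapply(boots, is.null, logical(1))]
    nboot_ok <- length(boots)
    if (nboot_ok > 0) {
      counts <- ape::prop.clades(tree, boots, rooted = FALSE)
      counts[is.na(counts)] <- 0
    }
  })
  support <- if (nboot_ok > 0) 100 * counts / nboot_ok else
    rep(0, tree$Nnode)
  tree$node.label <- formatC(support, format = "f", digits = 1)
  structure(list(tree = tree, support = support, f0_members = f0,
                 labels = keep), class = "family_tree")
}

#' Cut a family tree into families
#'
#' Internal branches with bootstrap support strictly above `min_support`
#' AND length of at least `min_branch` substitutions/site are cut; the
#' connected components of the remaining tree are the families. A tree
#' with no qualifying branch yields a single family. Families are numbered
#' f1..fn by descending size, ties broken by the lexicographically smallest
#' member id; copies lacking an rt domain (the tree's `f0_members`, plus
#' any ids passed via `no_rt`) are labeled f0.
#'
#' @param ft a `family_tree` from [build_family_tree()].
#' @param min_support support threshold (percent, exclusive).
#' @param min_branch branch-length threshold (substitutions/site,
#'   inclusive).
#' @param no_rt additional copy ids without an rt domain.
#' @return named character vector: copy id -> family label ("f0", "f1", ...).
#' @export
cut_families <- function(ft, min_support = 70, min_branch = 0.3,
                         no_rt = character(0)) {
  stopifnot(inherits(ft, "family_tree"))
  assign_f0 <- union(ft$f0_members, no_rt)
  if (is.null(ft$tree)) {
    fam <- stats::setNames(rep("f1", length(ft$labels)), ft$labels)
    return(c(fam, stats::setNames(rep("f0", length(assign_f0)), assign_f0)))
  }
  tree <- ft$tree
  ntip <- length(tree$tip.label)
  # internal edges: child node is internal; its support indexes node.label
  child <- tree$edge[, 2L]
  is_internal <- child > ntip
  sup <- rep(NA_real_, nrow(tree$edge))
  sup[is_internal] <- ft$support[child[is_internal] - ntip]
  qualifies <- is_internal & !is.na(sup) & sup > min_support &
    tree$edge.length >= min_branch
  g <- igraph::graph_from_edgelist(tree$edge[!qualifies, , drop = FALSE],
                                   directed = FALSE)
  nv <- ntip + tree$Nnode
  if (igraph::vcount(g) < nv) {
    g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  }
  comp <- igraph::components(g)$membership
  tipc <- comp[seq_len(ntip)]
  groups <- split(tree$tip.label, tipc)
  key <- vapply(groups, min, character(1))
  sz <- vapply(groups, length, integer(1))
  ord <- order(-sz, key)
  fam <- stats::setNames(rep(NA_character_, ntip), tree$tip.label)
  for (i in seq_along(ord)) {
    fam[groups[[ord[i]]]] <- sprintf("f%d", i)
  }
  c(fam, stats::setNames(rep("f0", length(assign_f0)), assign_f0))
}

#' Canonical element name
#'
#' `{Superfamily}_{SpeciesPrefix}{Lineage}_f{F}.s{SSSS}_{chrom}:{start}-{end}`,
#' e.g. `Copia_DcAle_f2.s0082_chr3:100-5000`. Unclassified copies carry the
#' placeholder superfamily/lineage "unclassified" and family f0.
#'
#' @param superfamily,lineage,family,subfamily classification labels;
#'   `subfamily` is the zero-padded sNNNN label.
#' @param chrom,start,end genomic location (0-based half-open).
#' @param species_prefix prefix identifying the species (default "Dc").
#' @return character name.
#' @export
canonical_name <- function(superfamily, lineage, family, subfamily,
                           chrom, start, end, species_prefix = "Dc") {
  if (is.na(superfamily) || superfamily == "unclassified" ||
      is.na(lineage) || lineage == "unclassified") {
    sprintf("unclassified_%s.%s_%s:%d-%d",
            ifelse(is.na(family), "f0", family), subfamily, chrom,
            as.integer(start), as.integer(end))
  } else {
    sprintf("%s_%s%s_%s.%s_%s:%d-%d", superfamily, species_prefix, lineage,
            family, subfamily, chrom, as.integer(start), as.integer(end))
  }
}

#' Parse a canonical element name back into its fields
#'
#' @param name a name produced by [canonical_name()].
#' @return list(superfamily, lineage, family, subfamily, chrom, start, end);
#'   superfamily/lineage are "unclassified" for placeholder names.
#' @export
parse_canonical_name <- function(name) {
  parts <- strsplit(name, "_")[[1]]
  if (length(parts) < 3) stop("cannot parse canonical name: ", name)
  if (parts[1] == "unclassified") {
    sf <- "unclassified"; lin <- "unclassified"
    fs <- parts[2]; loc <- paste(parts[-(1:2)], collapse = "_")
  } else {
    sf <- parts[1]
    lins <- lineage_table()$lineage
    hit <- lins[vapply(lins, function(l) endsWith(parts[2], l), logical(1))]
    lin <- if (length(hit) > 0) hit[which.max(nchar(hit))] else
      sub("^[A-Z][a-z]", "", parts[2])
    fs <- parts[3]; loc <- paste(parts[-(1:3)], collapse = "_")
  }
  if (!grepl("^f[0-9]+\\.s[0-9]+$", fs)) {
    stop("cannot parse canonical name: ", name)
  }
  mm <- regmatches(loc, regexec("^(.+):([0-9]+)-([0-9]+)$", loc))[[1]]
  if (length(mm) == 0) stop("cannot parse canonical name: ", name)
  list(superfamily = sf, lineage = lin,
       family = sub("\\..*$", "", fs), subfamily = sub("^[^.]*\\.", "", fs),
       chrom = mm[2], start = as.integer(mm[3]), end = as.integer(mm[4]))
}
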