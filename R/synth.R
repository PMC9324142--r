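## Synthetic genomes, elements, circles and paired-end reads with known
## ground truth. The generator emulates the data structure of a plant
## mobilome study: a multi-chromosome genome carrying intact LTR-RT copies
## (paired LTRs, TG...CA termini, 2-20 bp TSDs, internal GAG/PR/INT/RT/RH
## coding domains), solo LTRs, gene intervals; eccDNA circles with one-LTR
## or two-LTR topology and small junction indels; and paired-end read sets.

#' Known plant LTR-RT lineages and their superfamilies
#'
#' Fixed lineage-to-superfamily lookup used by the classifier and the
#' generator: nine Copia lineages (Ale ... Tork) and six Gypsy lineages
#' (Athila ... Tekay), the set commonly recognized in plant genomes.
#'
#' @return data.frame with columns `lineage`, `superfamily`.
#' @export
lineage_table <- function() {
  data.frame(
    lineage = c("Ale", "Alesia", "Angela", "Bianca", "Ikeros", "Ivana",
                "SIRE", "TAR", "Tork",
                "Athila", "CRM", "Galadriel", "Reina", "Retand", "Tekay"),
    superfamily = c(rep("Copia", 9), rep("Gypsy", 6)),
    stringsAsFactors = FALSE
  )
}

## Internal protein-domain order differs between the two superfamilies and
## is the structural basis of the Copia/Gypsy distinction.
.DOMAIN_ORDER <- list(
  Copia = c("GAG", "PR", "INT", "RT", "RH"),
  Gypsy = c("GAG", "PR", "RT", "RH", "INT")
)

#' Synthetic protein-domain reference set
#'
#' A synthetic stand-in for a curated plant LTR-RT protein-domain database:
#' one deterministic pseudo-random peptide per lineage x domain combination
#' (GAG, PR, INT, RT, RH for each of the 15 lineages). Headers follow the
#' `LINEAGE#DOMAIN#id` contract consumed by [detect_domains()]. The set is
#' generated in code from a fixed internal seed, so it is identical across
#' sessions, and is labelled synthetic: the peptides share the database's
#' *structure* (lineage-tagged domain models), not real domain sequence.
#'
#' @param peptide_len amino acids per domain model.
#' @return named character vector of peptides; names are the FASTA headers.
#' @export
domain_reference_db <- function(peptide_len = 80) {
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  lt <- lineage_table()
  doms <- c("GAG", "PR", "INT", "RT", "RH")
  with_seed(derive_seed(271828L, "domain-db", peptide_len), {
    out <- character(0)
    for (lin in lt$lineage) {
      for (d in doms) {
        pep <- paste(sample(aa, peptide_len, replace = TRUE), collapse = "")
        out[sprintf("%s#%s#%s_%s", lin, d, lin, tolower(d))] <- pep
      }
    }
    out
  })
}

#' Specify one synthetic LTR retrotransposon
#'
#' @param name element name (used in ground truth and read names).
#' @param ltr_len LTR length (bp).
#' @param internal_len internal region length (bp); must fit the coding
#'   domains (5 x peptide length x 3 bp by default).
#' @param tsd_len target-site duplication length, 2-20 bp.
#' @param motif terminal dinucleotides, default `c("TG", "CA")`.
#' @param target_k intended LTR divergence (K80 substitutions/site).
#' @param lineage lineage label (see [lineage_table()]); superfamily and
#'   internal domain order follow from it.
#' @param domains subset of GAG/PR/INT/RT/RH to encode; default all five in
#'   superfamily order. `character(0)` gives a non-coding internal region
#'   (a copy the classifier must leave "unclassified").
#' @param strand planting strand.
#' @param n_copies number of intact copies to plant.
#' @param n_solo number of solo LTRs of this element to plant.
#' @return an `element_spec` list.
#' @export
element_spec <- function(name, ltr_len = 400, internal_len = 3500,
                         tsd_len = 5, motif = c("TG", "CA"), target_k = 0,
                         lineage = "Ale", domains = NULL, strand = "+",
                         n_copies = 1, n_solo = 0) {
  lt <- lineage_table()
  sf <- lt$superfamily[match(lineage, lt$lineage)]
  if (is.na(sf)) sf <- "Copia" # unknown lineage label: Copia domain order
  if (is.null(domains)) domains <- .DOMAIN_ORDER[[sf]]
  stopifnot(tsd_len >= 2, tsd_len <= 20, target_k >= 0, ltr_len >= 4,
            all(domains %in% c("GAG", "PR", "INT", "RT", "RH")),
            strand %in% c("+", "-"))
  structure(list(
    name = name, ltr_len = as.integer(ltr_len),
    internal_len = as.integer(internal_len), tsd_len = as.integer(tsd_len),
    motif = motif, target_k = target_k, lineage = lineage,
    superfamily = sf,
    domains = domains[order(match(domains, .DOMAIN_ORDER[[sf]]))],
    strand = strand, n_copies = as.integer(n_copies),
    n_solo = as.integer(n_solo)
  ), class = "element_spec")
}

#' Configuration for the synthetic-data generator
#'
#' Defaults state the emulated world: an AT-rich plant genome (GC 0.38),
#' PE150 paired-end reads from 200-800 bp insert libraries (mean 400,
#' sd 60), Illumina-like per-base substitution error 1e-3, 30x coverage.
#'
#' @param seed integer seed; all generator randomness derives from it.
#' @param n_chrom,chrom_len chromosome count and length (bp).
#' @param gc genomic GC fraction.
#' @param elements list of [element_spec()] objects.
#' @param read_len,insert_mean,insert_sd,error_rate,coverage read-simulation
#'   parameters.
#' @param gene_len,gene_spacing gene model length and average spacing used
#'   to lay down non-overlapping gene intervals.
#' @return a `synth_config` list.
#' @export
synth_config <- function(seed, n_chrom = 2, chrom_len = 100000L, gc = 0.38,
                         elements = list(), read_len = 150L,
                         insert_mean = 400, insert_sd = 60,
                         error_rate = 0.001, coverage = 30,
                         gene_len = 2000L, gene_spacing = 10000L) {
  stopifnot(error_rate >= 0, error_rate < 0.1, coverage >= 0,
            n_chrom >= 1, chrom_len >= 1, gc > 0, gc < 1)
  structure(list(
    seed = as.integer(seed), n_chrom = as.integer(n_chrom),
    chrom_len = as.integer(chrom_len), gc = gc, elements = elements,
    read_len = as.integer(read_len), insert_mean = insert_mean,
    insert_sd = insert_sd, error_rate = error_rate, coverage = coverage,
    gene_len = as.integer(gene_len), gene_spacing = as.integer(gene_spacing)
  ), class = "synth_config")
}

#' Mutate one LTR of a pair to a target K80 divergence
#'
#' Draws per-site substitutions (no indels) so that the expected K80
#' distance between the original and mutated LTR equals `target_k`. The
#' transition:transversion mix is configurable (default 2:1). Because a
#' mutated site is hit at most once, the realized proportions P (transition)
#' and Q (transversion) relate to the per-site substitution probability d
#' through P = d*ts/(ts+1), Q = d/(ts+1); d is solved from the K80 closed
#' form K = -1/2 ln(1-2P-Q) - 1/4 ln(1-2Q). Terminal dinucleotides (the
#' TG...CA motif) are protected; displaced substitutions are relocated so
#' the expected K is unchanged.
#'
#' @param ltr LTR sequence (character scalar).
#' @param target_k intended divergence, substitutions/site.
#' @param seed integer seed.
#' @param ts_tv transition:transversion ratio among substitutions.
#' @return list with `ltr5` (input), `ltr3` (mutated), `d` (per-site
#'   substitution probability), `n_sub` realized substitution count.
#' @export
mutate_ltr_pair <- function(ltr, target_k, seed, ts_tv = 2) {
  stopifnot(target_k >= 0, ts_tv > 0)
  L <- nchar(ltr)
  if (target_k == 0) {
    return(list(ltr5 = ltr, ltr3 = ltr, d = 0, n_sub = 0L))
  }
  tf <- ts_tv / (ts_tv + 1) # fraction of substitutions that are transitions
  kfun <- function(d) {
    p <- d * tf; q <- d * (1 - tf)
    -0.5 * log(1 - 2 * p - q) - 0.25 * log(1 - 2 * q)
  }
  dmax <- 1 / (2 * tf + (1 - tf)) # saturation: 1 - 2P - Q -> 0
  if (!is.finite(kfun(dmax * 0.999999)) || target_k >= kfun(dmax * 0.999999)) {
    stop("target_k = ", target_k, " is beyond K80 saturation for ts_tv = ",
         ts_tv)
  }
  d <- stats::uniroot(function(x) kfun(x) - target_k,
                      c(1e-12, dmax * 0.999999), tol = 1e-12)$root
  with_seed(seed, {
    hit <- which(stats::runif(L) < d)
    # protect motif termini; relocate, keeping the substitution count
    protected <- c(1L, 2L, L - 1L, L)
    bad <- intersect(hit, protected)
    if (length(bad) > 0) {
      pool <- setdiff(setdiff(seq_len(L), protected), hit)
      hit <- c(setdiff(hit, protected),
               sample(pool, min(length(bad), length(pool))))
    }
    v <- dna_ints(ltr)
    transition <- c(2L, 3L, 0L, 1L) # A<->G, C<->T (0-based codes)
    for (i in hit) {
      b <- v[i]
      if (stats::runif(1) < tf) {
        v[i] <- transition[b + 1L]
      } else {
        # the two transversion partners of each base
        tv <- setdiff(0:3, c(b, transition[b + 1L]))
        v[i] <- sample(tv, 1)
      }
    }
    list(ltr5 = ltr, ltr3 = ints_dna(v), d = d, n_sub = length(hit))
  })
}

## Build one element sequence from its spec: 5' LTR + internal (with coding
## domains planted in superfamily order) + 3' LTR mutated to target_k.
.build_element <- function(spec, seed, domain_db) {
  with_seed(derive_seed(seed, "element", spec$name), {
    ltr <- random_dna(spec$ltr_len, 0.38)
    ltr <- paste0(spec$motif[1], substr(ltr, 3, spec$ltr_len - 2),
                  spec$motif[2])
    internal <- random_dna(spec$internal_len, 0.38)
    dom_tbl <- NULL
    if (length(spec$domains) > 0) {
      keys <- sprintf("%s#%s", spec$lineage, spec$domains)
      db_keys <- sub("#[^#]*$", "", names(domain_db))
      cds <- vapply(keys, function(k) {
        i <- match(k, db_keys)
        if (is.na(i)) stop("no domain model for ", k)
        reverse_translate(domain_db[[i]])
      }, character(1))
      need <- sum(nchar(cds))
      if (need > spec$internal_len) {
        stop("internal_len ", spec$internal_len,
             " too short for domains (need ", need, " bp)")
      }
      gap <- (spec$internal_len - need) %/% (length(cds) + 1L)
      pos <- integer(length(cds)); at <- gap
      for (i in seq_along(cds)) {
        substr(internal, at + 1L, at + nchar(cds[i])) <- cds[i]
        pos[i] <- at
        at <- at + nchar(cds[i]) + gap
      }
      dom_tbl <- data.frame(domain = spec$domains,
                            start = spec$ltr_len + pos,
                            end = spec$ltr_len + pos + nchar(cds),
                            stringsAsFactors = FALSE)
    }
    mut <- mutate_ltr_pair(ltr, spec$target_k,
                           derive_seed(seed, "ltrmut", spec$name))
    seq <- paste0(mut$ltr5, internal, mut$ltr3)
    list(spec = spec, seq = seq, ltr5 = mut$ltr5, ltr3 = mut$ltr3,
         internal = internal, domains = dom_tbl,
         length = nchar(seq))
  })
}

#' Build a synthetic annotated genome with ground truth
#'
#' Generates `n_chrom` i.i.d.-base chromosomes at the configured GC, lays
#' down non-overlapping gene intervals, then plants each element (and its
#' solo LTRs) with an exact target-site duplication: the `tsd_len` bases at
#' the insertion point are duplicated so the element is flanked by two
#' identical copies. All planted coordinates are recorded as ground truth.
#'
#' @param config a [synth_config()].
#' @return an `AnnotatedGenome` list: `genome` (named character vector),
#'   `genes` (data.frame chrom/start/end/gene_id; 0-based half-open),
#'   `elements` (built element models, named by element name), and `truth`
#'   with `copies`, `solo` data.frames (0-based half-open coordinates).
#' @export
build_genome <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  db <- domain_reference_db()
  built <- list()
  for (el in config$elements) {
    if (2L * el$ltr_len + el$internal_len + 2L * el$tsd_len >=
        config$chrom_len) {
      stop("element '", el$name, "' does not fit in a chromosome of ",
           config$chrom_len, " bp")
    }
    built[[el$name]] <- .build_element(el, config$seed, db)
  }

  # enumerate planting jobs: intact copies then solo LTRs
  jobs <- list()
  for (b in built) {
    sp <- b$spec
    if (sp$n_copies > 0) {
      for (i in seq_len(sp$n_copies)) {
        jobs[[length(jobs) + 1L]] <- list(kind = "copy", el = b, idx = i)
      }
    }
    if (sp$n_solo > 0) {
      for (i in seq_len(sp$n_solo)) {
        jobs[[length(jobs) + 1L]] <- list(kind = "solo", el = b, idx = i)
      }
    }
  }

  with_seed(derive_seed(config$seed, "genome"), {
    chroms <- stats::setNames(
      vapply(seq_len(config$n_chrom),
             function(i) random_dna(config$chrom_len, config$gc),
             character(1)),
      sprintf("chr%d", seq_len(config$n_chrom))
    )

    # assign jobs to chromosomes round-robin, pick well-separated insertion
    # points per chromosome, plant right-to-left so coordinates stay valid
    copies <- list(); solos <- list()
    if (length(jobs) > 0) {
      chrom_of <- rep(seq_len(config$n_chrom), length.out = length(jobs))
      for (ci in seq_len(config$n_chrom)) {
        jidx <- which(chrom_of == ci)
        if (length(jidx) == 0) next
        nj <- length(jidx)
        margin <- 2000L
        usable <- config$chrom_len - 2L * margin
        slot <- usable %/% nj
        lens <- vapply(jidx, function(j) {
          if (jobs[[j]]$kind == "copy") jobs[[j]]$el$length
          else jobs[[j]]$el$spec$ltr_len
        }, numeric(1))
        if (any(lens + 100 > slot)) {
          stop("too many planted features for chromosome length ",
               config$chrom_len)
        }
        pts <- margin + (seq_len(nj) - 1L) * slot +
          vapply(seq_len(nj), function(i) {
            sample.int(max(1L, slot - as.integer(lens[i]) - 100L), 1)
          }, integer(1))
        ord <- order(pts, decreasing = TRUE)
        placed <- list()
        for (i in ord) {
          job <- jobs[[jidx[i]]]
          sp <- job$el$spec
          t <- sp$tsd_len
          p <- pts[i]
          ins_seq <- if (job$kind == "copy") job$el$seq else job$el$ltr5
          if (sp$strand == "-") ins_seq <- revcomp(ins_seq)
          s <- chroms[[ci]]
          if (job$kind == "copy") {
            # boundary identifiability: adjust the target site so the
            # planted boundaries are structurally unambiguous -- the flank
            # must not extend the LTR repeat pair on its diagonal, nor
            # duplicate the element termini next to the TSD (see the
            # methods vignette)
            L <- nchar(ins_seq)
            Dd <- L - sp$ltr_len # distance between the two LTR starts
            el_first <- substr(ins_seq, 1L, 1L)
            el_last <- substr(ins_seq, L, L)
            int_first <- substr(ins_seq, sp$ltr_len + 1L, sp$ltr_len + 1L)
            int_last <- substr(ins_seq, Dd, Dd)
            s <- .avoid_base(s, p, el_last)           # before the left TSD
            s <- .avoid_base(s, p + t + 1L, el_first) # after the right TSD
            s <- .avoid_base(s, p + 1L, int_first)    # TSD first base
            s <- .avoid_base(s, p + t, int_last)      # TSD last base
            chroms[[ci]] <- s
          }
          tsd <- substr(s, p + 1L, p + t)
          chroms[[ci]] <- paste0(substr(s, 1L, p + t), ins_seq,
                                 substr(s, p + 1L, nchar(s)))
          placed[[length(placed) + 1L]] <- list(
            kind = job$kind, name = sp$name, idx = job$idx, p = p, tsd = tsd,
            len = nchar(ins_seq), strand = sp$strand, el = job$el
          )
        }
        # convert to final coordinates: features planted right-to-left, so
        # each later (more leftward) feature shifts all earlier ones
        placed <- rev(placed) # left to right
        shift <- 0L
        for (pl in placed) {
          sp <- built[[pl$name]]$spec
          start <- pl$p + sp$tsd_len + shift # 0-based start of feature
          end <- start + pl$len
          rec <- data.frame(
            name = pl$name, copy = pl$idx, chrom = names(chroms)[ci],
            start = start, end = end, strand = pl$strand,
            tsd = pl$tsd, tsd_len = sp$tsd_len, stringsAsFactors = FALSE
          )
          if (pl$kind == "copy") {
            rec$ltr_len <- sp$ltr_len
            rec$internal_len <- sp$internal_len
            rec$lineage <- sp$lineage
            rec$superfamily <- sp$superfamily
            rec$target_k <- sp$target_k
            copies[[length(copies) + 1L]] <- rec
          } else {
            solos[[length(solos) + 1L]] <- rec
          }
          shift <- shift + pl$len + sp$tsd_len
        }
      }
    }

    copies <- if (length(copies)) do.call(rbind, copies) else
      data.frame(name = character(0), copy = integer(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 tsd = character(0), tsd_len = integer(0),
                 ltr_len = integer(0), internal_len = integer(0),
                 lineage = character(0), superfamily = character(0),
                 target_k = numeric(0), stringsAsFactors = FALSE)
    solos <- if (length(solos)) do.call(rbind, solos) else
      data.frame(name = character(0), copy = integer(0), chrom = character(0),
                 start = integer(0), end = integer(0), strand = character(0),
                 tsd = character(0), tsd_len = integer(0),
                 stringsAsFactors = FALSE)

    # non-overlapping gene intervals avoiding planted features
    genes <- list()
    feat <- rbind(copies[, c("chrom", "start", "end")],
                  solos[, c("chrom", "start", "end")])
    for (ci in seq_along(chroms)) {
      cn <- names(chroms)[ci]
      clen <- nchar(chroms[[ci]])
      f <- feat[feat$chrom == cn, , drop = FALSE]
      at <- as.integer(stats::runif(1, 500, config$gene_spacing))
      gi <- 1L
      while (at + config$gene_len < clen - 500L) {
        gs <- at; ge <- at + config$gene_len
        clash <- nrow(f) > 0 && any(gs < f$end & ge > f$start)
        if (!clash) {
          genes[[length(genes) + 1L]] <- data.frame(
            chrom = cn, start = gs, end = ge,
            gene_id = sprintf("%s_g%03d", cn, gi), stringsAsFactors = FALSE
          )
          gi <- gi + 1L
        }
        at <- at + config$gene_spacing +
          as.integer(stats::runif(1, -2000, 2000))
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0),
                 gene_id = character(0), stringsAsFactors = FALSE)

    structure(list(
      genome = chroms, genes = genes, elements = built,
      truth = list(copies = copies, solo = solos),
      config = config
    ), class = "AnnotatedGenome")
  })
}

#' Generate eccDNA circles from an element model
#'
#' Two topologies are produced. A *two-LTR* circle is the full linear
#' extrachromosomal element circularized end-to-start by non-homologous end
#' joining, leaving an LTR-LTR junction; NHEJ's hallmark small indel is
#' applied at the junction. A *one-LTR* circle is the internal region plus
#' exactly one LTR (the product of recombination between the two LTRs),
#' circularized. Circles are returned as linear strings whose junction sits
#' between the last and first base.
#'
#' @param element a built element model (entry of `$elements` of
#'   [build_genome()] output).
#' @param topology `"two-LTR"` or `"one-LTR"`.
#' @param junction_indel signed indel length at the junction: negative =
#'   deletion of bases at the junction, positive = insertion of random
#'   bases; |indel| <= 20.
#' @param n number of circle molecules.
#' @param seed integer seed (inserted junction bases are random).
#' @return list of circle records: `seq`, `topology`, `indel`, `element`.
#' @export
make_circles <- function(element, topology = c("two-LTR", "one-LTR"),
                         junction_indel = 0, n = 1, seed = 1) {
  topology <- match.arg(topology)
  stopifnot(abs(junction_indel) <= 20)
  sp <- element$spec
  if (abs(junction_indel) > sp$ltr_len) {
    stop("junction indel longer than the LTR")
  }
  base <- if (topology == "two-LTR") {
    element$seq
  } else {
    paste0(element$internal, element$ltr5)
  }
  with_seed(derive_seed(seed, "circles", sp$name, topology, junction_indel), {
    lapply(seq_len(n), function(i) {
      s <- base
      if (junction_indel < 0) {
        s <- substr(s, 1L, nchar(s) + junction_indel)
      } else if (junction_indel > 0) {
        s <- paste0(s, random_dna(junction_indel, 0.5))
      }
      list(seq = s, topology = topology, indel = as.integer(junction_indel),
           element = sp$name, id = sprintf("%s_%s_c%d", sp$name,
                                           sub("-LTR", "ltr", topology), i))
    })
  })
}

#' Simulate paired-end reads from linear or circular templates
#'
#' Fragment starts are uniform over the template (wrapping for circular
#' templates, so junction-spanning read pairs occur); fragment lengths are
#' normal(insert_mean, insert_sd); fragments come off either strand with
#' equal probability and reads are FR-oriented (R1 = fragment 5' end, R2 =
#' reverse complement of the fragment 3' end). Per-base substitution errors
#' are applied at `error_rate`. The pair count per template is
#' `round(coverage * len / (2 * read_len))`.
#'
#' @param templates named character vector of template sequences.
#' @param coverage fold coverage.
#' @param config a [synth_config()] (read length, insert size, error rate).
#' @param circular logical, recycled over templates.
#' @param seed integer seed.
#' @return list with `r1`, `r2` (named character vectors) and `truth`
#'   (data.frame read_id/template/frag_start/frag_len/strand).
#' @export
simulate_reads <- function(templates, coverage, config, circular = FALSE,
                           seed = 1) {
  stopifnot(coverage >= 0, length(templates) > 0)
  circular <- rep_len(circular, length(templates))
  rl <- config$read_len
  r1 <- character(0); r2 <- character(0)
  truth <- list()
  with_seed(derive_seed(seed, "reads"), {
    for (ti in seq_along(templates)) {
      tmpl <- templates[[ti]]
      tn <- names(templates)[ti]
      len <- nchar(tmpl)
      if (!circular[ti] && rl > len) {
        stop("read length ", rl, " exceeds linear template '", tn, "' (",
             len, " bp)")
      }
      n_pairs <- round(coverage * len / (2 * rl))
      if (n_pairs == 0) next
      frag <- pmax(rl, pmin(
        if (circular[ti]) len else len,
        as.integer(round(stats::rnorm(n_pairs, config$insert_mean,
                                      config$insert_sd)))
      ))
      if (circular[ti]) {
        starts <- sample.int(len, n_pairs, replace = TRUE) - 1L
        doubled <- paste0(tmpl, tmpl)
        frags <- substring(doubled, starts + 1L, starts + frag)
      } else {
        starts <- vapply(frag, function(f) {
          sample.int(len - f + 1L, 1) - 1L
        }, integer(1))
        frags <- substring(tmpl, starts + 1L, starts + frag)
      }
      minus <- stats::runif(n_pairs) < 0.5
      if (any(minus)) frags[minus] <- revcomp(frags[minus])
      a <- substr(frags, 1L, rl)
      b <- revcomp(substring(frags, nchar(frags) - rl + 1L))
      if (config$error_rate > 0) {
        a <- .apply_errors(a, config$error_rate)
        b <- .apply_errors(b, config$error_rate)
      }
      ids <- sprintf("%s_p%06d", tn, seq_len(n_pairs))
      names(a) <- ids; names(b) <- ids
      r1 <- c(r1, a); r2 <- c(r2, b)
      truth[[length(truth) + 1L]] <- data.frame(
        read_id = ids, template = tn, frag_start = starts,
        frag_len = frag, strand = ifelse(minus, "-", "+"),
        stringsAsFactors = FALSE
      )
    }
  })
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(read_id = character(0), template = character(0),
               frag_start = integer(0), frag_len = integer(0),
               strand = character(0), stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, truth = truth)
}

#' Plant de novo element insertions into a genome copy
#'
#' Builds a "subline" genome: at each requested reference position the
#' element is inserted with an exact target-site duplication, emulating new
#' integration events. Positions are interpreted on the *reference*
#' coordinate system (the unmodified input genome), which is also the
#' coordinate system on which the insertion caller reports sites.
#'
#' @param genome named character vector (or `AnnotatedGenome`).
#' @param element built element model (entry of `AnnotatedGenome$elements`).
#' @param sites data.frame with columns chrom, pos (0-based insertion
#'   point on the reference) and optionally tsd_len (default 5).
#' @return list(genome = modified named character vector, truth = sites
#'   with tsd sequence and element name attached).
#' @export
plant_insertions <- function(genome, element, sites) {
  if (inherits(genome, "AnnotatedGenome")) genome <- genome$genome
  stopifnot(all(c("chrom", "pos") %in% names(sites)))
  if (is.null(sites$tsd_len)) sites$tsd_len <- 5L
  sites$element <- element$spec$name
  sites$tsd <- NA_character_
  ord <- order(sites$chrom, -sites$pos) # right-to-left per chromosome
  for (i in ord) {
    cn <- sites$chrom[i]; p <- sites$pos[i]; t <- sites$tsd_len[i]
    s <- genome[[cn]]
    if (p + t > nchar(s)) stop("insertion point beyond chromosome end")
    sites$tsd[i] <- substr(s, p + 1L, p + t)
    genome[[cn]] <- paste0(substr(s, 1L, p + t), element$seq,
                           substr(s, p + 1L, nchar(s)))
  }
  list(genome = genome, truth = sites)
}

## deterministically replace the base at 1-based index `idx` when it equals
## `avoid` (cyclic successor in A<C<G<T order)
.avoid_base <- function(s, idx, avoid) {
  if (idx < 1L || idx > nchar(s)) return(s)
  if (substr(s, idx, idx) == avoid) {
    cur <- match(avoid, DNA_BASES4)
    substr(s, idx, idx) <- DNA_BASES4[(cur %% 4L) + 1L]
  }
  s
}

## vectorized per-base substitution errors
.apply_errors <- function(reads, rate) {
  tot <- sum(nchar(reads))
  n_err <- stats::rbinom(1, tot, rate)
  if (n_err == 0) return(reads)
  offs <- c(0, cumsum(nchar(reads)))
  pos <- sort(sample.int(tot, n_err))
  ri <- findInterval(pos, offs + 1)
  within <- pos - offs[ri]
  shift <- sample(1:3, n_err, replace = TRUE)
  for (i in seq_len(n_err)) {
    r <- reads[[ri[i]]]
    b <- .DNA_LOOKUP[utf8ToInt(substr(r, within[i], within[i]))]
    if (is.na(b)) next
    nb <- (b + shift[i]) %% 4L
    substr(reads[[ri[i]]], within[i], within[i]) <- DNA_BASES4[nb + 1L]
  }
  reads
}
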