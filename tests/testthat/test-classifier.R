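test_that("domain detection finds planted domains at exact coordinates", {
  db <- domain_reference_db()
  el <- quick_element(lineage = "Ale")
  h <- detect_domains(el$seq, db)
  expect_setequal(h$domain, c("GAG", "PR", "INT", "RT", "RH"))
  expect_true(all(h$lineage == "Ale"))
  m <- merge(h[, c("domain", "start", "end")], el$domains, by = "domain")
  expect_equal(m$start.x, m$start.y)
  expect_equal(m$end.x, m$end.y)
  # minus strand: hits recovered through the reverse frames, mirrored
  h_rc <- detect_domains(mobilomeR:::revcomp(el$seq), db)
  expect_setequal(h_rc$domain, h$domain)
  expect_true(all(h_rc$frame < 0))
  n <- nchar(el$seq)
  m2 <- merge(h[, c("domain", "start", "end")],
              h_rc[, c("domain", "start", "end")], by = "domain")
  expect_equal(m2$start.y, n - m2$end.x)
  # internal region deleted: no hits at all
  trunc <- paste0(el$ltr5, el$ltr3)
  expect_equal(nrow(detect_domains(trunc, db)), 0)
  # malformed header is rejected by name
  bad <- c(db, `brokenheader` = "MKLV")
  expect_error(detect_domains(el$seq, bad), "brokenheader")
})

test_that("lineage assignment follows the majority rule with ties unclassified", {
  h1 <- data.frame(domain = "RT", lineage = "Ale", frame = 1L,
                   start = 0L, end = 9L, score = 100)
  h2 <- data.frame(domain = "INT", lineage = "Ale", frame = 1L,
                   start = 0L, end = 9L, score = 90)
  h3 <- data.frame(domain = "RT", lineage = "Tekay", frame = 1L,
                   start = 0L, end = 9L, score = 80)
  expect_equal(assign_lineage(list(h1, h2))$lineage, "Ale")
  expect_equal(assign_lineage(list(h1, h2))$superfamily, "Copia")
  expect_equal(assign_lineage(list(rbind(h3, h3, h3)))$superfamily, "Gypsy")
  expect_equal(assign_lineage(list())$lineage, "unclassified")
  expect_warning(tie <- assign_lineage(list(h1, h3)), "tie")
  expect_equal(tie$lineage, "unclassified")
})

test_that("subfamily clustering equals brute-force components of the pair graph", {
  # randomized families: clusters of diverged copies of shared ancestors
  for (seed in c(1, 2, 3, 4, 5)) {
    seqs <- mobilomeR:::with_seed(seed, {
      n_fam <- sample(2:4, 1)
      out <- character(0)
      for (f in seq_len(n_fam)) {
        anc <- mobilomeR:::random_dna(sample(150:250, 1), 0.5)
        for (m in seq_len(sample(1:4, 1))) {
          out[sprintf("f%d_m%d", f, m)] <-
            mutate_ltr_pair(anc, stats::runif(1, 0, 0.15),
                            sample.int(1e6, 1))$ltr3
        }
      }
      out
    })
    part <- cluster_subfamilies(seqs)
    # brute-force oracle: adjacency matrix + BFS, independent of igraph
    n <- length(seqs)
    adj <- matrix(FALSE, n, n)
    xs <- Biostrings::DNAStringSet(seqs)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        m <- mobilomeR:::.pair_metrics(xs[[i]], xs[[j]])
        adj[i, j] <- adj[j, i] <- m[["ident"]] >= 0.6 && m[["cover"]] >= 0.7
      }
    }
    comp <- rep(0L, n); cur <- 0L
    for (s0 in seq_len(n)) {
      if (comp[s0] > 0) next
      cur <- cur + 1L
      queue <- s0
      while (length(queue) > 0) {
        v <- queue[1]; queue <- queue[-1]
        if (comp[v] > 0) next
        comp[v] <- cur
        queue <- c(queue, which(adj[v, ] & comp == 0L))
      }
    }
    # identical partitions (up to label names)
    expect_equal(
      unname(split(names(seqs), part$membership[names(seqs)])[
        order(vapply(split(names(seqs), part$membership[names(seqs)]),
                     min, character(1)))]),
      unname(split(names(seqs), comp)[
        order(vapply(split(names(seqs), comp), min, character(1)))])
    )
    # partition property: every copy appears exactly once
    expect_setequal(names(part$membership), names(seqs))
  }
})

test_that("clustering respects the identity and overlap thresholds", {
  a <- rand_dna(300, seed = 30)
  # ~90% identity over only half of the longer sequence: no edge
  half <- paste0(substr(a, 1, 150), rand_dna(150, seed = 31))
  part <- cluster_subfamilies(c(x = a, y = half))
  # x and y share 150/300 = 50% of the longer seq, below overlap 0.7
  expect_equal(length(unique(part$membership)), 2)
  # identical sequences cluster together with deterministic labels
  p2 <- cluster_subfamilies(c(b = a, a = a, c = a))
  expect_true(all(p2$membership == "s0001"))
  # label assignment is invariant to input order
  p3 <- cluster_subfamilies(c(c = a, a = a, b = a))
  expect_identical(p2$membership[sort(names(p2$membership))],
                   p3$membership[sort(names(p3$membership))])
})

test_that("alignment filter drops low-occupancy columns", {
  base <- rand_dna(120, seed = 40)
  seqs <- stats::setNames(rep(base, 20), sprintf("s%02d", 1:20))
  # identical sequences: nothing dropped, no gaps
  aln0 <- align_and_filter(seqs)
  expect_equal(unname(nchar(aln0[1])), 120)
  expect_equal(attr(aln0, "dropped"), 0)
  # one sequence with a unique 50-bp insertion: those columns are 1/20
  # occupied and fall below the 90% floor
  seqs2 <- seqs
  seqs2["s01"] <- paste0(substr(base, 1, 60), rand_dna(50, seed = 41),
                         substr(base, 61, 120))
  aln2 <- align_and_filter(seqs2)
  expect_true(all(nchar(aln2) == nchar(aln2[1])))
  expect_lte(nchar(aln2[1]), 120) # insertion columns removed
  expect_gte(attr(aln2, "dropped"), 45)
  expect_error(align_and_filter(seqs[1]), "at least 2")
})

test_that("family trees resolve two clades and respect the cut thresholds", {
  seqs <- mobilomeR:::with_seed(50, {
    ancA <- mobilomeR:::random_dna(300, 0.5)
    ancB <- mutate_ltr_pair(ancA, 0.5, 99)$ltr3
    c(
      stats::setNames(vapply(1:5, function(i)
        mutate_ltr_pair(ancA, 0.04, i)$ltr3, character(1)),
        paste0("A", 1:5)),
      stats::setNames(vapply(1:5, function(i)
        mutate_ltr_pair(ancB, 0.04, 100 + i)$ltr3, character(1)),
        paste0("B", 1:5))
    )
  })
  aln <- align_and_filter(seqs)
  ft <- build_family_tree(aln, n_bootstrap = 100, seed = 3)
  fam <- cut_families(ft)
  expect_setequal(unique(fam), c("f1", "f2"))
  expect_equal(length(unique(fam[paste0("A", 1:5)])), 1)
  expect_equal(length(unique(fam[paste0("B", 1:5)])), 1)
  # same seed, identical supports (bootstrap determinism)
  ft2 <- build_family_tree(aln, n_bootstrap = 100, seed = 3)
  expect_identical(ft$support, ft2$support)
  # near-identical sequences: no branch passes the cut, single family
  near <- mobilomeR:::with_seed(60, {
    anc <- mobilomeR:::random_dna(300, 0.5)
    stats::setNames(vapply(1:6, function(i)
      mutate_ltr_pair(anc, 0.01, i)$ltr3, character(1)), paste0("s", 1:6))
  })
  ftn <- build_family_tree(align_and_filter(near), n_bootstrap = 50,
                           seed = 1)
  famn <- cut_families(ftn)
  expect_equal(unname(unique(famn)), "f1")
  # copies without an rt domain land in f0
  famr <- cut_families(ftn, no_rt = c("trunc1", "trunc2"))
  expect_equal(unname(famr["trunc1"]), "f0")
})

test_that("canonical names follow the naming rule and round-trip", {
  nm <- canonical_name("Copia", "Ale", "f2", "s0082", "chr3", 100, 5000)
  expect_identical(nm, "Copia_DcAle_f2.s0082_chr3:100-5000")
  p <- parse_canonical_name(nm)
  expect_identical(p$superfamily, "Copia")
  expect_identical(p$lineage, "Ale")
  expect_identical(p$family, "f2")
  expect_identical(p$subfamily, "s0082")
  expect_identical(p$chrom, "chr3")
  expect_equal(c(p$start, p$end), c(100L, 5000L))
  un <- canonical_name("unclassified", "unclassified", "f0", "s0191",
                       "chr1", 5, 10)
  expect_identical(un, "unclassified_f0.s0191_chr1:5-10")
  pu <- parse_canonical_name(un)
  expect_identical(pu$superfamily, "unclassified")
  # Gypsy name with a different species prefix
  nm2 <- canonical_name("Gypsy", "Tekay", "f1", "s0001", "chr1", 0, 100,
                        species_prefix = "At")
  expect_identical(parse_canonical_name(nm2)$lineage, "Tekay")
})

test_that("classify_copies ties the stages together on mined copies", {
  els <- list(
    element_spec("cop", ltr_len = 300, internal_len = 3000, tsd_len = 5,
                 lineage = "Ale", n_copies = 2),
    element_spec("gyp", ltr_len = 300, internal_len = 3000, tsd_len = 6,
                 lineage = "Retand"),
    element_spec("bare", ltr_len = 300, internal_len = 3000, tsd_len = 5,
                 lineage = "Ale", domains = character(0))
  )
  ag <- build_genome(synth_config(seed = 70, n_chrom = 2,
                                  chrom_len = 200000, elements = els))
  cand <- find_ltr_candidates(ag)
  expect_equal(nrow(cand), 4)
  cls <- classify_copies(ag, cand, n_bootstrap = 20, seed = 2)
  truth <- ag$truth$copies
  for (i in seq_len(nrow(cls))) {
    tr <- truth[truth$chrom == cls$chrom[i] & truth$start == cls$start[i], ]
    if (tr$name == "bare") {
      expect_equal(cls$lineage[i], "unclassified")
      expect_equal(cls$family[i], "f0")
      expect_match(cls$name[i], "^unclassified_f0")
    } else {
      expect_equal(cls$lineage[i], tr$lineage)
      expect_equal(cls$superfamily[i], tr$superfamily)
      expect_match(cls$name[i], paste0("^", tr$superfamily, "_Dc"))
    }
  }
  # the two copies of the same element share a subfamily
  cop_rows <- cls$subfamily[cls$lineage == "Ale"]
  expect_equal(length(unique(cop_rows)), 1)
})
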