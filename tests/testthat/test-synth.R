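test_that("build_genome plants elements with exact TSD semantics and is deterministic", {
  els <- list(
    element_spec("a", ltr_len = 200, internal_len = 1500, tsd_len = 5),
    element_spec("b", ltr_len = 150, internal_len = 1200, tsd_len = 8,
                 lineage = "Athila", strand = "-")
  )
  cfg <- synth_config(seed = 11, n_chrom = 2, chrom_len = 60000,
                      elements = els)
  ag <- build_genome(cfg)
  expect_s3_class(ag, "AnnotatedGenome")
  expect_equal(nrow(ag$truth$copies), 2)
  for (i in seq_len(nrow(ag$truth$copies))) {
    cp <- ag$truth$copies[i, ]
    s <- ag$genome[[cp$chrom]]
    left <- substr(s, cp$start - cp$tsd_len + 1, cp$start)
    right <- substr(s, cp$end + 1, cp$end + cp$tsd_len)
    expect_identical(left, cp$tsd)
    expect_identical(right, cp$tsd)
    expect_lte(cp$end, nchar(s))
    expect_equal(cp$end - cp$start, 2 * cp$ltr_len + cp$internal_len)
  }
  # gene intervals non-overlapping within a chromosome
  for (cn in unique(ag$genes$chrom)) {
    g <- ag$genes[ag$genes$chrom == cn, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
  # determinism: same config, byte-identical genome and truth
  ag2 <- build_genome(cfg)
  expect_identical(ag$genome, ag2$genome)
  expect_identical(ag$truth, ag2$truth)
  # empty element list
  ag0 <- build_genome(synth_config(seed = 3, n_chrom = 1,
                                   chrom_len = 10000))
  expect_equal(nrow(ag0$truth$copies), 0)
  # element longer than chromosome is rejected
  expect_error(
    build_genome(synth_config(seed = 1, n_chrom = 1, chrom_len = 2000,
                              elements = list(element_spec("big")))),
    "does not fit"
  )
})

test_that("mutate_ltr_pair hits the target K80 divergence in expectation", {
  ltr <- rand_dna(400, seed = 7)
  # zero divergence leaves the pair identical
  m0 <- mutate_ltr_pair(ltr, 0, seed = 1)
  expect_identical(m0$ltr5, m0$ltr3)
  # different seeds, different substitution patterns, same expected K
  m1 <- mutate_ltr_pair(ltr, 0.05, seed = 1)
  m2 <- mutate_ltr_pair(ltr, 0.05, seed = 2)
  expect_false(identical(m1$ltr3, m2$ltr3))
  # saturation is rejected
  expect_error(mutate_ltr_pair(ltr, 10, seed = 1), "saturation")
  # empirical K over replicates matches target within 3 SD
  target <- 0.06
  ks <- vapply(1:120, function(s) {
    m <- mutate_ltr_pair(ltr, target, seed = s)
    unname(k80_distance(m$ltr5, m$ltr3)["K"])
  }, numeric(1))
  se <- stats::sd(ks) / sqrt(length(ks))
  expect_lt(abs(mean(ks) - target), 3 * se + 1e-9)
})

test_that("make_circles produces the stated topologies and lengths", {
  el <- quick_element()
  elen <- nchar(el$seq)
  two <- make_circles(el, "two-LTR", junction_indel = -3, n = 2)
  expect_length(two, 2)
  expect_equal(nchar(two[[1]]$seq), elen - 3)
  expect_equal(two[[1]]$topology, "two-LTR")
  one <- make_circles(el, "one-LTR", junction_indel = 0)
  expect_equal(nchar(one[[1]]$seq),
               el$spec$internal_len + el$spec$ltr_len)
  ins <- make_circles(el, "two-LTR", junction_indel = 2)
  expect_equal(nchar(ins[[1]]$seq), elen + 2)
  expect_error(make_circles(el, "two-LTR", junction_indel = 25))
})

test_that("simulate_reads respects coverage, errors and the wrap contract", {
  el <- quick_element()
  cfg <- synth_config(seed = 2, error_rate = 0)
  # zero coverage, zero reads
  rd0 <- simulate_reads(c(t = el$seq), 0, cfg)
  expect_length(rd0$r1, 0)
  # error-free reads are exact substrings (mod wrap) of the template
  circ <- paste0(el$seq, el$seq) # doubled for wrap checking
  rd <- simulate_reads(c(t = el$seq), 10, cfg, circular = TRUE, seed = 4)
  hits <- vapply(rd$r1, function(r) {
    grepl(r, circ, fixed = TRUE) ||
      grepl(mobilomeR:::revcomp(r), circ, fixed = TRUE)
  }, logical(1))
  expect_true(all(hits))
  # read count follows coverage * len / (2 * read_len)
  expect_equal(length(rd$r1), round(10 * nchar(el$seq) / (2 * 150)))
  # read length exceeding a linear template is rejected
  expect_error(simulate_reads(c(s = rand_dna(100)), 5, cfg), "exceeds")
  # empirical mismatch rate matches error_rate within 3 binomial SD
  cfg_e <- synth_config(seed = 2, error_rate = 0.01)
  lin <- rand_dna(5000, seed = 9)
  rde <- simulate_reads(c(t = lin), 30, cfg_e, seed = 6)
  tr <- rde$truth
  nm <- 0L; tot <- 0L
  for (i in seq_len(nrow(tr))) {
    frag <- substr(lin, tr$frag_start[i] + 1,
                   tr$frag_start[i] + tr$frag_len[i])
    if (tr$strand[i] == "-") frag <- mobilomeR:::revcomp(frag)
    r1t <- substr(frag, 1, 150)
    nm <- nm + length(mobilomeR:::mismatch_positions(rde$r1[[i]], r1t))
    tot <- tot + 150L
  }
  p_hat <- nm / tot
  sd3 <- 3 * sqrt(0.01 * 0.99 / tot)
  expect_lt(abs(p_hat - 0.01), sd3)
})

test_that("plant_insertions records the duplicated target site", {
  el <- quick_element()
  g <- stats::setNames(rand_dna(30000, seed = 12), "chr1")
  pl <- plant_insertions(g, el, data.frame(chrom = "chr1", pos = 10000,
                                           tsd_len = 6))
  s <- pl$genome[["chr1"]]
  expect_equal(nchar(s), 30000 + nchar(el$seq) + 6)
  expect_identical(substr(s, 10001, 10006), pl$truth$tsd[1])
  expect_identical(substr(s, 10007, 10006 + nchar(el$seq)), el$seq)
  expect_identical(substr(s, 10007 + nchar(el$seq),
                          10012 + nchar(el$seq)),
                   pl$truth$tsd[1])
})
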