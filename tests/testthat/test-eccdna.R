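test_that("organelle read pairs are removed, nuclear pairs retained", {
  org <- c(chloro = rand_dna(20000, 0.36, seed = 1))
  nuc <- c(chr = rand_dna(20000, 0.38, seed = 2))
  cfg <- synth_config(seed = 3, error_rate = 0.001)
  rd_o <- simulate_reads(org, 4, cfg, seed = 4)
  rd_n <- simulate_reads(nuc, 4, cfg, seed = 5)
  # organelle-only pool: everything removed
  f1 <- filter_organelle_reads(rd_o$r1, rd_o$r2, org)
  expect_length(f1$r1, 0)
  # empty organelle set: identity
  f2 <- filter_organelle_reads(rd_o$r1, rd_o$r2, NULL)
  expect_identical(f2$r1, rd_o$r1)
  # mixed pool: retained fraction matches the nuclear share
  r1 <- c(rd_o$r1, rd_n$r1); r2 <- c(rd_o$r2, rd_n$r2)
  f3 <- filter_organelle_reads(r1, r2, org)
  expect_setequal(names(f3$r1), names(rd_n$r1))
})

test_that("RPKM follows its definition and scaling law", {
  one <- data.frame(
    read_id = sprintf("r%d", 1:10), ref = "s1", pos = 0, strand = "+",
    span = 150, nm = 0, clip_left = 0, clip_right = 0,
    clip_seq_left = "", clip_seq_right = "", score = 150, n_best = 1,
    stringsAsFactors = FALSE
  )
  pr <- profile_subfamilies(one, c(s1 = 1000, s2 = 2000), 1e6)
  # 10 reads, 1-kb reference, 1e6 total: 10 * 1e9 / (1000 * 1e6)
  expect_equal(pr$rpkm[pr$subfamily == "s1"], 10)
  expect_equal(pr$n_reads[pr$subfamily == "s2"], 0)
  expect_equal(pr$rpkm[pr$subfamily == "s2"], 0)
  # doubling the total mapped halves every RPKM
  pr2 <- profile_subfamilies(one, c(s1 = 1000, s2 = 2000), 2e6)
  expect_equal(pr2$rpkm, pr$rpkm / 2)
  expect_error(profile_subfamilies(one, c(s1 = 1000), 0), "positive")
})

test_that("enrichment chi-squared matches hand arithmetic and enumeration", {
  # equal proportions: zero statistic, p = 1
  eq <- test_enrichment(100, 1000, 200, 2000)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  # hand-computed 2x2 without continuity correction
  r <- test_enrichment(100, 1000, 50, 1000)
  m <- matrix(c(100, 900, 50, 950), 2, byrow = TRUE)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  expect_equal(r$chi2, sum((m - e)^2 / e))
  expect_equal(r$chi2, 18.018018, tolerance = 1e-6)
  expect_false(r$simulated)
  # small expected counts: Monte-Carlo p against exact enumeration over
  # all tables with the observed margins (hypergeometric weights)
  obs <- test_enrichment(3, 10, 0, 12, mc_reps = 20000, seed = 4)
  expect_true(obs$simulated)
  m0 <- matrix(c(3, 7, 0, 12), 2, byrow = TRUE)
  stat <- function(a) {
    mm <- matrix(c(a, 10 - a, 3 - a, 9 + a), 2, byrow = TRUE)
    ee <- outer(rowSums(mm), colSums(mm)) / sum(mm)
    sum((mm - ee)^2 / ee)
  }
  s_obs <- stat(3)
  p_exact <- sum(vapply(0:3, function(a) {
    if (stat(a) >= s_obs - 1e-9) stats::dhyper(a, 10, 12, 3) else 0
  }, numeric(1)))
  expect_lt(abs(obs$p - p_exact), 0.02)
  # degenerate margins are missing
  expect_true(is.na(test_enrichment(0, 10, 0, 10)$chi2))
})

test_that("candidate retention applies both cluster criteria", {
  pr <- data.frame(
    subfamily = c("keep", "small", "weak", "edge"),
    n_reads = c(501, 400, 5000, 500),
    ref_len = 1000, rpkm = 1,
    hit_fraction = c(0.9, 0.9, 0.4, 0.9),
    stringsAsFactors = FALSE
  )
  kept <- filter_candidates(pr)
  expect_identical(kept$subfamily, "keep") # 500 is not > 500; 0.4 fails
  expect_equal(nrow(filter_candidates(pr[0, ])), 0)
})

test_that("junction detection separates topologies and reads off the indel", {
  el <- quick_element(ltr_len = 100, internal_len = 1400)
  cfg <- synth_config(seed = 5, error_rate = 0.002)
  for (topo in c("two-LTR", "one-LTR")) {
    circ <- make_circles(el, topo, junction_indel = -3, n = 1, seed = 7)[[1]]
    rd <- simulate_reads(stats::setNames(circ$seq, circ$id), 50, cfg,
                         circular = TRUE, seed = 11)
    ev <- detect_junctions(pool_pairs(rd), el)
    expect_gt(nrow(ev), 0)
    expect_true(all(ev$topology == topo))
    expect_true(all(ev$indel == -3))
    expect_true(all(ev$anchor_left >= 15 & ev$anchor_right >= 15))
  }
  # linear element reads produce no junction evidence
  rd_lin <- simulate_reads(c(lin = el$seq), 50, cfg, seed = 13)
  expect_equal(nrow(detect_junctions(pool_pairs(rd_lin), el)), 0)
  # ground-truth round trip: the recorded topology matches the call
  for (topo in c("two-LTR", "one-LTR")) {
    circ <- make_circles(el, topo, junction_indel = 2, n = 1, seed = 8)[[1]]
    rd <- simulate_reads(stats::setNames(circ$seq, circ$id), 50, cfg,
                         circular = TRUE, seed = 14)
    ev <- detect_junctions(pool_pairs(rd), el)
    expect_true(all(ev$topology == circ$topology))
    expect_true(all(ev$indel == circ$indel))
  }
})
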