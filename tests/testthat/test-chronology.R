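test_that("K80 distances match the closed form on constructed cases", {
  expect_equal(unname(k80_distance("ACGTACGT", "ACGTACGT")),
               c(0, 0, 0))
  # 100 ungapped columns, 10 transitions, 0 transversions
  base <- rand_dna(100, seed = 1)
  v <- mobilomeR:::dna_ints(base)
  idx <- mobilomeR:::with_seed(2, sample(100, 10))
  v[idx] <- c(2L, 3L, 0L, 1L)[v[idx] + 1L] # transition partners
  k1 <- k80_distance(base, mobilomeR:::ints_dna(v))
  expect_equal(unname(k1["P"]), 0.1)
  expect_equal(unname(k1["Q"]), 0)
  expect_equal(unname(k1["K"]), -0.5 * log(0.8), tolerance = 1e-12)
  # P = 0.1, Q = 0.1 over 100 columns
  v2 <- mobilomeR:::dna_ints(base)
  idx2 <- mobilomeR:::with_seed(3, sample(100, 20))
  ts_idx <- idx2[1:10]; tv_idx <- idx2[11:20]
  v2[ts_idx] <- c(2L, 3L, 0L, 1L)[v2[ts_idx] + 1L]
  v2[tv_idx] <- (v2[tv_idx] + 1L) %% 4L
  # +1 mod 4 maps A->C (tv), C->G (tv), G->T (tv), T->A (tv)
  k2 <- k80_distance(base, mobilomeR:::ints_dna(v2))
  expect_equal(unname(k2["P"]), 0.1)
  expect_equal(unname(k2["Q"]), 0.1)
  expect_equal(unname(k2["K"]), -0.5 * log(0.7) - 0.25 * log(0.8),
               tolerance = 1e-12)
  # symmetry: swapping the LTRs leaves the distance unchanged
  expect_equal(k80_distance(base, mobilomeR:::ints_dna(v2)),
               k80_distance(mobilomeR:::ints_dna(v2), base))
  # saturation reports missing with a warning
  expect_warning(ks <- k80_distance(paste(rep("A", 50), collapse = ""),
                                    paste(rep("G", 50), collapse = "")),
                 "saturated")
  expect_true(is.na(ks["K"]))
})

test_that("ages follow T = K/(2r) on the Myr scale", {
  expect_equal(estimate_age(0), 0)
  expect_equal(estimate_age(0.026, r = 1.3e-8), 1.0)
  expect_equal(estimate_age(0.026 * 2), 2.0)
  ks <- seq(0, 0.5, by = 0.05)
  expect_true(all(diff(estimate_age(ks)) > 0))
  expect_error(estimate_age(0.1, r = 0), "positive")
})

test_that("age histograms use half-open bins and conserve counts", {
  h <- age_histogram(c(0, 0.05, 0.15))
  expect_equal(h$count[h$bin == 0], 2)
  expect_equal(h$count[h$bin == 1], 1)
  expect_equal(nrow(age_histogram(numeric(0))), 0)
  ages <- mobilomeR:::with_seed(4, stats::runif(500, 0, 3))
  expect_equal(sum(age_histogram(ages)$count), 500)
  # boundary value lands in the upper bin (half-open convention)
  expect_equal(age_histogram(0.1)$bin, 1)
})

test_that("gene context distances, classes and bins are assigned correctly", {
  genes <- data.frame(chrom = "chr1", start = c(10000, 50000),
                      end = c(12000, 52000))
  copies <- data.frame(
    chrom = "chr1",
    start = c(10500, 12500, 16500, 40000, 30000),
    end = c(11000, 13000, 17000, 41000, 31000)
  )
  gc <- gene_context(copies, genes)
  expect_equal(gc$distance, c(0, 500, 4500, 9000, 18000))
  expect_equal(gc$class,
               c("genic", "genic", "intergenic", "intergenic", "intergenic"))
  expect_equal(gc$bin, c(NA, 1, 5, 9, NA))
  # chromosome without genes: missing distance, intergenic by convention
  lonely <- gene_context(data.frame(chrom = "chr9", start = 1, end = 100),
                         genes)
  expect_true(is.na(lonely$distance))
  expect_equal(lonely$class, "intergenic")
})

test_that("context-distribution comparison reproduces chi-squared arithmetic", {
  # identical distributions: zero statistic, p = 1
  same <- compare_context_distributions(c(10, 20, 30), c(100, 200, 300))
  expect_equal(same$chi2, 0)
  expect_equal(same$chi2_p, 1)
  # hand-computed GOF: A = (100, 900) against 50/50 expectations
  r <- compare_context_distributions(c(100, 900), c(500, 500))
  expect_equal(r$chi2, (100 - 500)^2 / 500 + (900 - 500)^2 / 500)
  expect_equal(r$chi2, 640)
  # brute-force sum on random tables
  for (seed in 1:5) {
    ab <- mobilomeR:::with_seed(seed, {
      list(a = stats::rpois(8, 40) + 1, b = stats::rpois(8, 60) + 1)
    })
    rr <- suppressWarnings(compare_context_distributions(ab$a, ab$b))
    e <- sum(ab$a) * ab$b / sum(ab$b)
    expect_equal(rr$chi2, sum((ab$a - e)^2 / e))
  }
  # KS on identical samples: statistic 0
  x <- mobilomeR:::with_seed(5, stats::runif(100, 0, 10000))
  rks <- suppressWarnings(
    compare_context_distributions(c(1, 1), c(1, 1), x, x))
  expect_equal(rks$ks_stat, 0)
  expect_error(compare_context_distributions(c(0, 0), c(1, 1)), "zero")
})

test_that("lineage correlations recover collinear structure", {
  tab <- data.frame(
    lineage = c("Ale", "SIRE", "Retand", "Tekay"),
    n_copies = c(10, 50, 30, 20),
    n_solo = c(20, 100, 60, 40),     # exactly 2x n_copies
    mean_age = c(4, 1, 2, 3)          # perfectly anti-ranked, nonlinear ok
  )
  r <- lineage_correlations(tab)
  cs <- r[r$feature_x == "n_copies" & r$feature_y == "n_solo", ]
  expect_equal(cs$r, 1)
  expect_equal(cs$r2, 1)
  anti <- data.frame(l = c("a", "b", "c"), x = c(1, 2, 3), y = c(3, 2, 1))
  ra <- lineage_correlations(anti)
  expect_equal(ra$r[1], -1)
  # hand-computed r on a small table
  small <- data.frame(x = c(1, 2, 4), y = c(1, 3, 4))
  rs <- lineage_correlations(small)
  expect_equal(rs$r[1], stats::cov(small$x, small$y) /
                 (stats::sd(small$x) * stats::sd(small$y)))
  expect_warning(
    lineage_correlations(data.frame(x = c(1, 1, 1), y = c(1, 2, 3))),
    "zero variance"
  )
  expect_error(lineage_correlations(data.frame(x = 1:2, y = 1:2)),
               "at least 3")
})

test_that("synth round trip: mean estimated age recovers the target divergence", {
  target <- 0.052 # K for a 2-Myr-old insertion at the default clock
  ltr <- rand_dna(500, seed = 8)
  ts <- vapply(1:100, function(s) {
    m <- mutate_ltr_pair(ltr, target, seed = s)
    estimate_age(unname(k80_distance(m$ltr5, m$ltr3)["K"]))
  }, numeric(1))
  expected_t <- target / (2 * 1.3e-8) / 1e6
  se <- stats::sd(ts) / sqrt(length(ts))
  expect_lt(abs(mean(ts) - expected_t), 3 * se + 1e-9)
})
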