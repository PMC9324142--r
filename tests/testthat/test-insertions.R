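# One shared mid-scale fixture for the caller tests: a reference genome,
# two "sublines" with planted de novo insertions, and their read sets.
.ins_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    el <- quick_element("alex", ltr_len = 150, internal_len = 1200,
                        tsd_len = 5)
    genome <- stats::setNames(rand_dna(120000, 0.38, seed = 55), "chr1")
    shared <- data.frame(chrom = "chr1", pos = c(25000, 55000))
    g1 <- plant_insertions(genome, el, rbind(shared, data.frame(
      chrom = "chr1", pos = c(42000, 85000))))
    g2 <- plant_insertions(genome, el, rbind(shared, data.frame(
      chrom = "chr1", pos = 101000)))
    cfg <- synth_config(seed = 1, error_rate = 0.001)
    rd1 <- simulate_reads(g1$genome, 25, cfg, seed = 101)
    rd2 <- simulate_reads(g2$genome, 25, cfg, seed = 102)
    cache <<- list(el = el, genome = genome, g1 = g1, g2 = g2,
                   rd1 = rd1, rd2 = rd2)
    cache
  }
})

test_that("coverage estimation is the printed formula", {
  expect_equal(estimate_coverage(1e6, 150, 5e6), 30)
  expect_equal(estimate_coverage(5e6, 1, 5e6), 1)
  expect_equal(estimate_coverage(2e6, 150, 5e6),
               2 * estimate_coverage(1e6, 150, 5e6))
  expect_error(estimate_coverage(10, 150, 0), "positive")
})

test_that("window calling needs the support floor and finds planted sites", {
  fx <- .ins_fixture()
  lib <- c(alex = fx$el$seq)
  cw <- call_windows(fx$rd1$r1, fx$rd1$r2, lib, fx$genome)
  expect_true(all(cw$windows$support >= 2))
  hit_wins <- unique(cw$windows$win_start)
  for (p in c(25000, 42000, 55000, 85000)) {
    expect_true(((p %/% 10000) * 10000) %in% hit_wins)
  }
  # reads from the unmodified reference genome: no candidate windows at
  # the planted sites (the reference carries no element copy at all)
  cfg <- synth_config(seed = 1, error_rate = 0.001)
  rd0 <- simulate_reads(fx$genome, 10, cfg, seed = 200)
  cw0 <- call_windows(rd0$r1, rd0$r2, lib, fx$genome)
  expect_equal(nrow(cw0$windows), 0)
  # a single supporting pair is below the floor
  cw1 <- call_windows(fx$rd1$r1[1], fx$rd1$r2[1], lib, fx$genome)
  expect_equal(nrow(cw1$windows), 0)
})

test_that("breakpoints refine to <= 200 bp containing the planted site with its TSD", {
  fx <- .ins_fixture()
  lib <- c(alex = fx$el$seq)
  cw <- call_windows(fx$rd1$r1, fx$rd1$r2, lib, fx$genome)
  truth_pos <- sort(fx$g1$truth$pos)
  found <- 0
  for (i in seq_len(nrow(cw$windows))) {
    rf <- refine_breakpoints(cw$windows[i, ], cw$genome_aln,
                             c(fx$el$ltr5))
    if (is.na(rf$start)) next
    expect_lte(rf$end - rf$start, 200)
    tp <- truth_pos[truth_pos >= rf$start - 200 & truth_pos <= rf$end]
    if (length(tp) == 1) {
      found <- found + 1
      # refined interval contains the planted breakpoint
      expect_gte(tp, rf$start)
      expect_lte(tp, rf$end)
      if (!is.na(rf$tsd_len)) expect_equal(rf$tsd_len, 5L)
    }
  }
  expect_gte(found, 4) # all four g1 sites (some via two flanking windows)
})

test_that("sample comparison merges by distance and labels statuses", {
  calls <- data.frame(
    sample = c("s1", "s2", "s1", "s1", "s2"),
    subfamily = "alex", chrom = "chr1",
    start = c(1000, 1050, 9000, 30000, 50000),
    end = c(1010, 1060, 9010, 30010, 50010),
    stringsAsFactors = FALSE
  )
  copies <- data.frame(chrom = "chr1", start = 49900, end = 51400)
  cs <- compare_samples(calls, copies)
  expect_equal(nrow(cs$sites), 4) # 1000/1050 merge; others distinct
  st <- cs$sites
  expect_equal(st$status[st$start == 1000], "shared-non-reference")
  expect_equal(st$status[st$start == 9000], "private")
  expect_equal(st$status[st$start == 30000], "private")
  expect_equal(st$status[st$start == 50000], "reference")
  expect_true(cs$presence["1", "s1"] && cs$presence["1", "s2"])
  # sites far apart stay distinct
  far <- compare_samples(data.frame(
    sample = c("s1", "s2"), subfamily = "alex", chrom = "chr1",
    start = c(1000, 6000), end = c(1010, 6010)), NULL)
  expect_equal(nrow(far$sites), 2)
})

test_that("masking restores the empty allele (excise) or blanks it (nmask)", {
  el <- quick_element()
  genome <- stats::setNames(rand_dna(20000, 0.4, seed = 61), "chr1")
  pl <- plant_insertions(genome, el, data.frame(chrom = "chr1",
                                                pos = 8000, tsd_len = 5))
  sites <- data.frame(chrom = "chr1", start = 8005,
                      end = 8005 + nchar(el$seq), tsd_len = 5)
  ex <- mask_genome(pl$genome, sites, mode = "excise")
  # excision restores the original pre-insertion sequence exactly
  expect_identical(ex$genome[["chr1"]], genome[["chr1"]])
  expect_equal(ex$sites$masked_pos, 8000)
  nm <- mask_genome(pl$genome, sites, mode = "nmask")
  expect_equal(nchar(nm$genome[["chr1"]]), nchar(pl$genome[["chr1"]]))
  expect_identical(substr(nm$genome[["chr1"]], 8006, 8010), "NNNNN")
  expect_error(mask_genome(pl$genome, sites[, 1:3], mode = "excise"),
               "tsd_len")
})

test_that("validation-report arithmetic and bounds hold", {
  vr <- validation_report(9, 4, 0, 1)
  expect_equal(vr$n_calls, 36)
  expect_equal(vr$fn_rate, 2.8)
  expect_equal(vr$fp_rate, 0)
  vr2 <- validation_report(9, 4, 2, 0)
  expect_equal(vr2$fp_rate, round(100 * 2 / 36, 1))
  expect_error(validation_report(2, 2, 5, 0))
  expect_error(validation_report(2, 2, -1, 0))
})

test_that("FP/FN counts move monotonically with the soft-clip threshold", {
  # stricter qualification (longer min_clip) can only lose evidence:
  # FP count is non-increasing, FN count non-decreasing
  fx <- .ins_fixture()
  sites <- data.frame(chrom = "chr1",
                      start = fx$g1$truth$pos[1] + 5,
                      end = fx$g1$truth$pos[1] + 5 + nchar(fx$el$seq),
                      tsd_len = 5)
  rs <- list(s1 = list(r1 = fx$rd1$r1, r2 = fx$rd1$r2))
  v_loose <- mask_and_validate(fx$g1$genome, sites, rs, c(fx$el$ltr5),
                               min_clip = 8)
  v_tight <- mask_and_validate(fx$g1$genome, sites, rs, c(fx$el$ltr5),
                               min_clip = 40)
  expect_lte(v_tight$fp_count, v_loose$fp_count)
  expect_gte(v_tight$fn_count, v_loose$fn_count)
})
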