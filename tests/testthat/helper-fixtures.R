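# Shared fixture builders: everything is generated in code, seeded, small.

quick_element <- function(name = "alex", ltr_len = 150, internal_len = 1200,
                          tsd_len = 5, lineage = "Ale", target_k = 0,
                          seed = 5, ...) {
  mobilomeR:::.build_element(
    element_spec(name, ltr_len = ltr_len, internal_len = internal_len,
                 tsd_len = tsd_len, target_k = target_k,
                 lineage = lineage, ...),
    seed, domain_reference_db()
  )
}

# random DNA string under a local seed (does not disturb the session RNG)
rand_dna <- function(n, gc = 0.5, seed = 1) {
  mobilomeR:::with_seed(seed, mobilomeR:::random_dna(n, gc))
}

# apply `n_sub` random substitutions (transitions with prob ts_frac)
mutate_seq <- function(s, n_sub, seed = 1, ts_frac = 2 / 3) {
  mobilomeR:::with_seed(seed, {
    v <- mobilomeR:::dna_ints(s)
    idx <- sample(length(v), n_sub)
    for (i in idx) {
      v[i] <- if (runif(1) < ts_frac) {
        c(2L, 3L, 0L, 1L)[v[i] + 1L]
      } else {
        sample(setdiff(0:3, c(v[i], c(2L, 3L, 0L, 1L)[v[i] + 1L])), 1)
      }
    }
    mobilomeR:::ints_dna(v)
  })
}

# pool mates with /1 and /2 suffixes (mapper needs unique read ids)
pool_pairs <- function(rd) {
  c(stats::setNames(rd$r1, paste0(names(rd$r1), "/1")),
    stats::setNames(rd$r2, paste0(names(rd$r2), "/2")))
}
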