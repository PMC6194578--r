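# Shared fixtures, built lazily once per test run and cached in an
# environment so the expensive cohorts are constructed a single time.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small 20-experiment cohort for unit tests (sub-second build).
small_cohort <- function() {
  fixture("small_cohort", function() {
    sim <- simulate_experiments(n_experiments = 20, seed = 5, n_private = 1,
                                n_core = 5, n_accessory = 20,
                                len_range = c(100, 200))
    idx <- suppressMessages(
      build_index(sim$manifest, cap_bytes = 4096, seed = 2, group_size = 8,
                  keep_groups = TRUE))
    list(sim = sim, idx = idx)
  })
}

# Full-scale study cohort: 100 experiments, ~5e5 distinct 21-mers.
full_cohort <- function() {
  fixture("full_cohort", function() {
    sim <- simulate_experiments(seed = 42)
    idx <- suppressMessages(
      build_index(sim$manifest, cap_bytes = 65536, seed = 7))
    unlink(sim$dir, recursive = TRUE)
    list(sim = sim, idx = idx)
  })
}

# Othello on 1e5 random 21-mers with v = 3 (alien-recognition studies).
large_othello <- function() {
  fixture("large_othello", function() {
    keys <- random_kmers(1e5, 21, seed = 301)
    vals <- with_seed(302, sample.int(3L, 1e5, replace = TRUE))
    list(keys = keys, vals = vals,
         oth = build_othello(keys, vals, v = 3L, seed = 303))
  })
}

random_occurrence_map <- function(m, t = NULL) {
  bits <- integer(m)
  if (is.null(t)) t <- sample.int(m, 1L)
  bits[sample.int(m, t)] <- 1L
  occurrence_map(bits)
}

expect_map_roundtrip <- function(enc, map) {
  expect_identical(decode_occurrence(enc, map$m)$bits, map$bits)
}
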