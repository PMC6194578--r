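# The XOR-retrieval hashing classifier: construction, query, alien-value
# analytics, and serialization.

test_that("every constructed key retrieves its assigned category", {
  k1 <- "ACGTACGTACGTACGTACGTA"
  o1 <- build_othello(k1, 1L)
  expect_identical(query_othello(o1, k1), 1L)

  keys <- random_kmers(1000, 21, seed = 11)
  vals <- with_seed(12, sample.int(7L, 1000, replace = TRUE))
  o <- build_othello(keys, vals, v = 7L, seed = 13)
  expect_identical(query_othello(o, keys), vals)
})

test_that("array sizes and storage respect the stated bounds", {
  for (n in c(1L, 1000L, 5000L, 30000L)) {
    keys <- random_kmers(n, 21, seed = n)
    vals <- with_seed(n + 1L, sample.int(7L, n, replace = TRUE))
    o <- build_othello(keys, vals, v = 7L, seed = 1)
    ratio <- (o$ma + o$mb) / o$n
    if (n > 1) {
      expect_gte(ratio, 2.67)
      expect_lt(ratio, 4)
    }
    expect_lte((o$ma + o$mb) * o$l, 4 * n * ceiling(log2(7 + 1)))
    expect_identical(o$ma, as.integer(2^ceiling(log2(n))))
    expect_identical(o$mb, as.integer(2^ceiling(log2(4 * n / 3))))
  }
})

test_that("invalid inputs are rejected with informative errors", {
  keys <- c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTA")
  expect_error(build_othello(keys, c(1L, 2L)), "duplicate key")
  expect_error(build_othello(keys[1], 0L, v = 3L), "values must lie")
  expect_error(build_othello(keys[1], 5L, v = 3L), "values must lie")
  expect_error(build_othello("ACGTNCGTACGTACGTACGTA", 1L), "non-ACGT")
})

test_that("a fixed hash seed yields byte-identical structures", {
  keys <- random_kmers(500, 21, seed = 21)
  vals <- with_seed(22, sample.int(3L, 500, replace = TRUE))
  o1 <- build_othello(keys, vals, seed = 23)
  o2 <- build_othello(keys, vals, seed = 23)
  expect_identical(serialize_othello(o1), serialize_othello(o2))
})

test_that("alien queries are deterministic and recomputable from the arrays", {
  keys <- random_kmers(200, 21, seed = 31)
  vals <- with_seed(32, sample.int(3L, 200, replace = TRUE))
  o <- build_othello(keys, vals, seed = 33)
  probes <- sample_alien_kmers(50, 21, exclude = keys, seed = 34)
  expect_identical(query_othello(o, probes), query_othello(o, probes))
  # the result is literally A[h_a] XOR B[h_b]: check against a brute-force
  # scan over all (a, b) pairs consistent with the returned value
  tau <- query_othello(o, probes)
  expect_true(all(tau >= 0 & tau < 2^o$l))
  xor_table <- outer(o$A, o$B, bitwXor)
  expect_true(all(tau %in% as.vector(xor_table)))
})

test_that("alien value distribution matches the XOR convolution and Monte Carlo", {
  # degenerate all-zero arrays: every alien key maps to 0
  o0 <- build_othello("ACGTACGTACGTACGTACGTA", 1L)
  o0$A[] <- 0L; o0$B[] <- 0L
  prof0 <- alien_value_distribution(o0)
  expect_equal(prof0$p0, 1)
  expect_equal(sum(prof0$p), 1)

  keys <- random_kmers(1e4, 21, seed = 41)
  vals <- with_seed(42, sample.int(3L, 1e4, replace = TRUE))
  o <- build_othello(keys, vals, v = 3L, seed = 43)
  prof <- alien_value_distribution(o)
  expect_equal(sum(prof$p), 1, tolerance = 1e-12)
  probes <- sample_alien_kmers(1e5, 21, exclude = keys, seed = 44)
  tau <- query_othello(o, probes)
  emp <- tabulate(tau + 1L, nbins = 2^o$l) / length(probes)
  sig <- sqrt(prof$p * (1 - prof$p) / length(probes))
  expect_true(all(abs(emp - prof$p) <= 3 * sig + 1e-12))
})

test_that("alien rejection probability sums the out-of-category mass", {
  keys <- random_kmers(2000, 21, seed = 51)
  # v saturates C - {0}: P_Alien reduces to p0
  vals <- with_seed(52, sample.int(3L, 2000, replace = TRUE))
  o <- build_othello(keys, vals, v = 3L, seed = 53)
  prof <- alien_value_distribution(o)
  expect_equal(alien_rejection_probability(o), prof$p0)
  # non-saturating v: tail terms included
  o2 <- build_othello(keys, vals, v = 5L, seed = 53)
  p2 <- alien_value_distribution(o2)$p
  expect_equal(alien_rejection_probability(o2), p2[1] + p2[7] + p2[8])
})

test_that("serialization round-trips and rejects corrupt streams", {
  keys <- random_kmers(2000, 21, seed = 61)
  vals <- with_seed(62, sample.int(5L, 2000, replace = TRUE))
  o <- build_othello(keys, vals, seed = 63)
  bytes <- serialize_othello(o)
  o2 <- deserialize_othello(bytes)
  probes <- random_kmers(1e4, 21, seed = 64)
  expect_identical(query_othello(o, probes), query_othello(o2, probes))
  # payload size arithmetic: header + ceil(ma*l/8) + ceil(mb*l/8)
  expect_identical(length(bytes),
                   as.integer(4 + 7 * 4 + 8 +
                              ceiling(o$ma * o$l / 8) +
                              ceiling(o$mb * o$l / 8)))
  expect_error(deserialize_othello(bytes[1:20]), "truncated")
  expect_error(deserialize_othello(bytes[-length(bytes)]), "truncated")
  bad <- bytes; bad[60] <- as.raw(bitwXor(as.integer(bad[60]), 255L))
  expect_error(deserialize_othello(bad), "checksum")
  nomagic <- bytes; nomagic[1] <- as.raw(0)
  expect_error(deserialize_othello(nomagic), "magic")
})

test_that("unassigned array entries hold zero", {
  # with n much smaller than m_a + m_b most entries are never visited;
  # all must be exactly 0 for the alien-rejection bound to apply
  keys <- random_kmers(10, 21, seed = 71)
  o <- build_othello(keys, rep(1L, 10), seed = 72)
  expect_gte(sum(o$A == 0L) + sum(o$B == 0L), o$ma + o$mb - 2L * 10L)
})
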