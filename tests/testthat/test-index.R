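# Two-level index: group files, merge, bucket estimation/assignment, full
# construction, persistence, and incremental insertion.

test_that("a single-member group maps every k-mer to <0,1,0>", {
  kmers <- random_kmers(50, 21, seed = 101, canonical = TRUE)
  g <- build_group_file(list(sort(kmers)), member_ids = 1L)
  expect_identical(g$maps, "1")
  expect_identical(encode_delta_list(occurrence_map(g$maps[1]))[1:3],
                   c(0L, 1L, 0L))
})

test_that("group and merge maps equal brute-force membership", {
  with_seed(102, {
    pool <- random_kmers(400, 21, seed = 103, canonical = TRUE)
    sets <- lapply(1:10, function(i)
      sort(sample(pool, sample(50:200, 1)), method = "radix"))
  })
  groups <- lapply(1:3, function(g) {
    ids <- list(1:4, 5:8, 9:10)[[g]]
    build_group_file(sets[ids], member_ids = ids, group_id = g)
  })
  merged <- merge_group_files(groups)
  expect_identical(merged$kmers,
                   sort(unique(unlist(sets)), method = "radix"))
  # dense membership oracle
  want <- vapply(merged$kmers, function(km) {
    paste(as.integer(vapply(sets, function(s) km %in% s, logical(1))),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
  expect_identical(merged$maps[merged$map_id], want)
  expect_error(merge_group_files(groups[c(1, 1, 3)]), "overlap")
})

test_that("group files round-trip through disk and shrink overlapping input", {
  sm <- small_cohort()
  g <- sm$idx$groups[[1]]
  path <- tempfile(fileext = ".tsv.gz")
  write_group_file(g, path, k = 21)
  g2 <- read_group_file(path)
  expect_identical(g2$kmers, g$kmers)
  expect_identical(g2$maps[g2$map_id], g$maps[g$map_id])
  expect_identical(g2$member_ids, g$member_ids)
  # overlapping member sets compress: group file smaller than concatenated
  # member k-mer files
  member_bytes <- sum(file.size(sm$sim$manifest$path[g$member_ids]))
  expect_lt(file.size(path), member_bytes)
})

test_that("bucket ranges are greedy-maximal under the capacity", {
  # hand-computable histogram: lengths 1..4 with 10 k-mers each,
  # cap 8 bytes = 64 bits; payload(1,2) = 30 <= 64, +3*10 -> 60 <= 64,
  # +4*10 -> 100 > 64, so first bucket is [1,4), second [4,Inf)
  lens <- rep(1:4, each = 10)
  specs <- estimate_bucket_ranges(lens, total = 40, cap_bytes = 8)
  expect_identical(specs$min_bits, c(1L, 4L))
  expect_identical(specs$max_bits, c(4, Inf))
  # huge capacity: a single open-ended bucket
  one <- estimate_bucket_ranges(lens, total = 40, cap_bytes = 2^30)
  expect_identical(nrow(one), 1L)
  expect_identical(one$max_bits, Inf)
  # scaling: the same sample representing 10x the k-mers splits earlier
  scaled <- estimate_bucket_ranges(lens, total = 400, cap_bytes = 8)
  expect_gt(nrow(scaled), nrow(specs))
  expect_error(estimate_bucket_ranges(integer(0)), "empty")
})

test_that("every bucketed k-mer lands inside its bucket's length range", {
  sm <- small_cohort()
  idx <- sm$idx
  truth <- sm$sim$truth
  tt <- vapply(truth$maps, function(s) sum(bitstring_to_bits(s)), integer(1))
  multi <- which(tt[truth$map_id] >= 2L)
  routes <- query_kmer_routes(idx, truth$kmers[multi])
  expect_true(all(routes$status == 2L))
  lens <- vapply(multi, function(i)
    choose_encoding(truth$maps[truth$map_id[i]])$bit_length, integer(1))
  spec <- idx$bucket_specs
  expect_true(all(lens >= spec$min_bits[routes$bucket] &
                  lens < spec$max_bits[routes$bucket]))
})

test_that("indexed k-mers retrieve exact occurrence maps; singles hit the root", {
  sm <- small_cohort()
  truth <- sm$sim$truth
  got <- query_kmer_maps(sm$idx, truth$kmers)
  expect_identical(got, truth$maps[truth$map_id])
  # t = 1 k-mers route root-direct (status "single"), never into a bucket
  tt <- vapply(truth$maps, function(s) sum(bitstring_to_bits(s)), integer(1))
  singles <- truth$kmers[tt[truth$map_id] == 1L]
  routes <- query_kmer_routes(sm$idx, singles)
  expect_true(all(routes$status == 1L))
})

test_that("a one-experiment build has zero buckets", {
  kmers <- random_kmers(200, 21, seed = 111, canonical = TRUE)
  f <- tempfile(); write_kmer_file(kmers, f)
  idx <- build_index(data.frame(name = "only", path = f), seed = 3)
  expect_length(idx$buckets, 0L)
  routes <- query_kmer_routes(idx, sort(kmers, method = "radix"))
  expect_true(all(routes$status == 1L & routes$exp == 1L))
})

test_that("rebuilding with the same seed gives byte-identical index files", {
  sm <- small_cohort()
  idx2 <- suppressMessages(
    build_index(sm$sim$manifest, cap_bytes = 4096, seed = 2, group_size = 8,
                keep_groups = TRUE))
  d1 <- tempfile(); d2 <- tempfile()
  save_index(sm$idx, d1); save_index(idx2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     label = f)
  }
})

test_that("save/load round-trips in both preload modes", {
  sm <- small_cohort()
  truth <- sm$sim$truth
  d <- tempfile()
  save_index(sm$idx, d)
  expect_true(file.exists(file.path(d, "meta.xml")))
  for (preload in c(TRUE, FALSE)) {
    idx <- load_index(d, preload = preload)
    expect_identical(idx$exp_names, sm$sim$manifest$name)
    expect_identical(query_kmer_maps(idx, truth$kmers),
                     truth$maps[truth$map_id])
  }
  # the stored index is far smaller than the k-mer files it summarizes
  index_bytes <- sum(file.size(list.files(d, recursive = TRUE,
                                          full.names = TRUE)))
  input_bytes <- sum(file.size(sm$sim$manifest$path))
  expect_lt(index_bytes, input_bytes)
  expect_error(load_index(tempfile()), "meta.xml")
})

test_that("incremental insertion equals a from-scratch build on the union", {
  sm <- small_cohort()
  man <- sm$sim$manifest
  part <- suppressMessages(
    build_index(man[1:12, ], cap_bytes = 4096, seed = 2, group_size = 8,
                keep_groups = TRUE))
  ins <- suppressMessages(insert_experiments(part, man[13:20, ]))
  expect_identical(ins$exp_names, man$name)
  truth <- sm$sim$truth
  expect_identical(query_kmer_maps(ins, truth$kmers),
                   query_kmer_maps(sm$idx, truth$kmers))
  probes <- sample_alien_kmers(5000, 21, exclude = truth$kmers, seed = 112,
                               canonical = TRUE)
  expect_identical(query_kmer_maps(ins, probes),
                   query_kmer_maps(sm$idx, probes))
  # zero-insertion is query-equivalent
  noop <- suppressMessages(insert_experiments(part, man[0, ]))
  expect_identical(query_kmer_maps(noop, truth$kmers),
                   query_kmer_maps(part, truth$kmers))
  expect_error(insert_experiments(part, man[1, ]), "duplicate")
  expect_error(insert_experiments(sm$idx$root, man[13:20, ]))
})
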