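# Occurrence-map codecs: value list, delta list + hexadecimal stream,
# bitmap, and shortest-code selection.

test_that("the 20-experiment worked example encodes and decodes exactly", {
  map <- occurrence_map("11100111111111111110")
  runs <- encode_delta_list(map)
  expect_identical(as.integer(runs), c(0L, 3L, 2L, 14L, 1L))
  enc <- hex_encode_delta_list(runs, 20)
  expect_identical(enc$payload, as.raw(c(0x8b, 0xa4, 0xe9)))
  expect_identical(enc$bit_length, 24L)
  expect_identical(hex_decode_stream(enc$payload, 20),
                   structure(c(0L, 3L, 2L, 14L, 1L), class = "delta_list"))
  expect_identical(format(decode_occurrence(enc, 20)),
                   "11100111111111111110")
})

test_that("hexadecimal tokens follow the five length classes", {
  tok <- hex_encode_integer(0)
  expect_identical(tok$bits, c(1L, 0L, 0L, 0L))  # 0x8
  expect_identical(tok$nbits, 4L)
  tok14 <- hex_encode_integer(14)
  expect_identical(bits_to_int_msb(tok14$bits), 0x4EL)
  expect_identical(tok14$nbits, 8L)
  expect_identical(hex_encode_integer(7)$nbits, 4L)
  expect_identical(hex_encode_integer(8)$nbits, 8L)
  expect_identical(hex_encode_integer(63)$nbits, 8L)
  expect_identical(hex_encode_integer(64)$nbits, 12L)
  expect_identical(hex_encode_integer(511)$nbits, 12L)
  expect_identical(hex_encode_integer(512)$nbits, 16L)
  expect_identical(hex_encode_integer(4095)$nbits, 16L)
  expect_identical(hex_encode_integer(4096)$nbits, 32L)
  expect_error(hex_encode_integer(2^28), "overflow")
})

test_that("token streams round-trip over an integer range", {
  zs <- c(0:300, with_seed(1, sample.int(2^28 - 2, 200)))
  for (z in zs) {
    runs <- c(as.integer(z), 1L, 0L)
    enc <- hex_encode_delta_list(runs, m = z + 1L)
    expect_identical(as.integer(hex_decode_stream(enc$payload, z + 1L)),
                     runs)
  }
})

test_that("value-list encoding uses t fixed-width indices", {
  enc <- encode_value_list(occurrence_map(c(1, 1, 1, rep(0, 17))))
  expect_identical(enc$bit_length, 15L)  # 3 indices x ceil(log2 20) = 5 bits
  expect_map_roundtrip(enc, occurrence_map(c(1, 1, 1, rep(0, 17))))
  enc2 <- encode_value_list(occurrence_map(c(0, 1)))
  expect_identical(enc2$bit_length, 1L)  # single 1-bit index
  expect_map_roundtrip(enc2, occurrence_map(c(0, 1)))
  expect_error(encode_value_list(occurrence_map(rep(0, 4))), "never stored")
  expect_error(encode_value_list(occurrence_map(rep(1, 20))),
               "not applicable")
})

test_that("delta lists satisfy the run-structure invariants", {
  expect_identical(as.integer(encode_delta_list(occurrence_map(rep(1, 5)))),
                   c(0L, 5L, 0L))
  expect_identical(as.integer(encode_delta_list(occurrence_map(rep(0, 7)))),
                   7L)
  with_seed(77, {
    for (i in 1:200) {
      m <- sample(1:300, 1)
      map <- random_occurrence_map(m)
      runs <- as.integer(encode_delta_list(map))
      expect_identical(sum(runs), m)
      expect_identical(length(runs) %% 2L, 1L)
      w <- (length(runs) - 1L) %/% 2L
      if (w > 0) {
        expect_true(all(runs[2L * seq_len(w)] >= 1L))       # y_i >= 1
        if (w > 1)
          expect_true(all(runs[2L * (2:w) - 1L] >= 1L))     # interior x_i >= 1
      }
      expect_identical(decode_delta_list(runs, m)$bits, map$bits)
    }
  })
})

test_that("all three codecs round-trip on random maps", {
  with_seed(78, {
    for (i in 1:400) {
      m <- sample(2:2048, 1)
      map <- random_occurrence_map(m)
      expect_map_roundtrip(encode_bitmap(map), map)
      expect_map_roundtrip(hex_encode_delta_list(encode_delta_list(map), m),
                           map)
      if (map$t * ceiling(log2(m)) <= 64)
        expect_map_roundtrip(encode_value_list(map), map)
      expect_map_roundtrip(choose_encoding(map), map)
    }
  })
})

test_that("bitmap bit order places experiment 1 at the MSB of byte 1", {
  enc <- encode_bitmap(occurrence_map(c(1, rep(0, 7))))
  expect_identical(enc$payload, as.raw(0x80))
  expect_identical(encode_bitmap(occurrence_map(rep(0, 8)))$payload,
                   as.raw(0x00))
  expect_identical(decode_occurrence(new_enc <- encode_bitmap(
    occurrence_map(rep(0, 8))), 8)$t, 0L)
})

test_that("the shortest applicable code is always selected", {
  # m=10000, t=2: value list at 2*14=28 bits
  big <- integer(10000); big[c(3, 9999)] <- 1L
  enc <- choose_encoding(occurrence_map(big))
  expect_identical(ENC_NAMES[enc$kind], "value_list")
  expect_identical(enc$bit_length, 28L)
  # m=20 all ones: delta <0,20,0> at 16 bits beats the 20-bit bitmap;
  # value list inapplicable (20*5 = 100 > 64)
  enc2 <- choose_encoding(occurrence_map(rep(1, 20)))
  expect_identical(ENC_NAMES[enc2$kind], "delta_list")
  expect_identical(enc2$bit_length, 16L)
  # m=512 with t~256 random: the bitmap wins
  with_seed(79, {
    enc3 <- choose_encoding(random_occurrence_map(512, 256))
    expect_identical(ENC_NAMES[enc3$kind], "bitmap")
  })
  # minimality against all applicable alternatives
  with_seed(80, {
    for (i in 1:100) {
      map <- random_occurrence_map(sample(2:500, 1))
      chosen <- choose_encoding(map)
      lens <- c(if (map$t * ceiling(log2(map$m)) <= 64)
                  encode_value_list(map)$bit_length,
                hex_encode_delta_list(encode_delta_list(map), map$m)$bit_length,
                map$m)
      expect_identical(chosen$bit_length, min(lens))
    }
  })
  expect_error(choose_encoding(occurrence_map(rep(0, 5))), "never stored")
})

test_that("corrupt delta streams are rejected, not silently decoded", {
  enc <- hex_encode_delta_list(c(0L, 3L, 2L, 14L, 1L), 20)
  expect_error(hex_decode_stream(enc$payload, 15), "overshoot")
  expect_error(hex_decode_stream(enc$payload[1], 20), "truncated")
})
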