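# Hybrid occurrence-map codecs: value list for rare k-mers, delta list with
# a prefix-coded hexadecimal stream for runs, plain bitmap otherwise. The
# shortest applicable code wins.

#' Occurrence map of a k-mer across m experiments
#'
#' @param bits presence vector: integer/logical 0/1 vector, or a single
#'   "0"/"1" character string. Position `e` (1-based) is experiment `e`.
#' @return object of class `occurrence_map` with fields `m`, `bits`
#'   (integer 0/1) and `t` (number of set bits).
#' @export
occurrence_map <- function(bits) {
  if (is.character(bits) && length(bits) == 1L)
    bits <- bitstring_to_bits(bits)
  bits <- as.integer(bits)
  if (length(bits) < 1L) stop("occurrence map must have m >= 1")
  if (any(is.na(bits)) || any(bits < 0L | bits > 1L))
    stop("occurrence map bits must be 0/1")
  structure(list(m = length(bits), bits = bits, t = sum(bits)),
            class = "occurrence_map")
}

as_occurrence_map <- function(x) {
  if (inherits(x, "occurrence_map")) x else occurrence_map(x)
}

#' @export
print.occurrence_map <- function(x, ...) {
  cat(sprintf("occurrence_map: m=%d, t=%d [%s]\n", x$m, x$t,
              bits_to_bitstring(x$bits)))
  invisible(x)
}

#' @method format occurrence_map
#' @export
format.occurrence_map <- function(x, ...) bits_to_bitstring(x$bits)

ENC_VALUE_LIST <- 1L
ENC_DELTA_LIST <- 2L
ENC_BITMAP <- 3L
ENC_NAMES <- c("value_list", "delta_list", "bitmap")

new_encoded <- function(kind, payload, bit_length, m) {
  structure(list(kind = kind, payload = payload,
                 bit_length = as.integer(bit_length), m = as.integer(m)),
            class = "encoded_occurrence")
}

#' @export
print.encoded_occurrence <- function(x, ...) {
  cat(sprintf("encoded_occurrence: %s, %d bits (m=%d)\n",
              ENC_NAMES[x$kind], x$bit_length, x$m))
  invisible(x)
}

#' Value-list encoding of a sparse occurrence map
#'
#' Stores the `t` positions of set bits as fixed-width indices of
#' `ceil(log2 m)` bits each (positions are 1-based ascending; the field
#' holds `position - 1`). Applicable when `t * ceil(log2 m) <= 64` and
#' `m >= 2`.
#'
#' @param map an `occurrence_map` (or 0/1 vector / bitstring).
#' @return an `encoded_occurrence` of kind `value_list`.
#' @export
encode_value_list <- function(map) {
  map <- as_occurrence_map(map)
  if (map$t == 0L) stop("an all-absent occurrence map is never stored")
  bpi <- value_list_index_bits(map$m)
  if (is.na(bpi) || map$t * bpi > 64L)
    stop("value-list encoding not applicable: t*ceil(log2 m) = ",
         map$t * bpi, " exceeds 64 (or m < 2)")
  pos <- which(map$bits == 1L)
  bits <- unlist(lapply(pos - 1L, int_to_bits_msb, width = bpi))
  new_encoded(ENC_VALUE_LIST, pack_bits_msb(bits), map$t * bpi, map$m)
}

value_list_index_bits <- function(m) {
  if (m < 2L) return(NA_integer_)
  ceil_log2(m)
}

#' Delta-list (run-length) representation of an occurrence map
#'
#' The map is read as alternating runs of 0s and 1s:
#' `<x1, y1, ..., xw, yw, x(w+1)>` with a possibly empty leading and
#' trailing 0-run. Run lengths sum to `m`. An all-zero map yields the
#' degenerate single-element list `<m>` (used only transiently in group
#' files).
#'
#' @inheritParams encode_value_list
#' @return integer vector of run lengths, class `delta_list`.
#' @export
encode_delta_list <- function(map) {
  map <- as_occurrence_map(map)
  r <- rle(map$bits)
  if (map$t == 0L)
    return(structure(map$m, class = "delta_list"))
  runs <- r$lengths
  if (r$values[1L] == 1L) runs <- c(0L, runs)
  if (r$values[length(r$values)] == 1L) runs <- c(runs, 0L)
  structure(as.integer(runs), class = "delta_list")
}

decode_delta_list <- function(runs, m) {
  runs <- as.integer(runs)
  if (sum(runs) != m) stop("delta-list run lengths do not sum to m")
  vals <- rep(c(0L, 1L), length.out = length(runs))
  occurrence_map(rep(vals, runs))
}

#' Prefix-coded hexadecimal token for one delta-list integer
#'
#' Token classes (all multiples of 4 bits, so the stream is a hexadecimal
#' digit sequence): `0 <= z < 8` -> `1zzz` (4 bits); `8 <= z < 64` ->
#' `01zzzzzz` (8 bits); `64 <= z < 512` -> `001` + 9 bits (12 bits);
#' `512 <= z < 4096` -> `0001` + 12 bits (16 bits); `z >= 4096` -> `0000` +
#' 28 bits (32 bits). The leading-zero prefix identifies the class, so any
#' token concatenation decodes uniquely.
#'
#' @param z non-negative integer `< 2^28`.
#' @return list with `bits` (MSB-first integer bit vector) and `nbits`.
#' @export
hex_encode_integer <- function(z) {
  stopifnot(length(z) == 1L, !is.na(z), z >= 0)
  z <- as.integer(z)
  if (z < 8L) {
    bits <- c(1L, int_to_bits_msb(z, 3L))
  } else if (z < 64L) {
    bits <- c(0L, 1L, int_to_bits_msb(z, 6L))
  } else if (z < 512L) {
    bits <- c(0L, 0L, 1L, int_to_bits_msb(z, 9L))
  } else if (z < 4096L) {
    bits <- c(0L, 0L, 0L, 1L, int_to_bits_msb(z, 12L))
  } else if (z < 2^28) {
    bits <- c(0L, 0L, 0L, 0L, int_to_bits_msb(z, 28L))
  } else {
    stop("delta-list integer ", z, " overflows the 28-bit field")
  }
  list(bits = bits, nbits = length(bits))
}

hex_token_nbits <- function(z) {
  # vectorized token lengths without materializing bits
  ifelse(z < 8L, 4L,
  ifelse(z < 64L, 8L,
  ifelse(z < 512L, 12L,
  ifelse(z < 4096L, 16L, 32L))))
}

#' Encode a delta list as a concatenated hexadecimal stream
#'
#' Tokens are concatenated in list order; the payload is padded with zero
#' nibbles to a byte boundary while `bit_length` records the unpadded
#' length used for bucket assignment.
#'
#' @param runs a `delta_list` (or plain integer run-length vector).
#' @param m total map width; defaults to `sum(runs)`.
#' @return an `encoded_occurrence` of kind `delta_list`.
#' @export
hex_encode_delta_list <- function(runs, m = sum(runs)) {
  runs <- as.integer(runs)
  if (sum(runs) != m) stop("delta-list run lengths do not sum to m")
  bits <- unlist(lapply(runs, function(z) hex_encode_integer(z)$bits))
  new_encoded(ENC_DELTA_LIST, pack_bits_msb(bits), length(bits), m)
}

#' Decode a hexadecimal delta-list stream
#'
#' Reads prefix-identified tokens until the decoded run lengths sum to
#' `m`; a malformed prefix, exhausted stream, or run-sum overshoot raises a
#' corruption error.
#'
#' @param payload raw payload from `hex_encode_delta_list`.
#' @param m map width the runs must sum to.
#' @return integer run-length vector of class `delta_list`.
#' @export
hex_decode_stream <- function(payload, m) {
  bits <- unpack_bits_msb(payload, 8L * length(payload))
  pos <- 1L
  take_token <- function() {
    if (pos + 3L > length(bits))
      stop("corrupt delta-list stream: truncated token")
    take <- function(nb) {
      if (pos + nb - 1L > length(bits))
        stop("corrupt delta-list stream: truncated token")
      out <- bits[pos:(pos + nb - 1L)]
      pos <<- pos + nb
      out
    }
    if (bits[pos] == 1L) bits_to_int_msb(take(4L)[-1L])
    else if (bits[pos + 1L] == 1L) bits_to_int_msb(take(8L)[-(1:2)])
    else if (bits[pos + 2L] == 1L) bits_to_int_msb(take(12L)[-(1:3)])
    else if (bits[pos + 3L] == 1L) bits_to_int_msb(take(16L)[-(1:4)])
    else bits_to_int_msb(take(32L)[-(1:4)])
  }
  runs <- integer(0)
  total <- 0L
  repeat {
    z <- take_token()
    runs <- c(runs, z)
    total <- total + z
    if (total > m) stop("corrupt delta-list stream: runs overshoot m")
    if (total == m) {
      # a valid list has odd length; an even count here means the trailing
      # (necessarily zero) 0-run token is still pending
      if (length(runs) %% 2L == 0L) {
        z2 <- take_token()
        if (z2 != 0L)
          stop("corrupt delta-list stream: nonzero token after runs sum to m")
        runs <- c(runs, 0L)
      }
      break
    }
  }
  structure(runs, class = "delta_list")
}

#' Bitmap encoding of an occurrence map
#'
#' `m` bits, experiment 1 at the most significant bit of the first byte.
#'
#' @inheritParams encode_value_list
#' @return an `encoded_occurrence` of kind `bitmap`.
#' @export
encode_bitmap <- function(map) {
  map <- as_occurrence_map(map)
  new_encoded(ENC_BITMAP, pack_bits_msb(map$bits), map$m, map$m)
}

# Encoded bit lengths of the three codecs for a map given as popcount +
# run-length vector; NA where inapplicable.
codec_bit_lengths <- function(m, t, runs) {
  bpi <- value_list_index_bits(m)
  vl <- if (!is.na(bpi) && t >= 1L && t * bpi <= 64L) t * bpi else NA_integer_
  dl <- sum(hex_token_nbits(runs))
  c(value_list = vl, delta_list = dl, bitmap = m)
}

#' Choose the shortest encoding for an occurrence map
#'
#' Computes the encoded bit length of every applicable codec and returns
#' the shortest; ties break value list > delta list > bitmap.
#'
#' @inheritParams encode_value_list
#' @return an `encoded_occurrence`.
#' @export
choose_encoding <- function(map) {
  map <- as_occurrence_map(map)
  if (map$t == 0L) stop("an all-absent occurrence map is never stored")
  runs <- encode_delta_list(map)
  lens <- codec_bit_lengths(map$m, map$t, runs)
  kind <- which.min(lens)  # first minimum = presentation-order tie-break
  switch(names(lens)[kind],
         value_list = encode_value_list(map),
         delta_list = hex_encode_delta_list(runs, map$m),
         bitmap = encode_bitmap(map))
}

#' Decode an encoded occurrence map
#'
#' @param enc an `encoded_occurrence`.
#' @param m map width (defaults to the width recorded in `enc`).
#' @return the reconstructed `occurrence_map`.
#' @export
decode_occurrence <- function(enc, m = enc$m) {
  stopifnot(inherits(enc, "encoded_occurrence"))
  if (enc$kind == ENC_VALUE_LIST) {
    bpi <- value_list_index_bits(m)
    t <- as.integer(enc$bit_length / bpi)
    if (is.na(bpi) || t * bpi != enc$bit_length)
      stop("corrupt value-list payload: bit length not a multiple of index width")
    bits <- unpack_bits_msb(enc$payload, enc$bit_length)
    pos <- vapply(seq_len(t), function(i) {
      bits_to_int_msb(bits[((i - 1L) * bpi + 1L):(i * bpi)]) + 1L
    }, integer(1))
    out <- integer(m)
    out[pos] <- 1L
    occurrence_map(out)
  } else if (enc$kind == ENC_DELTA_LIST) {
    decode_delta_list(hex_decode_stream(enc$payload, m), m)
  } else if (enc$kind == ENC_BITMAP) {
    occurrence_map(unpack_bits_msb(enc$payload, m))
  } else {
    stop("unknown encoding kind ", enc$kind)
  }
}
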