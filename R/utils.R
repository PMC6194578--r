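#' @keywords internal
"_PACKAGE"

#' @useDynLib kothello, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rbeta
#' @importFrom utils write.table read.table
NULL

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the caller's RNG
#' state, so seeded helpers never perturb surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# MSB-first bit packing used by the occurrence-map codecs: bit 1 of the
# stream is the most significant bit of byte 1.
pack_bits_msb <- function(bits) {
  if (length(bits) == 0L) return(raw(0))
  pad <- (-length(bits)) %% 8L
  bits <- c(as.integer(bits), integer(pad))
  m <- matrix(bits, nrow = 8L)
  as.raw(colSums(m * c(128L, 64L, 32L, 16L, 8L, 4L, 2L, 1L)))
}

unpack_bits_msb <- function(bytes, nbits) {
  if (nbits == 0L) return(integer(0))
  b <- matrix(as.integer(rawToBits(bytes)), nrow = 8L)
  bits <- as.vector(b[8:1, , drop = FALSE])
  if (length(bits) < nbits) stop("bit stream shorter than declared length")
  bits[seq_len(nbits)]
}

# Integer -> fixed-width MSB-first bit vector.
int_to_bits_msb <- function(x, width) {
  if (width == 0L) return(integer(0))
  bitwAnd(bitwShiftR(x, (width - 1L):0L), 1L)
}

bits_to_int_msb <- function(bits) {
  as.integer(sum(bits * 2^((length(bits) - 1L):0L)))
}

# "0"/"1" string <-> integer bit vector (occurrence maps travel as strings
# in the bulk pipeline so duplicates dedup cheaply).
bitstring_to_bits <- function(s) {
  as.integer(charToRaw(s)) - 48L
}

bits_to_bitstring <- function(bits) {
  rawToChar(as.raw(bits + 48L))
}

ceil_log2 <- function(x) {
  as.integer(ceiling(log2(x)))
}
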