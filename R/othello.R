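# The Othello minimal-perfect-hashing classifier: a many-to-one map from a
# fixed key set S to categories {1..v}, stored in two l-bit arrays A and B
# with tau(s) = A[h_a(s)] XOR B[h_b(s)].

#' Build an Othello classifier over a set of k-mer keys
#'
#' Constructs the XOR-retrieval structure mapping each key to its assigned
#' category in `1..v`. Keys are modelled as edges of a bipartite graph over
#' the two arrays; when the graph is acyclic the values are assigned by
#' traversal, otherwise the hash pair is reseeded and construction retried.
#' Array lengths are the powers of two `m_a = 2^ceil(log2 n)` and
#' `m_b = 2^ceil(log2 (4n/3))`, so total storage is at most
#' `4 n ceil(log2(v+1))` bits. Entries never touched by construction hold 0.
#'
#' @param keys character vector of distinct fixed-length k-mer tokens
#'   (ACGT). No canonicalization is applied here; callers index canonical
#'   k-mers if strand collapsing is wanted.
#' @param values integer vector of categories in `1..v`, one per key.
#' @param v number of valid categories; defaults to `max(values)`.
#' @param seed base hash seed; retry `i` uses `seed + i - 1`.
#' @param max_retries number of hash reseeds before failing.
#' @return an object of class `othello` with fields `n`, `v`, `l`, `ma`,
#'   `mb`, `seed` (the seed actually used), `attempts`, and the arrays
#'   `A`, `B`.
#' @export
build_othello <- function(keys, values, v = NULL, seed = 1L,
                          max_retries = 100L) {
  n <- length(keys)
  stopifnot(n >= 1L, length(values) == n)
  values <- as.integer(values)
  if (is.null(v)) v <- max(values)
  v <- as.integer(v)
  if (v < 1L) stop("v must be >= 1")
  if (any(is.na(values)) || any(values < 1L) || any(values > v))
    stop("all values must lie in 1..", v)
  l <- ceil_log2(v + 1L)
  ma <- as.integer(2^max(0L, ceil_log2(n)))
  mb <- as.integer(2^max(0L, ceil_log2(4 * n / 3)))
  res <- cpp_othello_build(keys, values, ma, mb, as.integer(seed),
                           as.integer(max_retries))
  if (res$attempts > 1L)
    message(sprintf("othello: %d hash reseed(s) before acyclic construction",
                    res$attempts - 1L))
  structure(list(n = n, v = v, l = l, ma = ma, mb = mb,
                 seed = res$seed, attempts = res$attempts,
                 A = res$A, B = res$B),
            class = "othello")
}

#' Query an Othello
#'
#' Total on the k-mer universe: two array reads and one XOR per key. For
#' constructed keys the assigned category is returned; for alien keys the
#' result is a deterministic value in `0..2^l-1`.
#'
#' @param o an `othello` object.
#' @param keys character vector of k-mer tokens.
#' @return integer vector of values in `0..2^l-1`.
#' @export
query_othello <- function(o, keys) {
  stopifnot(inherits(o, "othello"))
  cpp_othello_query(keys, o$A, o$B, o$seed)
}

#' @export
print.othello <- function(x, ...) {
  cat(sprintf("othello: n=%d keys -> v=%d categories (l=%d bits), m_a=%d, m_b=%d, seed=%d\n",
              x$n, x$v, x$l, x$ma, x$mb, x$seed))
  invisible(x)
}

#' Alien-key value distribution of an Othello
#'
#' The probability that a uniformly random alien key maps to each value
#' `x` in `0..2^l-1` is the XOR convolution `p_x = sum_t a_t b_(x XOR t)`
#' of the array value fractions `a`, `b`. The exact convolution is used for
#' `l < 12`; for wider arrays `p_0 = sum_x a_x b_x` is computed exactly and
#' the remaining mass is spread evenly, `p_(x!=0) = (1 - p_0)/(2^l - 1)`.
#'
#' @param o an `othello` object.
#' @param exact force (`TRUE`) or suppress (`FALSE`) the exact convolution;
#'   `NULL` switches on `l < 12`.
#' @return object of class `alien_profile`: `p` (length `2^l`), `p0`,
#'   `p_alien` (mass on `C - V = {0, v+1, ..., 2^l-1}`), `v`, `l`, `exact`.
#' @export
alien_value_distribution <- function(o, exact = NULL) {
  stopifnot(inherits(o, "othello"))
  l <- o$l
  nc <- 2L^l
  a <- tabulate(o$A + 1L, nbins = nc) / o$ma
  b <- tabulate(o$B + 1L, nbins = nc) / o$mb
  if (is.null(exact)) exact <- l < 12L
  if (exact) {
    p <- vapply(0:(nc - 1L), function(x) {
      sum(a * b[bitwXor(x, 0:(nc - 1L)) + 1L])
    }, numeric(1))
  } else {
    p0 <- sum(a * b)
    p <- rep((1 - p0) / (nc - 1L), nc)
    p[1L] <- p0
  }
  p_alien <- p[1L] +
    if (o$v + 1L <= nc - 1L) sum(p[(o$v + 2L):nc]) else 0
  structure(list(p = p, p0 = p[1L], p_alien = p_alien,
                 v = o$v, l = l, exact = exact),
            class = "alien_profile")
}

#' Probability that an alien key is recognized as alien
#'
#' `P_Alien = p_0 + sum_(x=v+1)^(2^l-1) p_x`: the alien-value mass falling
#' outside the valid category set. For large key sets this exceeds
#' `exp(-1.5) ~ 0.223`.
#'
#' @inheritParams alien_value_distribution
#' @return a probability.
#' @export
alien_rejection_probability <- function(o, exact = NULL) {
  alien_value_distribution(o, exact = exact)$p_alien
}

# ---- serialization ---------------------------------------------------------

OTH_MAGIC <- charToRaw("KOTH")
OTH_VERSION <- 1L

#' Serialize / deserialize an Othello
#'
#' Binary layout: magic bytes, format version, `n`, `v`, `l`, `m_a`, `m_b`,
#' hash seed, little-endian `l`-bit packed arrays `A` then `B`, and an
#' FNV-1a checksum of the packed payload. `deserialize_othello` rejects
#' truncated streams, wrong magic/version, and checksum mismatches.
#'
#' @param o an `othello` object.
#' @return `serialize_othello`: a raw vector; `deserialize_othello`: an
#'   `othello` object answering identically to the original.
#' @export
serialize_othello <- function(o) {
  stopifnot(inherits(o, "othello"))
  payload <- c(cpp_pack_lbits(o$A, o$l), cpp_pack_lbits(o$B, o$l))
  con <- rawConnection(raw(0), "wb")
  on.exit(close(con))
  writeBin(OTH_MAGIC, con)
  writeBin(as.integer(c(OTH_VERSION, o$n, o$v, o$l, o$ma, o$mb, o$seed)),
           con, size = 4L, endian = "little")
  writeBin(cpp_fnv1a32(payload), con, size = 8L, endian = "little")
  writeBin(payload, con)
  rawConnectionValue(con)
}

#' @param bytes raw vector produced by `serialize_othello`.
#' @rdname serialize_othello
#' @export
deserialize_othello <- function(bytes) {
  header_len <- 4L + 7L * 4L + 8L
  if (length(bytes) < header_len)
    stop("truncated othello stream: header incomplete")
  if (!identical(bytes[1:4], OTH_MAGIC))
    stop("not an othello stream (bad magic bytes)")
  con <- rawConnection(bytes[-(1:4)])
  on.exit(close(con))
  ints <- readBin(con, "integer", n = 7L, size = 4L, endian = "little")
  if (ints[1] != OTH_VERSION)
    stop("unsupported othello format version ", ints[1])
  n <- ints[2]; v <- ints[3]; l <- ints[4]; ma <- ints[5]; mb <- ints[6]
  seed <- ints[7]
  checksum <- readBin(con, "double", n = 1L, size = 8L, endian = "little")
  nbytes <- ceiling(ma * l / 8) + ceiling(mb * l / 8)
  payload <- readBin(con, "raw", n = nbytes)
  if (length(payload) < nbytes)
    stop("truncated othello stream: expected ", nbytes, " payload bytes")
  if (!isTRUE(all.equal(cpp_fnv1a32(payload), checksum)))
    stop("othello stream checksum mismatch")
  na_bytes <- ceiling(ma * l / 8)
  A <- cpp_unpack_lbits(payload[seq_len(na_bytes)], l, ma)
  B <- cpp_unpack_lbits(payload[-seq_len(na_bytes)], l, mb)
  structure(list(n = n, v = v, l = l, ma = ma, mb = mb,
                 seed = seed, attempts = NA_integer_, A = A, B = B),
            class = "othello")
}

write_othello <- function(o, path) {
  writeBin(serialize_othello(o), path)
  invisible(path)
}

read_othello <- function(path) {
  deserialize_othello(readBin(path, "raw", n = file.size(path)))
}
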