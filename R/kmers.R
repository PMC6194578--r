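# k-mer file IO and canonicalization. Input dialects: Jellyfish dump
# (">count" header followed by the k-mer sequence) and plain one-k-mer-per-
# line text, both gzip-transparent. Counts are presence-only and ignored.

#' Read a k-mer file into sorted unique canonical k-mers
#'
#' Auto-detects the Jellyfish-dump FASTA dialect versus plain text. Each
#' k-mer is canonicalized (lexicographic minimum of the k-mer and its
#' reverse complement), deduplicated and sorted; lexicographic order on
#' ACGT strings coincides with numeric order of the 2-bit packing. Records
#' of the wrong length or containing non-ACGT characters are skipped with
#' a message.
#'
#' @param path k-mer file (optionally gzip-compressed).
#' @param k k-mer length.
#' @return character vector of sorted unique canonical k-mers.
#' @export
read_kmer_file <- function(path, k) {
  if (!file.exists(path)) stop("cannot read k-mer file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  is_header <- startsWith(lines, ">")
  if (any(is_header)) lines <- lines[!is_header]
  canon <- cpp_canonical_kmers(lines, as.integer(k))
  n_bad <- sum(is.na(canon))
  if (n_bad > 0L) {
    message(sprintf("read_kmer_file: skipped %d invalid record(s) in %s",
                    n_bad, basename(path)))
    canon <- canon[!is.na(canon)]
  }
  if (length(canon) == 0L)
    stop("zero valid k-mers in ", path)
  sort(unique(canon), method = "radix")
}

#' Write a k-mer file
#'
#' @param kmers character vector of k-mers.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param format `"jellyfish"` for ">count\\nKMER" records or `"plain"` for
#'   one k-mer per line.
#' @return `path`, invisibly.
#' @export
write_kmer_file <- function(kmers, path, format = c("jellyfish", "plain")) {
  format <- match.arg(format)
  lines <- if (format == "jellyfish") paste0(">1\n", kmers) else kmers
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Generate random k-mers
#'
#' Uniform draws from the 4^k universe using a dedicated deterministic
#' stream (independent of R's RNG state).
#'
#' @param n number of k-mers.
#' @param k k-mer length.
#' @param seed integer seed.
#' @param canonical canonicalize each draw.
#' @param distinct force pairwise-distinct output.
#' @return character vector of length `n`.
#' @export
random_kmers <- function(n, k, seed = 1L, canonical = FALSE,
                         distinct = TRUE) {
  cpp_random_kmers(as.integer(n), as.integer(k), as.integer(seed),
                   canonical, distinct)
}

#' Sample alien k-mers (absent from an exclusion set)
#'
#' Uniform draws from the 4^k universe, rejecting any member of `exclude`.
#' Used to probe false-positive behaviour of a built index.
#'
#' @inheritParams random_kmers
#' @param exclude character vector of k-mers to avoid (e.g. all indexed
#'   k-mers).
#' @export
sample_alien_kmers <- function(n, k, exclude, seed = 1L, canonical = FALSE,
                               distinct = FALSE) {
  cpp_alien_kmers(as.integer(n), as.integer(k), as.integer(seed),
                  exclude, canonical, distinct)
}

#' Extract the canonical k-mer set of raw sequences
#'
#' Convenience k-mer extractor for tests and small inputs: slides a window
#' over each sequence, skips windows containing non-ACGT characters, and
#' returns the sorted unique canonical k-mer set.
#'
#' @param seqs character vector of sequences (reads or transcripts).
#' @param k k-mer length.
#' @export
kmer_set <- function(seqs, k) {
  sort(unique(cpp_kmers_of_seqs(seqs, as.integer(k), TRUE)),
       method = "radix")
}
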